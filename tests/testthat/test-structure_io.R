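# PDB fixture lines built in code (fixed-column V3 ATOM/HETATM records)
pdb_line <- function(type, serial, name, resn, chain, resno, x, y, z,
                     elem = substr(name, 1, 1), alt = " ", occ = 1.00) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f  0.00          %2s",
          type, serial, name, alt, resn, chain, resno, x, y, z, occ, elem)
}

write_min_pdb <- function(path, ligand_copies = 1, waters = 2,
                          noncanonical = FALSE, altloc = FALSE) {
  lines <- character(0)
  s <- 0
  for (r in 1:3) {
    s <- s + 1
    lines <- c(lines, pdb_line("ATOM", s, "CA", "GLY", "A", r,
                               3.8 * r, 0, 0, "C"))
    if (altloc && r == 1) {
      # two conformers of a CB atom: B has the higher occupancy
      lines <- c(lines,
                 pdb_line("ATOM", s + 100, "CB", "GLY", "A", r,
                          1.0, 0, 0, "C", alt = "A", occ = 0.4),
                 pdb_line("ATOM", s + 101, "CB", "GLY", "A", r,
                          2.0, 0, 0, "C", alt = "B", occ = 0.6))
    }
  }
  if (noncanonical) {
    s <- s + 1
    lines <- c(lines, pdb_line("HETATM", s, "SE", "MSE", "A", 4,
                               10, 0, 0, "SE"))
  }
  for (k in seq_len(ligand_copies)) {
    for (j in 1:3) {
      s <- s + 1
      lines <- c(lines, pdb_line("HETATM", s, paste0("C", j), "ABC", "B",
                                 100 + k, 20 + 1.4 * j, 5 * k, 0, "C"))
    }
  }
  for (w in seq_len(waters)) {
    s <- s + 1
    lines <- c(lines, pdb_line("HETATM", s, "O", "HOH", "W", 200 + w,
                               -5 * w, -5, -5, "O"))
  }
  writeLines(c(lines, "END"), path)
  path
}

test_that("read_structure separates polymer, ligands and waters", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_min_pdb(tmp, ligand_copies = 1, waters = 2)
  st <- read_structure(tmp)
  expect_s3_class(st$receptor, "ReceptorStructure")
  expect_equal(nrow(st$receptor$residues), 3)
  expect_length(st$ligands, 1)
  expect_equal(st$ligands[[1]]$comp_id, "ABC")
  # waters never surface as ligands
  tmp2 <- withr::local_tempfile(fileext = ".pdb")
  write_min_pdb(tmp2, ligand_copies = 0, waters = 3)
  expect_length(read_structure(tmp2)$ligands, 0)
})

test_that("multiple asymmetric-unit copies yield one instance each", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_min_pdb(tmp, ligand_copies = 2)
  st <- read_structure(tmp)
  expect_length(st$ligands, 2)
  expect_setequal(vapply(st$ligands, `[[`, character(1), "comp_id"),
                  c("ABC", "ABC"))
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_min_pdb(tmp, altloc = TRUE)
  st <- read_structure(tmp)
  cb <- st$receptor$atoms[st$receptor$atoms$name == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$x, 2.0)
})

test_that("noncanonical residues stay in the receptor, flagged", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_min_pdb(tmp, noncanonical = TRUE, ligand_copies = 1)
  st <- read_structure(tmp)
  expect_equal(sum(!st$receptor$residues$canonical), 1)
  expect_equal(st$receptor$residues$resid[!st$receptor$residues$canonical],
               "MSE")
  expect_length(st$ligands, 1)  # MSE is not a ligand
})

test_that("degenerate inputs raise the documented errors", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a pdb file at all", tmp)
  expect_error(read_structure(tmp))
  tmp2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line("HETATM", 1, "C1", "ABC", "B", 1, 0, 0, 0, "C"),
               "END"), tmp2)
  expect_error(read_structure(tmp2), "empty receptor")
  expect_error(read_structure("/nonexistent/file.pdb"), "not found")
})

test_that("writing and re-reading preserves counts and coordinates", {
  sc <- make_kinase_scaffold()
  lig <- place_ligand_for_mode(sc, sc$map, "I")
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sc$receptor, tmp, ligands = list(lig))
  rt <- read_structure(tmp)
  expect_equal(nrow(rt$receptor$residues), nrow(sc$receptor$residues))
  expect_equal(nrow(rt$receptor$atoms), nrow(sc$receptor$atoms))
  expect_lt(max(abs(as.matrix(rt$receptor$atoms[, c("x", "y", "z")]) -
                    as.matrix(sc$receptor$atoms[, c("x", "y", "z")]))), 1e-3)
  expect_length(rt$ligands, 1)
  expect_lt(max(abs(heavy_coords(rt$ligands[[1]]) - heavy_coords(lig))), 1e-3)
})

test_that("filter_ligands applies exclusion list and size cutoff in order", {
  mk <- function(id, n) {
    ligand_instance(id, data.frame(name = paste0("C", 1:n), element = "C",
                                   charge = 0, x = seq_len(n), y = 0, z = 0))
  }
  excl <- exclusion_list(c("GOL", "SO4", "EDO"))
  ligs <- c(lapply(c("GOL", "SO4", "EDO"), mk, n = 6),
            list(mk("DRG", 12), mk("TIN", 3)),
            lapply(paste0("L", 1:5), mk, n = 8))
  out <- filter_ligands(ligs, excl, min_heavy_atoms = 6)
  expect_length(out, 6)  # 10 in, 3 excluded, 1 too small
  expect_equal(vapply(out, `[[`, character(1), "comp_id"),
               c("DRG", paste0("L", 1:5)))  # order preserved
  # idempotent
  expect_identical(filter_ligands(out, excl, 6), out)
  # empty in, empty out
  expect_length(filter_ligands(list(), excl, 6), 0)
  # glycerol-style artifact dropped, drug-like ligand kept
  expect_length(filter_ligands(list(mk("GOL", 6), mk("DRG", 20)), excl, 6), 1)
})

test_that("default exclusion list loads and screens common artifacts", {
  excl <- default_exclusion_list()
  expect_true(all(c("GOL", "SO4", "EDO", "CL", "MG") %in% excl$comp_ids))
  expect_false(any(grepl("#", excl$comp_ids)))
})

test_that("noncanonical proximity uses a strict cutoff and is monotone", {
  res <- data.frame(chain = "A", resno = 1:2, resid = c("GLY", "MSE"),
                    canonical = c(TRUE, FALSE))
  mk_rec <- function(d) receptor_structure("t", res, data.frame(
    chain = "A", resno = 1:2, name = c("CA", "SE"), element = c("C", "SE"),
    x = c(0, d), y = 0, z = 0))
  lig <- ligand_instance("LIG", data.frame(name = "C1", element = "C",
                                           charge = 0, x = 0, y = 0, z = 0))
  expect_true(flag_noncanonical_proximity(mk_rec(3), lig, cutoff = 5))
  expect_false(flag_noncanonical_proximity(mk_rec(5.0), lig, cutoff = 5))
  expect_false(flag_noncanonical_proximity(mk_rec(7), lig, cutoff = 5))
  # no noncanonical residues at all
  rec0 <- receptor_structure("t", res[1, , drop = FALSE], data.frame(
    chain = "A", resno = 1, name = "CA", element = "C", x = 0, y = 0, z = 0))
  expect_false(flag_noncanonical_proximity(rec0, lig, cutoff = 5))
  # monotone: true at c implies true at any larger c
  for (d in c(1, 4.9, 6.5)) {
    r <- mk_rec(d)
    for (co in c(2, 5, 8)) {
      if (flag_noncanonical_proximity(r, lig, co))
        expect_true(flag_noncanonical_proximity(r, lig, co + 3))
    }
  }
})

test_that("ligand manifest records exclusion reasons", {
  mk <- function(id, n) ligand_instance(id, data.frame(
    name = paste0("C", 1:n), element = "C", charge = 0,
    x = seq_len(n), y = 0, z = 0))
  man <- ligand_manifest("1abc", list(mk("GOL", 6), mk("DRG", 12), mk("XS", 2)),
                         exclusion_list("GOL"), min_heavy_atoms = 6)
  expect_equal(man$excluded, c(TRUE, FALSE, TRUE))
  expect_equal(man$reason, c("exclusion_list", "", "too_few_heavy_atoms"))
})

test_that("SMILES and SDF ligand I/O round-trips atoms, bonds and charges", {
  lg <- ligand_from_smiles("CC(=O)[O-]", comp_id = "ACT")
  expect_equal(net_charge(lg), -1L)
  expect_equal(sum(lg$atoms$element != "H"), 4)
  tmp <- withr::local_tempfile(fileext = ".sdf")
  write_ligands_sdf(list(lg), tmp)
  back <- read_ligands_sdf(tmp)
  expect_length(back, 1)
  expect_equal(net_charge(back[[1]]), -1L)
  expect_equal(nrow(back[[1]]$bonds), nrow(lg$bonds))
  expect_equal(back[[1]]$atoms$element, lg$atoms$element)
})
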