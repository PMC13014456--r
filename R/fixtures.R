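#' Fixture generation settings
#'
#' @param seed integer seed; a fixed seed yields byte-identical fixtures.
#' @param mode_target binding mode a placed ligand should realise.
#' @param noise_sigma per-coordinate Gaussian noise (Angstrom) for pose
#'   sets.
#' @param n_poses poses per generated pose set (default 10, matching the
#'   ten-sample Any/Top-1 evaluation protocol).
#' @param n_klifs fingerprint length (fixed at 84).
#' @return object of class `FixtureSpec`.
#' @export
fixture_spec <- function(seed = 1L, mode_target = "I", noise_sigma = 0.5,
                         n_poses = 10L, n_klifs = 84L) {
  stopifnot(n_klifs == 84, mode_target %in% BINDING_MODES)
  structure(list(seed = as.integer(seed), mode_target = mode_target,
                 noise_sigma = noise_sigma, n_poses = as.integer(n_poses),
                 n_klifs = 84L),
            class = "FixtureSpec")
}

# Fixed anchor geometry of the toy kinase (Angstrom). Regions are laid out
# well separated so that every classifier branch is reachable with margin:
# hinge at the origin, the back-pocket grid at x in [7, 14], the
# Type-II-only site beyond it, the alpha-C N-terminal cluster above the
# cleft entrance and the alpha-C-Glu(+4) anchor below the back pocket.
.SCAFFOLD <- list(
  hinge_xyz = rbind(c(-1.5, 0, 0), c(0, 0, 0), c(1.5, 0, 0)),
  type2_xyz = rbind(c(10, 6, 0), c(11, 6, 0), c(10, 7, 0), c(11, 7, 0)),
  nterm_xyz = rbind(c(4.5, 6, 0), c(5.5, 6, 0), c(6.5, 6, 0),
                    c(5, 7, 0), c(6, 7, 0)),
  glu4_xyz = rbind(c(10, -3, 0)),
  back_grid = function(n) {
    gx <- 7 + 1.4 * (0:5); gy <- -2 + 1.3 * (0:5)
    g <- expand.grid(x = gx, y = gy)
    cbind(g$x[seq_len(n)], g$y[seq_len(n)], 0)
  },
  klifs_grid = function(n) {
    gx <- -2 + 2 * (0:11); gy <- -6 + 2 * (0:6)
    g <- expand.grid(x = gx, y = gy)
    cbind(g$x[seq_len(n)], g$y[seq_len(n)], 4)
  })

#' Build the synthetic kinase scaffold
#'
#' A toy receptor whose residues realise every region of the default map at
#' known, geometrically separated coordinates: each residue contributes a
#' CA atom at its anchor and a CB pseudoatom 0.8 A above it. Residues
#' belonging to the named regions take the anchor positions above; the
#' remaining KLIFS residues fill a lattice over the cleft. The geometry is
#' deterministic (the seed only matters for downstream ligand jitter).
#'
#' @param spec a `FixtureSpec`.
#' @return list with `receptor` (`ReceptorStructure`) and `map`
#'   (`KinaseRegionMap`, the default map).
#' @export
make_kinase_scaffold <- function(spec = fixture_spec()) {
  map <- default_region_map()
  placed <- list()
  for (i in seq_along(map$hinge))
    placed[[as.character(map$hinge[i])]] <- .SCAFFOLD$hinge_xyz[i, ]
  for (i in seq_along(map$type2_pocket))
    placed[[as.character(map$type2_pocket[i])]] <- .SCAFFOLD$type2_xyz[i, ]
  for (i in seq_along(map$alphaC_nterm))
    placed[[as.character(map$alphaC_nterm[i])]] <- .SCAFFOLD$nterm_xyz[i, ]
  placed[[as.character(map$alphaC_glu_plus4[1])]] <- .SCAFFOLD$glu4_xyz[1, ]
  back_rest <- setdiff(map$back_pocket, as.integer(names(placed)))
  bg <- .SCAFFOLD$back_grid(length(back_rest))
  for (i in seq_along(back_rest))
    placed[[as.character(back_rest[i])]] <- bg[i, ]
  all_res <- sort(unique(c(map$hinge, map$back_pocket, map$type2_pocket,
                           map$alphaC_nterm, map$alphaC_glu_plus4,
                           map$klifs_residues)))
  rest <- setdiff(all_res, as.integer(names(placed)))
  kg <- .SCAFFOLD$klifs_grid(length(rest))
  for (i in seq_along(rest))
    placed[[as.character(rest[i])]] <- kg[i, ]

  resno <- as.integer(names(placed))
  ord <- order(resno)
  resno <- resno[ord]
  xyz <- do.call(rbind, placed[ord])
  residues <- data.frame(chain = "A", resno = resno, resid = "GLY",
                         canonical = TRUE, stringsAsFactors = FALSE)
  atoms <- data.frame(
    chain = "A", resno = rep(resno, each = 2),
    name = rep(c("CA", "CB"), length(resno)),
    element = "C",
    x = as.numeric(rbind(xyz[, 1], xyz[, 1])),
    y = as.numeric(rbind(xyz[, 2], xyz[, 2])),
    z = as.numeric(rbind(xyz[, 3], xyz[, 3] + 0.8)),
    stringsAsFactors = FALSE)
  receptor <- receptor_structure("toy_kinase", residues, atoms)
  list(receptor = receptor, map = map)
}

# Rigid asymmetric 6-atom chain (C-C-N-O-C-S, single bonds): no nontrivial
# graph automorphism, so naive and symmetry-corrected RMSD agree.
.toy_chain_ligand <- function(origin, direction, comp_id = "LIG") {
  d <- direction / sqrt(sum(direction^2))
  pts <- t(vapply(0:5, function(k) origin + 1.5 * k * d, numeric(3)))
  atoms <- data.frame(name = paste0("X", 1:6),
                      element = c("C", "C", "N", "O", "C", "S"),
                      charge = 0, x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = 1:5, a2 = 2:6, order = 1L)
  ligand_instance(comp_id, atoms, bonds)
}

#' Symmetric toy ligand (para-disubstituted ring)
#'
#' A six-membered carbon ring with nitrogen substituents at opposite
#' positions: its heavy-atom graph has a 4-element automorphism group, so
#' symmetry correction actually matters for RMSD.
#'
#' @param center ring-center coordinates.
#' @return a `LigandInstance` with 8 heavy atoms.
#' @export
make_symmetric_ligand <- function(center = c(0, 0, 0)) {
  ang <- (0:5) * pi / 3
  ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  subs <- rbind(c(2.8, 0, 0), c(-2.8, 0, 0))
  pts <- sweep(rbind(ring, subs), 2, center, "+")
  atoms <- data.frame(name = paste0("X", 1:8),
                      element = c(rep("C", 6), "N", "N"),
                      charge = 0, x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = c(1:6, 1, 4), a2 = c(2:6, 1, 7, 8),
                      order = 1L)
  ligand_instance("SYM", atoms, bonds)
}

# Anchor and direction per target mode, chosen so the rule inequalities hold
# with >= 0.5 A margin on the shipped scaffold (see the methods vignette for
# the derivation). The Type IV site sits 7.0 A from the nearest hinge atom,
# just beyond the 6.5 A remoteness threshold, so that a 2 A hinge-ward
# shift demonstrably flips the label.
.MODE_PLACEMENTS <- list(
  I    = list(origin = c(0, 0, 2.5),  direction = c(0, 0, 1)),
  I12B = list(origin = c(4.5, 0, 0),  direction = c(1, 0, 0)),
  I12F = list(origin = c(4.5, 0, 0),  direction = c(0, 1, 0)),
  II   = list(origin = c(7, 1, 0),    direction = c(3, 5, 0)),
  III  = list(origin = c(12, -3, 1),  direction = c(1, 0, 0)),
  IV   = list(origin = c(-8.5, 0, 0), direction = c(0, 0, 1)))

#' Place a ligand realising a requested binding mode
#'
#' Positions the rigid toy ligand on the scaffold so that
#' [compute_contacts()] + [classify_binding_mode()] return exactly `mode`.
#' A small seeded jitter (uniform in +/- 0.1 A, below the construction
#' margins) varies coordinates across seeds without crossing any rule
#' boundary.
#'
#' @param scaffold output of [make_kinase_scaffold()] (unused beyond
#'   asserting compatibility; placements are defined against the fixed
#'   scaffold geometry).
#' @param map the scaffold's `KinaseRegionMap`.
#' @param mode target label, one of [BINDING_MODES].
#' @param spec a `FixtureSpec` supplying the seed.
#' @return a `LigandInstance`.
#' @export
place_ligand_for_mode <- function(scaffold, map, mode,
                                  spec = fixture_spec()) {
  if (!mode %in% BINDING_MODES) stop("unknown mode: ", mode)
  pl <- .MODE_PLACEMENTS[[mode]]
  lig <- .toy_chain_ligand(pl$origin, pl$direction)
  set.seed(spec$seed + match(mode, BINDING_MODES))
  jit <- matrix(runif(18, -0.1, 0.1), ncol = 3)
  lig$atoms$x <- lig$atoms$x + jit[, 1]
  lig$atoms$y <- lig$atoms$y + jit[, 2]
  lig$atoms$z <- lig$atoms$z + jit[, 3]
  lig
}

#' Generate a noisy pose set around a reference ligand
#'
#' Per-atom Gaussian noise emulates near-native docking poses; an optional
#' whole-ligand translation applied to a fraction of poses emulates
#' wrong-pocket placements. The naive (identity-mapping) RMSD of each
#' generated pose is recorded as generation metadata.
#'
#' @param reference a `LigandInstance`.
#' @param n_poses number of poses (pose 1 = "top-ranked").
#' @param noise_sigma per-coordinate Gaussian sigma in Angstrom.
#' @param seed integer seed.
#' @param translate_frac fraction of poses additionally translated (from
#'   the last pose backwards).
#' @param translation 3-vector applied to translated poses (default 20 A
#'   along x).
#' @return a `PoseSet` with attribute `generation_rmsd`.
#' @export
make_pose_set <- function(reference, n_poses = 10L, noise_sigma = 0.5,
                          seed = 1L, translate_frac = 0,
                          translation = c(20, 0, 0)) {
  stopifnot(n_poses >= 1)
  set.seed(seed)
  ref <- heavy_coords(reference)
  n_shift <- floor(translate_frac * n_poses)
  poses <- vector("list", n_poses)
  gen_rmsd <- numeric(n_poses)
  for (i in seq_len(n_poses)) {
    noise <- matrix(rnorm(length(ref), sd = noise_sigma), ncol = 3)
    p <- ref + noise
    if (i > n_poses - n_shift) p <- sweep(p, 2, translation, "+")
    poses[[i]] <- p
    gen_rmsd[i] <- sqrt(mean(rowSums((p - ref)^2)))
  }
  ps <- pose_set(paste0("fixture_", seed), poses, reference)
  attr(ps, "generation_rmsd") <- gen_rmsd
  ps
}

#' Generate a labeled cloud of synthetic pocket fingerprints
#'
#' Three Gaussian clusters in the 84-dimensional fingerprint space, centred
#' on distinct region-distance profiles for the orthosteric, Type III and
#' Type IV sites. `separation` scales the distance between class centres;
#' the per-coordinate noise sigma is 1 A. Distances are clipped at 0.1 A to
#' stay physical.
#'
#' @param n_per_class fingerprints per class.
#' @param separation centre separation scale (0 = identical centres, chance
#'   level; >> 1 = trivially separable).
#' @param seed integer seed.
#' @return list with `fingerprints` (list of `PocketFingerprint`) and
#'   `labels` (character over [POCKET_CLASSES]).
#' @export
make_fingerprint_cloud <- function(n_per_class = 50L, separation = 10,
                                   seed = 1L) {
  stopifnot(separation >= 0)
  set.seed(seed)
  base <- 6 + 2 * sin(seq_len(84) / 5)
  u1 <- rep_len(c(1, -1), 84) / sqrt(84)
  u2 <- rep_len(c(1, 1, -1), 84); u2 <- u2 / sqrt(sum(u2^2))
  centers <- list(orthosteric = base,
                  III = base + separation * u1,
                  IV = base + separation * u2)
  fingerprints <- list(); labels <- character(0)
  for (cl in POCKET_CLASSES) {
    for (i in seq_len(n_per_class)) {
      v <- pmax(0.1, centers[[cl]] + rnorm(84, sd = 1))
      fingerprints <- c(fingerprints, list(pocket_fingerprint(v)))
      labels <- c(labels, cl)
    }
  }
  list(fingerprints = fingerprints, labels = labels)
}

#' Write a self-contained fixture bundle
#'
#' Emits the scaffold receptor (PDB), one ligand per binding mode (SDF) and
#' the region map (JSON) into a directory, exercising the package's own
#' writers so that re-reading the bundle covers the I/O paths.
#'
#' @param dir output directory (created if needed).
#' @param spec a `FixtureSpec`.
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(dir, spec = fixture_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- make_kinase_scaffold(spec)
  write_structure(sc$receptor, file.path(dir, "toy_kinase.pdb"))
  ligs <- lapply(BINDING_MODES, function(m)
    place_ligand_for_mode(sc, sc$map, m, spec))
  names(ligs) <- BINDING_MODES
  for (m in BINDING_MODES) {
    ligs[[m]]$comp_id <- paste0("L", m)
    write_ligands_sdf(ligs[m], file.path(dir, paste0("ligand_", m, ".sdf")))
  }
  jsonlite::write_json(
    list(toy_kinase = lapply(sc$map, identity)),
    file.path(dir, "region_map.json"), digits = NA)
  invisible(dir)
}
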