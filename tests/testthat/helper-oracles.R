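# Independent reference implementations and small fixture builders used
# across the suite. Each oracle is written directly from the operation's
# definition, not from the package internals it checks.

# -- contact profile assembled by hand (for classifier-level tests) ----------
make_profile <- function(hinge = 3, back = 10, type2 = 20, nterm = 20,
                         glu4 = 20, n_hinge = 1L, n_back = 0L, n_type2 = 0L,
                         n_nterm = 0L, n_glu4 = 0L) {
  structure(list(
    min_dist = c(hinge = hinge, back_pocket = back, type2_pocket = type2,
                 alphaC_nterm = nterm, alphaC_glu_plus4 = glu4),
    contact_count = c(hinge = n_hinge, back_pocket = n_back,
                      type2_pocket = n_type2, alphaC_nterm = n_nterm,
                      alphaC_glu_plus4 = n_glu4),
    contact_cutoff = 4.5), class = "ContactProfile")
}

# Direct transcription of the published rule text, precedence as documented:
# remote (IV), then DFG-out (II), then hinge-distal back pocket (III), then
# the two I1/2 variants, then I.
oracle_classify <- function(p, t4 = 6.5, t3 = 6.0, nb = 3) {
  md <- p$min_dist; cc <- p$contact_count
  if (md[["hinge"]] > t4 && md[["alphaC_glu_plus4"]] > t4) "IV"
  else if (cc[["back_pocket"]] >= nb && cc[["type2_pocket"]] >= 1) "II"
  else if (md[["hinge"]] > t3 && cc[["back_pocket"]] >= nb) "III"
  else if (cc[["back_pocket"]] >= nb && cc[["alphaC_nterm"]] >= 1) "I12F"
  else if (cc[["back_pocket"]] >= nb) "I12B"
  else "I"
}

# -- naive O(n^2) Butina reference -------------------------------------------
oracle_butina <- function(fps, sim_threshold = 0.8) {
  n <- length(fps)
  dmax <- 1 - sim_threshold
  tani <- function(a, b) {
    u <- sum(a | b)
    if (u == 0) 0 else 1 - sum(a & b) / u
  }
  nbr <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && tani(fps[[i]], fps[[j]]) <= dmax)
        nbr[[i]] <- c(nbr[[i]], j)
    }
  }
  unassigned <- rep(TRUE, n)
  clusters <- list()
  while (any(unassigned)) {
    best <- -1L; centroid <- 0L
    for (i in seq_len(n)) {
      if (!unassigned[i]) next
      cnt <- sum(unassigned[nbr[[i]]])
      if (cnt > best) { best <- cnt; centroid <- i }
    }
    members <- sort(nbr[[centroid]][unassigned[nbr[[centroid]]]])
    cl <- c(centroid, members)
    unassigned[cl] <- FALSE
    clusters <- c(clusters, list(as.integer(cl)))
  }
  clusters
}

random_fps <- function(n, bits = 64, density = 0.3, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) as.integer(runif(bits) < density))
}

# -- brute-force symmetry-corrected RMSD -------------------------------------
# Enumerates every permutation that preserves elements and the bond graph,
# then minimises the in-place RMSD.
perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms_of(v[-i])) out <- c(out, list(c(v[i], rest)))
  out
}

oracle_sym_rmsd <- function(pose, lig) {
  heavy <- which(lig$atoms$element != "H")
  el <- lig$atoms$element[heavy]
  ref <- as.matrix(lig$atoms[heavy, c("x", "y", "z")])
  b <- lig$bonds[lig$bonds$a1 %in% heavy & lig$bonds$a2 %in% heavy, ]
  remap <- match(seq_len(nrow(lig$atoms)), heavy)
  bkey <- function(p) {
    a1 <- p[remap[b$a1]]; a2 <- p[remap[b$a2]]
    sort(paste(pmin(a1, a2), pmax(a1, a2), b$order))
  }
  ref_bonds <- bkey(seq_along(heavy))
  classes <- split(seq_along(heavy), el)
  class_perms <- lapply(classes, perms_of)
  grids <- expand.grid(lapply(class_perms, seq_along))
  best <- Inf
  for (r in seq_len(nrow(grids))) {
    p <- integer(length(heavy))
    for (ci in seq_along(classes))
      p[classes[[ci]]] <- class_perms[[ci]][[grids[r, ci]]]
    if (!identical(bkey(p), ref_bonds)) next
    rmsd <- sqrt(mean(rowSums((pose[p, , drop = FALSE] - ref)^2)))
    if (rmsd < best) best <- rmsd
  }
  best
}

# Random tree-shaped molecule with bounded element multiplicity (keeps the
# permutation enumeration small) and random coordinates.
random_tree_ligand <- function(n = 8, seed = 1) {
  set.seed(seed)
  pool <- c(rep("C", 4), rep("N", 3), rep("O", 2), "S", "P", "F")
  el <- sample(pool, n)
  atoms <- data.frame(name = paste0("X", 1:n), element = el, charge = 0,
                      x = rnorm(n, sd = 3), y = rnorm(n, sd = 3),
                      z = rnorm(n, sd = 3), stringsAsFactors = FALSE)
  parent <- c(NA, vapply(2:n, function(i) sample(i - 1, 1), integer(1)))
  bonds <- data.frame(a1 = parent[-1], a2 = 2:n,
                      order = sample(1:2, n - 1, replace = TRUE))
  ligand_instance("RND", atoms, bonds)
}

# -- receptor built from a one-letter sequence (alignment tests) -------------
.AA123 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
            E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
            M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
            Y = "TYR", V = "VAL")

receptor_from_seq <- function(seq1, coords = NULL, id = "test") {
  letters1 <- strsplit(seq1, "")[[1]]
  n <- length(letters1)
  if (is.null(coords))
    coords <- cbind(3.8 * seq_len(n), sin(seq_len(n)), cos(seq_len(n)))
  residues <- data.frame(chain = "A", resno = seq_len(n),
                         resid = unname(.AA123[letters1]), canonical = TRUE,
                         stringsAsFactors = FALSE)
  atoms <- data.frame(chain = "A", resno = seq_len(n), name = "CA",
                      element = "C", x = coords[, 1], y = coords[, 2],
                      z = coords[, 3], stringsAsFactors = FALSE)
  receptor_structure(id, residues, atoms)
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1), 3)
}
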