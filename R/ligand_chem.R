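#' Chemistry configuration
#'
#' @param fp_bits fingerprint length, a power of two (default 2048).
#' @param fp_radius circular-environment radius (default 3, i.e. ECFP6-class
#'   environments).
#' @param tanimoto_threshold Butina similarity threshold in (0, 1)
#'   (default 0.8: similarity >= 0.8 joins a cluster).
#' @param ph protonation pH for hydrogen correction (default 7.4; only the
#'   physiological rule table is implemented).
#' @return object of class `ChemConfig`.
#' @export
chem_config <- function(fp_bits = 2048L, fp_radius = 3L,
                        tanimoto_threshold = 0.8, ph = 7.4) {
  fp_bits <- as.integer(fp_bits)
  if (fp_bits < 1 || bitwAnd(fp_bits, fp_bits - 1L) != 0L)
    stop("fp_bits must be a power of two")
  if (tanimoto_threshold <= 0 || tanimoto_threshold >= 1)
    stop("tanimoto_threshold must be in (0, 1)")
  structure(list(fp_bits = fp_bits, fp_radius = as.integer(fp_radius),
                 tanimoto_threshold = tanimoto_threshold, ph = ph),
            class = "ChemConfig")
}

# ---- molecular-graph helpers on LigandInstance ------------------------------

.default_valence <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L, F = 1L,
                      CL = 1L, BR = 1L, I = 1L, B = 3L, H = 1L)

# bond-order sums and neighbor lists over all atoms
.graph_info <- function(lig) {
  n <- nrow(lig$atoms)
  deg <- numeric(n)
  nbrs <- vector("list", n)
  bord <- vector("list", n)
  if (nrow(lig$bonds)) {
    for (b in seq_len(nrow(lig$bonds))) {
      i <- lig$bonds$a1[b]; j <- lig$bonds$a2[b]; o <- lig$bonds$order[b]
      deg[i] <- deg[i] + o; deg[j] <- deg[j] + o
      nbrs[[i]] <- c(nbrs[[i]], j); nbrs[[j]] <- c(nbrs[[j]], i)
      bord[[i]] <- c(bord[[i]], o); bord[[j]] <- c(bord[[j]], o)
    }
  }
  list(deg = deg, nbrs = nbrs, bord = bord)
}

# implicit hydrogen count an atom still needs under standard valence rules
.implicit_h <- function(element, charge, bond_order_sum) {
  v <- .default_valence[element]
  if (is.na(v)) return(0L)
  # charge shifts the target valence for N (+1 -> 4, -1 -> 2) and O (-1 -> 1)
  if (element == "N") v <- v + charge
  if (element %in% c("O", "S")) v <- v + charge
  max(0L, as.integer(round(v - bond_order_sum)))
}

.ring_atoms <- function(lig) {
  if (nrow(lig$bonds) == 0) return(integer(0))
  g <- igraph::graph_from_edgelist(
    as.matrix(lig$bonds[, c("a1", "a2")]), directed = FALSE)
  if (igraph::vcount(g) < nrow(lig$atoms))
    g <- igraph::add_vertices(g, nrow(lig$atoms) - igraph::vcount(g))
  # atoms lying on a cycle: edges not in any bridge
  br <- igraph::bridges(g)
  g2 <- igraph::delete_edges(g, br)
  comp <- igraph::components(g2)
  keep <- which(comp$csize >= 3)
  which(comp$membership %in% keep & igraph::degree(g2) > 0)
}

# enumerate simple rings of a given size containing given element pattern
.find_rings <- function(lig, size) {
  if (nrow(lig$bonds) < size) return(list())
  g <- igraph::graph_from_edgelist(
    as.matrix(lig$bonds[, c("a1", "a2")]), directed = FALSE)
  if (igraph::vcount(g) < nrow(lig$atoms))
    g <- igraph::add_vertices(g, nrow(lig$atoms) - igraph::vcount(g))
  ring <- igraph::make_ring(size)
  iso <- igraph::subgraph_isomorphisms(ring, g, method = "vf2")
  if (!length(iso)) return(list())
  seen <- character(0); out <- list()
  for (m in iso) {
    ix <- sort(as.integer(m))
    key <- paste(ix, collapse = ",")
    if (!key %in% seen) { seen <- c(seen, key); out <- c(out, list(as.integer(m))) }
  }
  out
}

.remove_one_h <- function(lig, parent) {
  gi <- .graph_info(lig)
  hs <- gi$nbrs[[parent]][lig$atoms$element[gi$nbrs[[parent]]] == "H"]
  if (!length(hs)) return(lig)
  drop <- hs[1]
  keep <- setdiff(seq_len(nrow(lig$atoms)), drop)
  remap <- match(seq_len(nrow(lig$atoms)), keep)
  b <- lig$bonds[lig$bonds$a1 != drop & lig$bonds$a2 != drop, , drop = FALSE]
  b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
  lig$atoms <- lig$atoms[keep, , drop = FALSE]
  rownames(lig$atoms) <- NULL
  lig$bonds <- b
  lig
}

#' Add explicit hydrogens to fill standard valences
#'
#' Hydrogens are appended after the heavy atoms; when the parent atom has
#' coordinates, each hydrogen is placed 1.0 A away along a deterministic
#' direction (placement is topological bookkeeping, not geometry
#' optimisation).
#'
#' @param lig a `LigandInstance`.
#' @return a `LigandInstance` with explicit hydrogens.
#' @export
add_explicit_hydrogens <- function(lig) {
  gi <- .graph_info(lig)
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1), c(1, 1, 0) / sqrt(2),
                c(-1, -1, 0) / sqrt(2))
  for (i in which(lig$atoms$element != "H")) {
    exp_h <- sum(lig$atoms$element[gi$nbrs[[i]]] == "H")
    need <- .implicit_h(lig$atoms$element[i], lig$atoms$charge[i],
                        gi$deg[i]) # deg counts explicit H already
    if (need <= 0) next
    for (k in seq_len(need)) {
      p <- lig$atoms[i, c("x", "y", "z")]
      newxyz <- if (any(is.na(p))) c(NA_real_, NA_real_, NA_real_)
                else as.numeric(p) + dirs[(exp_h + k - 1) %% 8 + 1, ]
      lig$atoms <- rbind(lig$atoms,
                         data.frame(name = paste0("H", nrow(lig$atoms) + 1),
                                    element = "H", charge = 0,
                                    x = newxyz[1], y = newxyz[2], z = newxyz[3],
                                    stringsAsFactors = FALSE))
      lig$bonds <- rbind(lig$bonds,
                         data.frame(a1 = i, a2 = nrow(lig$atoms), order = 1L))
    }
    gi <- .graph_info(lig)
  }
  rownames(lig$atoms) <- NULL
  lig
}

#' Correct protonation states at physiological pH
#'
#' Applies a fixed pH-7.4 rule table to five functional groups, then writes
#' explicit hydrogens:
#' \itemize{
#'   \item carboxylic acid (pKa ~ 4-5): deprotonated to carboxylate, O(-1);
#'   \item tetrazole (pKa ~ 4.9): deprotonated tetrazolide, ring N(-1);
#'   \item aliphatic amines (primary/secondary/tertiary; not amide, aniline
#'     or guanidine-adjacent; pKa ~ 10): protonated, N(+1);
#'   \item nitro: enforced charge-separated form N(+1) with one O(-1);
#'   \item imidazole (pKa ~ 6-7): neutral with a single ring NH.
#' }
#' Atoms not matching any rule are unchanged. The operation is idempotent.
#'
#' @param lig a `LigandInstance`.
#' @param cfg a `ChemConfig` (only `ph` is consulted; 7.4 rules only).
#' @return corrected `LigandInstance` with explicit hydrogens.
#' @export
correct_hydrogens <- function(lig, cfg = chem_config()) {
  at <- lig$atoms; gi <- .graph_info(lig)
  el <- at$element
  heavy_deg <- vapply(seq_len(nrow(at)), function(i)
    sum(el[gi$nbrs[[i]]] != "H"), integer(1))

  is_terminal_O <- function(i) el[i] == "O" && heavy_deg[i] == 1
  bond_order_to <- function(i, j) {
    hit <- (lig$bonds$a1 == i & lig$bonds$a2 == j) |
           (lig$bonds$a1 == j & lig$bonds$a2 == i)
    if (any(hit)) lig$bonds$order[which(hit)[1]] else 0L
  }
  set_bond_order <- function(i, j, o) {
    hit <- (lig$bonds$a1 == i & lig$bonds$a2 == j) |
           (lig$bonds$a1 == j & lig$bonds$a2 == i)
    lig$bonds$order[which(hit)[1]] <<- as.integer(o)
  }

  ring_ix <- .ring_atoms(lig)

  # --- nitro: N with two terminal O neighbors and one other substituent ----
  for (i in which(el == "N")) {
    os <- gi$nbrs[[i]][el[gi$nbrs[[i]]] == "O" &
                         vapply(gi$nbrs[[i]], is_terminal_O, logical(1))]
    if (length(os) != 2 || heavy_deg[i] != 3) next
    orders <- vapply(os, function(o) bond_order_to(i, o), numeric(1))
    if (all(orders == 2)) set_bond_order(i, os[2], 1L)
    lig$atoms$charge[i] <- 1L
    singles <- os[vapply(os, function(o) bond_order_to(i, o) == 1, logical(1))]
    lig$atoms$charge[os] <- 0L
    lig$atoms$charge[singles[1]] <- -1L
  }

  # --- carboxylic acid -> carboxylate --------------------------------------
  at <- lig$atoms; el <- at$element
  for (i in which(el == "C")) {
    nb <- gi$nbrs[[i]]
    os <- nb[el[nb] == "O" & vapply(nb, is_terminal_O, logical(1))]
    if (length(os) != 2) next
    orders <- vapply(os, function(o) bond_order_to(i, o), numeric(1))
    if (!(any(orders == 2) && any(orders == 1))) next
    o_single <- os[orders == 1][1]
    if (lig$atoms$charge[o_single] == 0) {
      lig$atoms$charge[o_single] <- -1L
      lig <- .remove_one_h(lig, o_single)
      gi <- .graph_info(lig); at <- lig$atoms; el <- at$element
      heavy_deg <- vapply(seq_len(nrow(at)), function(k)
        sum(el[gi$nbrs[[k]]] != "H"), integer(1))
    }
  }

  # --- tetrazole -> tetrazolide --------------------------------------------
  for (ring in .find_rings(lig, 5)) {
    els <- lig$atoms$element[ring]
    if (sum(els == "N") != 4 || sum(els == "C") != 1) next
    ns <- ring[els == "N"]
    if (any(lig$atoms$charge[ns] == -1)) next  # already deprotonated
    gi <- .graph_info(lig)
    nh <- ns[vapply(ns, function(n)
      any(lig$atoms$element[gi$nbrs[[n]]] == "H"), logical(1))]
    # protonated ring N if explicit H present, else the N with lowest
    # bond-order sum accepts the charge
    target <- if (length(nh)) nh[1] else
      ns[which.min(vapply(ns, function(n) gi$deg[n], numeric(1)))]
    lig$atoms$charge[target] <- -1L
    lig <- .remove_one_h(lig, target)
  }

  # --- imidazole: neutral, single ring NH ----------------------------------
  for (ring in .find_rings(lig, 5)) {
    els <- lig$atoms$element[ring]
    if (sum(els == "N") != 2 || sum(els == "C") != 3) next
    ring_bonds <- mapply(function(a, b) bond_order_to(a, b),
                         ring, ring[c(2:5, 1)])
    if (sum(ring_bonds == 2) < 2) next   # not the conjugated azole
    ns <- ring[els == "N"]
    gi <- .graph_info(lig)
    lig$atoms$charge[ns][lig$atoms$charge[ns] == 1] <- 0L
    nh <- ns[vapply(ns, function(n)
      any(lig$atoms$element[gi$nbrs[[n]]] == "H") |
        (gi$deg[n] < 3), logical(1))]
    # pyridine-type N (two ring double-bond share) carries no H; if both ring
    # nitrogens would carry one, keep only the lower-index NH (tau default)
    if (length(nh) == 2) {
      both_h <- ns[vapply(ns, function(n)
        any(lig$atoms$element[gi$nbrs[[n]]] == "H"), logical(1))]
      if (length(both_h) == 2) lig$atoms <- lig$atoms  # handled by H removal
      drop_n <- sort(nh)[2]
      if (any(lig$atoms$element[gi$nbrs[[drop_n]]] == "H"))
        lig <- .remove_one_h(lig, drop_n)
    }
  }

  # --- aliphatic amines -> ammonium ----------------------------------------
  gi <- .graph_info(lig); at <- lig$atoms; el <- at$element
  ring_ix <- .ring_atoms(lig)
  for (i in which(el == "N")) {
    if (at$charge[i] != 0) next
    if (i %in% ring_ix) next
    if (any(gi$bord[[i]] > 1)) next                   # imine/nitrile/nitro
    heavies <- gi$nbrs[[i]][el[gi$nbrs[[i]]] != "H"]
    if (length(heavies) == 0 || length(heavies) > 3) next
    if (!all(el[heavies] == "C")) next
    ok <- TRUE
    for (c_nb in heavies) {
      # amide / guanidine / vinylogous: adjacent carbon with any double bond
      if (any(gi$bord[[c_nb]] > 1)) { ok <- FALSE; break }
      # aniline: adjacent carbon in a ring counts as aromatic-adjacent here
      if (c_nb %in% ring_ix &&
          any(vapply(gi$nbrs[[c_nb]], function(k)
            k %in% ring_ix && bond_order_to(c_nb, k) > 1, logical(1)))) {
        ok <- FALSE; break
      }
    }
    if (!ok) next
    lig$atoms$charge[i] <- 1L
  }

  add_explicit_hydrogens(lig)
}

#' Net formal charge of a ligand
#' @param lig a `LigandInstance`.
#' @return integer.
#' @export
net_charge <- function(lig) as.integer(round(sum(lig$atoms$charge)))

# ---- fingerprints and diversity --------------------------------------------

.lig_to_obmol <- function(lig) {
  if (!is.null(lig$smiles))
    return(ChemmineOB::forEachMol("SMILES", lig$smiles, identity))
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  write_ligands_sdf(list(lig), tmp)
  ChemmineOB::forEachMol("SDF", paste(readLines(tmp), collapse = "\n"),
                         identity)
}

#' Circular-substructure (Morgan-class) fingerprint
#'
#' Extended-connectivity fingerprint of the configured radius (default 3,
#' i.e. ECFP6-class environments), computed by OpenBabel via ChemmineOB and
#' folded by OR to `fp_bits` (default 2048). Deterministic and invariant to
#' input atom order.
#'
#' @param lig a `LigandInstance` or a SMILES string.
#' @param cfg a `ChemConfig`.
#' @return integer 0/1 vector of length `cfg$fp_bits`.
#' @export
morgan_fingerprint <- function(lig, cfg = chem_config()) {
  mol <- if (is.character(lig))
    ChemmineOB::forEachMol("SMILES", lig, identity)
  else .lig_to_obmol(lig)
  fp_name <- paste0("ECFP", 2L * cfg$fp_radius)
  raw <- tryCatch(ChemmineOB::fingerprint_OB(mol, fp_name),
                  error = function(e) stop("fingerprint failure: ",
                                           conditionMessage(e)))
  raw <- as.integer(raw != 0)
  n <- length(raw)
  if (n < cfg$fp_bits)
    stop("native fingerprint shorter than fp_bits")
  folds <- n / cfg$fp_bits
  out <- integer(cfg$fp_bits)
  for (f in seq_len(folds))
    out <- out | raw[((f - 1) * cfg$fp_bits + 1):(f * cfg$fp_bits)]
  as.integer(out)
}

#' Tanimoto distance between two bit vectors
#'
#' `1 - |a AND b| / |a OR b|`; two all-zero vectors have distance 0.
#'
#' @param a,b equal-length 0/1 vectors.
#' @return numeric in [0, 1].
#' @export
tanimoto_distance <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  u <- sum(a | b)
  if (u == 0) return(0)
  1 - sum(a & b) / u
}

#' Butina sphere-exclusion clustering
#'
#' Neighbors are pairs at Tanimoto distance <= 1 - similarity threshold
#' (similarity >= threshold joins a cluster). Iteratively, the unassigned
#' item with the most unassigned neighbors becomes a cluster centroid and
#' absorbs those neighbors; ties break to the lowest input index, and
#' members are listed centroid first, then by index. Every index appears in
#' exactly one cluster.
#'
#' @param fps list of equal-length 0/1 vectors (or a matrix, rows = items).
#' @param cfg a `ChemConfig` supplying the similarity threshold.
#' @return list of integer index vectors (the clusters), in formation order.
#' @export
butina_cluster <- function(fps, cfg = chem_config()) {
  if (is.matrix(fps)) fps <- lapply(seq_len(nrow(fps)), function(i) fps[i, ])
  n <- length(fps)
  if (n == 0) stop("need at least one fingerprint")
  dmax <- 1 - cfg$tanimoto_threshold
  X <- do.call(rbind, fps)
  inter <- tcrossprod(X)
  ones <- rowSums(X)
  uni <- outer(ones, ones, "+") - inter
  D <- 1 - inter / ifelse(uni == 0, 1, uni)
  D[uni == 0] <- 0
  nbr <- lapply(seq_len(n), function(i) setdiff(which(D[i, ] <= dmax), i))
  unassigned <- rep(TRUE, n)
  clusters <- list()
  while (any(unassigned)) {
    counts <- vapply(seq_len(n), function(i) {
      if (!unassigned[i]) return(-1L)
      sum(unassigned[nbr[[i]]])
    }, integer(1))
    centroid <- which.max(counts)   # ties: lowest index
    members <- sort(nbr[[centroid]][unassigned[nbr[[centroid]]]])
    cl <- c(centroid, members)
    unassigned[cl] <- FALSE
    clusters <- c(clusters, list(as.integer(cl)))
  }
  clusters
}

#' Shannon diversity index over cluster sizes
#'
#' `H = -sum(p_i log2 p_i)` with `p_i` the fraction of items in cluster i.
#' Maximal (`log2 S`) when all clusters are equal-sized; 0 for one cluster.
#'
#' @param cluster_sizes integer vector of positive sizes.
#' @return diversity in bits.
#' @export
shannon_index <- function(cluster_sizes) {
  if (length(cluster_sizes) == 0) stop("empty cluster size list")
  if (any(cluster_sizes < 1)) stop("cluster sizes must be >= 1")
  p <- cluster_sizes / sum(cluster_sizes)
  -sum(p * log2(p))
}

#' Full ligand-diversity report
#'
#' Fingerprints, Butina clustering and the Shannon index in one call.
#'
#' @param ligands list of `LigandInstance` or character vector of SMILES.
#' @param cfg a `ChemConfig`.
#' @return object of class `DiversityReport`: `n_ligands`, `n_clusters`,
#'   `cluster_sizes`, `shannon_bits`, `clusters`.
#' @export
diversity_report <- function(ligands, cfg = chem_config()) {
  fps <- lapply(ligands, morgan_fingerprint, cfg = cfg)
  clusters <- butina_cluster(fps, cfg)
  sizes <- lengths(clusters)
  structure(list(n_ligands = length(fps), n_clusters = length(clusters),
                 cluster_sizes = as.integer(sizes),
                 shannon_bits = shannon_index(sizes),
                 clusters = clusters),
            class = "DiversityReport")
}

#' @export
print.DiversityReport <- function(x, ...) {
  cat(sprintf("DiversityReport: %d ligands in %d clusters, H = %.2f bits (max %.2f)\n",
              x$n_ligands, x$n_clusters, x$shannon_bits, log2(x$n_ligands)))
  invisible(x)
}
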