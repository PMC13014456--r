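#' Pose set for one complex
#'
#' @param complex_id identifier.
#' @param poses list of coordinate matrices (n_heavy x 3), index 1 =
#'   top-ranked, all sharing the reference's heavy-atom count/connectivity.
#' @param reference a `LigandInstance` holding ground-truth coordinates.
#' @return object of class `PoseSet`.
#' @export
pose_set <- function(complex_id, poses, reference) {
  if (!length(poses)) stop("need at least one pose")
  nref <- nrow(heavy_coords(reference))
  for (p in poses)
    if (nrow(p) != nref) stop("pose atom count differs from reference")
  structure(list(complex_id = complex_id, poses = poses,
                 reference = reference),
            class = "PoseSet")
}

# Heavy-atom molecular graph automorphisms (element- and bond-order-
# preserving), as permutations of heavy-atom indices.
.heavy_automorphisms <- function(lig, cap = 1e5) {
  heavy <- which(lig$atoms$element != "H")
  n <- length(heavy)
  remap <- match(seq_len(nrow(lig$atoms)), heavy)
  b <- lig$bonds[lig$bonds$a1 %in% heavy & lig$bonds$a2 %in% heavy, ,
                 drop = FALSE]
  if (nrow(b) == 0) return(list(seq_len(n)))
  g <- igraph::graph_from_edgelist(cbind(remap[b$a1], remap[b$a2]),
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  vcol <- as.integer(factor(lig$atoms$element[heavy]))
  ecol <- as.integer(b$order)
  iso <- igraph::graph.get.isomorphisms.vf2(
    g, g, vertex.color1 = vcol, vertex.color2 = vcol,
    edge.color1 = ecol, edge.color2 = ecol)
  if (length(iso) > cap) {
    warning("automorphism count ", length(iso), " exceeds cap ", cap,
            "; falling back to identity mapping")
    return(list(seq_len(n)))
  }
  lapply(iso, as.integer)
}

#' Symmetry-corrected RMSD
#'
#' Minimum heavy-atom RMSD over all graph automorphisms of the reference
#' ligand (element- and bond-order-preserving relabelings), with no
#' re-superposition: coordinates are compared in place. A chemically
#' equivalent relabeling (e.g. a ring flip) therefore cannot inflate the
#' error.
#'
#' @param pose numeric matrix (n_heavy x 3) of predicted heavy-atom
#'   coordinates, in the reference's heavy-atom order.
#' @param reference a `LigandInstance` with bonds and ground-truth
#'   coordinates.
#' @param cap maximum number of automorphisms enumerated before falling
#'   back to the identity mapping (default 1e5).
#' @return RMSD in Angstrom.
#' @export
symmetry_corrected_rmsd <- function(pose, reference, cap = 1e5) {
  ref <- heavy_coords(reference)
  pose <- as.matrix(pose)
  if (nrow(pose) != nrow(ref) || ncol(pose) != 3)
    stop("pose must be an n x 3 matrix matching the reference heavy atoms")
  autos <- .heavy_automorphisms(reference, cap = cap)
  best <- Inf
  for (perm in autos) {
    r <- sqrt(mean(rowSums((pose[perm, , drop = FALSE] - ref)^2)))
    if (r < best) best <- r
  }
  best
}

#' Centroid distance
#'
#' Euclidean distance between the unweighted heavy-atom coordinate means of
#' pose and reference.
#'
#' @inheritParams symmetry_corrected_rmsd
#' @return distance in Angstrom.
#' @export
centroid_distance <- function(pose, reference) {
  ref <- heavy_coords(reference)
  pose <- as.matrix(pose)
  sqrt(sum((colMeans(pose) - colMeans(ref))^2))
}

#' Evaluate a pose set
#'
#' Top-1 metrics come from the first (top-ranked) pose; "best" metrics are
#' minima over all poses (the "Any" protocol over the generated samples).
#'
#' @param ps a `PoseSet`.
#' @param mode_label binding-mode label carried through to the record.
#' @return one-row data.frame (`EvalRecord`): `complex_id`, `rmsd_top1`,
#'   `rmsd_best`, `centroid_top1`, `centroid_best`, `mode_label`.
#' @export
evaluate_pose_set <- function(ps, mode_label = NA_character_) {
  rmsds <- vapply(ps$poses, symmetry_corrected_rmsd,
                  reference = ps$reference, numeric(1))
  cents <- vapply(ps$poses, centroid_distance,
                  reference = ps$reference, numeric(1))
  data.frame(complex_id = ps$complex_id,
             rmsd_top1 = rmsds[1], rmsd_best = min(rmsds),
             centroid_top1 = cents[1], centroid_best = min(cents),
             mode_label = mode_label, stringsAsFactors = FALSE)
}

#' Wilson score confidence interval
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param confidence confidence level (default 0.95).
#' @return named numeric `c(low, high)`.
#' @export
wilson_interval <- function(k, n, confidence = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- qnorm(1 - (1 - confidence) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Success-rate summary with Wilson interval
#'
#' A prediction is successful when the chosen metric is strictly below the
#' threshold (default 2 A).
#'
#' @param records data.frame of evaluation records (rows from
#'   [evaluate_pose_set()]), or a numeric vector of metric values.
#' @param metric one of `rmsd_top1`, `rmsd_best`, `centroid_top1`,
#'   `centroid_best` (ignored when `records` is numeric).
#' @param threshold success threshold in Angstrom (default 2).
#' @param confidence Wilson interval confidence level (default 0.95).
#' @return object of class `SuccessSummary`: `n`, `k_success`, `fraction`,
#'   `wilson_low`, `wilson_high`, `threshold`, `confidence`.
#' @export
success_summary <- function(records, metric = "rmsd_top1", threshold = 2,
                            confidence = 0.95) {
  values <- if (is.numeric(records)) records else {
    if (!metric %in% names(records)) stop("unknown metric: ", metric)
    records[[metric]]
  }
  n <- length(values)
  if (n == 0) stop("no evaluation records")
  k <- sum(values < threshold)
  ci <- wilson_interval(k, n, confidence)
  structure(list(n = n, k_success = k, fraction = k / n,
                 wilson_low = unname(ci["low"]),
                 wilson_high = unname(ci["high"]),
                 threshold = threshold, confidence = confidence),
            class = "SuccessSummary")
}

#' @export
print.SuccessSummary <- function(x, ...) {
  cat(sprintf("SuccessSummary: %d/%d = %.1f%% (< %g A), %.0f%% CI [%.1f%%, %.1f%%]\n",
              x$k_success, x$n, 100 * x$fraction, x$threshold,
              100 * x$confidence, 100 * x$wilson_low, 100 * x$wilson_high))
  invisible(x)
}

#' Compare two success rates
#'
#' Two-sided pooled two-proportion z-test (or Fisher's exact test);
#' significant when p < `alpha`.
#'
#' @param a,b `SuccessSummary` objects with matching thresholds.
#' @param alpha significance level (default 0.05).
#' @param method `"z"` (pooled z-test, default) or `"fisher"`.
#' @return list with `p_value`, `significant`, `z` (for the z-test).
#' @export
compare_success <- function(a, b, alpha = 0.05, method = c("z", "fisher")) {
  method <- match.arg(method)
  if (a$n == 0 || b$n == 0) stop("empty summary")
  if (!isTRUE(all.equal(a$threshold, b$threshold)))
    stop("summaries use different thresholds")
  if (method == "fisher") {
    p <- stats::fisher.test(matrix(c(a$k_success, a$n - a$k_success,
                                     b$k_success, b$n - b$k_success),
                                   nrow = 2))$p.value
    return(list(p_value = p, significant = p < alpha, z = NA_real_))
  }
  p1 <- a$k_success / a$n; p2 <- b$k_success / b$n
  pp <- (a$k_success + b$k_success) / (a$n + b$n)
  se <- sqrt(pp * (1 - pp) * (1 / a$n + 1 / b$n))
  if (se == 0) return(list(p_value = 1, significant = FALSE, z = 0))
  z <- (p1 - p2) / se
  p <- 2 * pnorm(-abs(z))
  list(p_value = p, significant = p < alpha, z = z)
}

# ---- cofolding pre-step: sequence alignment + Kabsch ------------------------

.receptor_sequence <- function(receptor, chain = NULL) {
  res <- receptor$residues
  if (!is.null(chain)) res <- res[res$chain == chain, , drop = FALSE]
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  letters1 <- .AA321[res$resid]
  letters1[is.na(letters1)] <- "X"
  list(seq = paste(letters1, collapse = ""), res = res)
}

.ca_coords <- function(receptor, res) {
  a <- receptor$atoms
  key <- paste(a$chain, a$resno, a$name)
  idx <- match(paste(res$chain, res$resno, "CA"), key)
  out <- as.matrix(a[idx, c("x", "y", "z")])
  rownames(out) <- NULL
  out
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Rotation is constrained to a proper rotation (determinant +1; no
#' reflection).
#'
#' @param P moving coordinate matrix (n x 3).
#' @param Q fixed coordinate matrix (n x 3).
#' @return list with `rotation` (3 x 3), `translation` (3-vector) such that
#'   `P %*% rotation + translation` superposes P onto Q, and `rmsd`.
#' @export
kabsch_superpose <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), nrow(P) >= 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t_vec <- cq - as.numeric(cp %*% R)
  moved <- sweep(P %*% R, 2, t_vec, "+")
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums((moved - Q)^2))))
}

#' Apply a rigid transform to coordinates or a ligand
#' @param x coordinate matrix (n x 3) or `LigandInstance`.
#' @param transform list with `rotation` and `translation` (e.g. from
#'   [align_and_superimpose()]).
#' @return transformed object of the same type.
#' @export
apply_transform <- function(x, transform) {
  if (inherits(x, "LigandInstance")) {
    xyz <- as.matrix(x$atoms[, c("x", "y", "z")])
    xyz <- sweep(xyz %*% transform$rotation, 2, transform$translation, "+")
    x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
    return(x)
  }
  sweep(as.matrix(x) %*% transform$rotation, 2, transform$translation, "+")
}

#' Align a predicted receptor onto a reference and superimpose
#'
#' Residue correspondence via global (Needleman-Wunsch) alignment of the
#' one-letter sequences (match +1, mismatch -1, linear gap -2), then
#' least-squares rigid superposition over all matched C-alpha pairs. The
#' returned transform maps predicted coordinates into the reference frame;
#' apply it to a predicted ligand (with [apply_transform()]) before metric
#' computation.
#'
#' @param predicted_receptor,reference_receptor `ReceptorStructure` objects.
#' @return list with `rotation`, `translation`, `ca_rmsd`, and `mapping`
#'   (data.frame of matched residue numbers per side).
#' @export
align_and_superimpose <- function(predicted_receptor, reference_receptor) {
  sp <- .receptor_sequence(predicted_receptor)
  sr <- .receptor_sequence(reference_receptor)
  letters <- unique(c(strsplit(sp$seq, "")[[1]], strsplit(sr$seq, "")[[1]]))
  sub <- matrix(-1, length(letters), length(letters),
                dimnames = list(letters, letters))
  diag(sub) <- 1
  aln <- Biostrings::pairwiseAlignment(sp$seq, sr$seq, type = "global",
                                       substitutionMatrix = sub,
                                       gapOpening = 0, gapExtension = 2)
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ip <- 0L; ir <- 0L
  map_p <- integer(0); map_r <- integer(0)
  for (pos in seq_along(ap)) {
    if (ap[pos] != "-") ip <- ip + 1L
    if (as_[pos] != "-") ir <- ir + 1L
    if (ap[pos] != "-" && as_[pos] != "-" && ap[pos] == as_[pos]) {
      map_p <- c(map_p, ip); map_r <- c(map_r, ir)
    }
  }
  P <- .ca_coords(predicted_receptor, sp$res[map_p, , drop = FALSE])
  Q <- .ca_coords(reference_receptor, sr$res[map_r, , drop = FALSE])
  ok <- stats::complete.cases(P) & stats::complete.cases(Q)
  if (sum(ok) < 3) stop("fewer than 3 matched C-alpha pairs")
  fit <- kabsch_superpose(P[ok, , drop = FALSE], Q[ok, , drop = FALSE])
  mapping <- data.frame(
    predicted_resno = sp$res$resno[map_p][ok],
    reference_resno = sr$res$resno[map_r][ok])
  list(rotation = fit$rotation, translation = fit$translation,
       ca_rmsd = fit$rmsd, mapping = mapping)
}
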