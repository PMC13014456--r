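#' Pocket-assignment classes
#'
#' ATP-competitive modes (I, I1/2F, I1/2B, II) are pooled as "orthosteric";
#' the allosteric modes III and IV keep their own centroids. The fixed order
#' also serves as the deterministic tie-break in [assign_pocket()].
#' @export
POCKET_CLASSES <- c("orthosteric", "III", "IV")

#' Collapse a binding-mode label to a pocket class
#' @param label character vector of [BINDING_MODES] labels.
#' @return character vector over [POCKET_CLASSES].
#' @export
mode_to_pocket_class <- function(label) {
  ifelse(label %in% c("III", "IV"), label, "orthosteric")
}

#' Fingerprint a ligand binding location
#'
#' The fingerprint is the 84-vector of minimum heavy-atom distances between
#' the ligand and each KLIFS residue of the region map, index-aligned to
#' `map$klifs_residues`. Unresolved residues are masked.
#'
#' @param receptor a `ReceptorStructure`.
#' @param ligand a `LigandInstance`.
#' @param map a `KinaseRegionMap`.
#' @return object of class `PocketFingerprint`: list with `values`
#'   (numeric 84, `NA` where masked) and `mask` (logical 84, TRUE = missing).
#' @export
fingerprint_pose <- function(receptor, ligand, map = default_region_map()) {
  lig_xyz <- heavy_coords(ligand)
  if (nrow(lig_xyz) == 0) stop("ligand has zero heavy atoms")
  ra <- receptor$atoms[receptor$atoms$element != "H", , drop = FALSE]
  values <- rep(NA_real_, 84)
  for (i in seq_len(84)) {
    sub <- ra[ra$resno == map$klifs_residues[i], , drop = FALSE]
    if (nrow(sub) == 0) next
    values[i] <- min(.cross_dist(lig_xyz, as.matrix(sub[, c("x", "y", "z")])))
  }
  mask <- is.na(values)
  if (all(mask)) stop("all 84 KLIFS residues unresolved in receptor")
  structure(list(values = values, mask = mask), class = "PocketFingerprint")
}

#' Construct a fingerprint from raw values
#' @param values numeric vector of length 84 (`NA` = masked).
#' @return a `PocketFingerprint`.
#' @export
pocket_fingerprint <- function(values) {
  values <- as.numeric(values)
  if (length(values) != 84) stop("fingerprint must have length 84")
  mask <- is.na(values)
  if (any(values[!mask] < 0)) stop("unmasked entries must be >= 0")
  structure(list(values = values, mask = mask), class = "PocketFingerprint")
}

.fp_matrix <- function(fingerprints) {
  t(vapply(fingerprints, function(fp) fp$values, numeric(84)))
}

#' Fit the PCA pocket embedding with per-class centroids
#'
#' PCA on mean-centred, unscaled fingerprints (all 84 features share
#' Angstrom units). The centroid of each pocket class is the mean of its
#' projected training points. When `n_per_class` is given, that many
#' fingerprints per class are sampled (seeded, without replacement) as the
#' PCA training subset, mirroring a 100/100/100 design.
#'
#' @param fingerprints list of `PocketFingerprint`.
#' @param labels character vector over [POCKET_CLASSES], one per fingerprint.
#' @param k number of components (default 2).
#' @param n_per_class optional per-class training subsample size.
#' @param seed integer seed used when subsampling.
#' @return object of class `EmbeddingModel`: `mean` (84), `components`
#'   (k x 84, orthonormal rows), `explained_variance_ratio` (k), `centroids`
#'   (named list of k-vectors).
#' @export
fit_embedding <- function(fingerprints, labels, k = 2, n_per_class = NULL,
                          seed = 1L) {
  stopifnot(length(fingerprints) == length(labels))
  labels <- as.character(labels)
  if (!all(labels %in% POCKET_CLASSES))
    stop("labels must be in {", paste(POCKET_CLASSES, collapse = ", "), "}")
  if (length(unique(labels)) < 2) stop("need at least 2 label classes")
  if (length(fingerprints) < k + 1) stop("need at least k+1 fingerprints")
  if (!is.null(n_per_class)) {
    set.seed(seed)
    keep <- unlist(lapply(POCKET_CLASSES, function(cl) {
      ix <- which(labels == cl)
      if (length(ix) < n_per_class)
        stop("class ", cl, " has ", length(ix), " < ", n_per_class,
             " fingerprints")
      sort(sample(ix, n_per_class))
    }))
    fingerprints <- fingerprints[keep]
    labels <- labels[keep]
  }
  X <- .fp_matrix(fingerprints)
  # impute masked entries with the column mean over available values
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[!nas, j])
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  total_var <- sum(pc$sdev^2)
  evr <- if (total_var > 0) pc$sdev[seq_len(k)]^2 / total_var else rep(0, k)
  proj <- pc$x[, seq_len(k), drop = FALSE]
  centroids <- lapply(split(seq_len(nrow(proj)), labels),
                      function(ix) colMeans(proj[ix, , drop = FALSE]))
  structure(list(mean = pc$center,
                 components = t(pc$rotation[, seq_len(k), drop = FALSE]),
                 explained_variance_ratio = evr,
                 centroids = centroids, k = k),
            class = "EmbeddingModel")
}

#' Project a fingerprint into the embedding
#' @param fp a `PocketFingerprint`.
#' @param model an `EmbeddingModel`.
#' @return numeric k-vector.
#' @export
project_fingerprint <- function(fp, model) {
  v <- fp$values
  v[fp$mask] <- model$mean[fp$mask]
  as.numeric(model$components %*% (v - model$mean))
}

#' Assign a pose to a pocket class by nearest centroid
#'
#' Masked entries are imputed with the training mean; the fingerprint is
#' projected and the Euclidean-nearest centroid wins. Exact ties break by
#' the fixed class order orthosteric < III < IV.
#'
#' @param fp a `PocketFingerprint`.
#' @param model an `EmbeddingModel`.
#' @return list with `label` and `projection`.
#' @export
assign_pocket <- function(fp, model) {
  z <- project_fingerprint(fp, model)
  classes <- intersect(POCKET_CLASSES, names(model$centroids))
  d <- vapply(classes, function(cl)
    sqrt(sum((z - model$centroids[[cl]])^2)), numeric(1))
  list(label = classes[which.min(d)], projection = z)
}

#' Serialize / deserialize an embedding model as JSON
#' @param model an `EmbeddingModel`.
#' @param path output (input) file path.
#' @return `path` invisibly (for write); an `EmbeddingModel` (for read).
#' @export
write_embedding_json <- function(model, path) {
  jsonlite::write_json(
    list(mean = model$mean, components = model$components,
         explained_variance_ratio = model$explained_variance_ratio,
         centroids = model$centroids, k = model$k),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_embedding_json
#' @export
read_embedding_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- raw$components
  if (!is.matrix(cm)) cm <- matrix(unlist(cm), nrow = raw$k, byrow = TRUE)
  structure(list(mean = as.numeric(raw$mean),
                 components = cm,
                 explained_variance_ratio = as.numeric(raw$explained_variance_ratio),
                 centroids = lapply(raw$centroids, as.numeric),
                 k = raw$k),
            class = "EmbeddingModel")
}

#' Write fingerprints as a CSV with 84 named columns
#' @param fingerprints list of `PocketFingerprint`.
#' @param path output path.
#' @param ids optional row identifiers.
#' @return `path`, invisibly.
#' @export
write_fingerprints_csv <- function(fingerprints, path, ids = NULL) {
  X <- .fp_matrix(fingerprints)
  colnames(X) <- paste0("klifs_", seq_len(84))
  df <- as.data.frame(X)
  if (!is.null(ids)) df <- cbind(id = ids, df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
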