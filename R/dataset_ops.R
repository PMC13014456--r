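#' Split configuration for dataset curation
#'
#' @param cutoff_date calendar date splitting train (strictly before) from
#'   post (on/after); default `"2019-01-01"`.
#' @param seed integer seed for stratified selection.
#' @param strata optional named integer vector, test count per mode.
#' @return object of class `SplitConfig`.
#' @export
split_config <- function(cutoff_date = "2019-01-01", seed = 1L,
                         strata = NULL) {
  cutoff <- as.Date(cutoff_date)
  if (is.na(cutoff)) stop("invalid cutoff date: ", cutoff_date)
  structure(list(cutoff_date = cutoff, seed = as.integer(seed),
                 strata = strata),
            class = "SplitConfig")
}

.entry_dates <- function(entries) {
  if (!"deposition_date" %in% names(entries))
    stop("entries need a deposition_date column")
  d <- as.Date(entries$deposition_date)
  bad <- which(is.na(d))
  if (length(bad))
    stop("missing/unparseable deposition date for entry ",
         paste(entries$structure_id[bad], collapse = ", "))
  d
}

#' Time-split a dataset by deposition date
#'
#' Entries deposited strictly before the cutoff go to `train`; entries on or
#' after the cutoff go to `post`. The two parts partition the input exactly.
#'
#' @param entries data.frame with at least `structure_id` and
#'   `deposition_date` columns.
#' @param cfg a `SplitConfig`.
#' @return list with data.frames `train` and `post`.
#' @export
time_split <- function(entries, cfg = split_config()) {
  if (nrow(entries) == 0) return(list(train = entries, post = entries))
  d <- .entry_dates(entries)
  list(train = entries[d < cfg$cutoff_date, , drop = FALSE],
       post = entries[d >= cfg$cutoff_date, , drop = FALSE])
}

#' Deduplicate entries by (UniProt ID, ligand name)
#'
#' Keeps the first occurrence in input order for each key; idempotent. Sort
#' inputs by date beforehand if the earliest structure should survive.
#'
#' @param entries data.frame with `uniprot_id` and `ligand_name` columns.
#' @return deduplicated data.frame.
#' @export
deduplicate <- function(entries) {
  if (nrow(entries) == 0) return(entries)
  key <- paste(entries$uniprot_id, entries$ligand_name, sep = "\r")
  entries[!duplicated(key), , drop = FALSE]
}

#' Stratified random selection by binding mode
#'
#' Samples the requested number of entries uniformly without replacement
#' within each mode (seeded, reproducible); everything not selected within a
#' requested mode lands in the remainder (available e.g. as a validation
#' set), as do all entries of unrequested modes.
#'
#' @param entries data.frame with a `mode_label` column.
#' @param per_mode_counts named integer vector, e.g. `c(III = 34, IV = 62)`.
#' @param seed integer seed.
#' @return list with data.frames `selected` and `remainder`.
#' @export
stratified_select <- function(entries, per_mode_counts, seed = 1L) {
  set.seed(seed)
  sel_idx <- integer(0)
  for (mode in names(per_mode_counts)) {
    ix <- which(entries$mode_label == mode)
    k <- per_mode_counts[[mode]]
    if (length(ix) < k)
      stop("stratum ", mode, " has ", length(ix), " < ", k, " entries")
    sel_idx <- c(sel_idx, sort(sample(ix, k)))
  }
  sel_idx <- sort(sel_idx)
  list(selected = entries[sel_idx, , drop = FALSE],
       remainder = entries[setdiff(seq_len(nrow(entries)), sel_idx), ,
                           drop = FALSE])
}

#' Bin a binding affinity
#'
#' On the -log(BA) scale: `weak` strictly below 4, `medium_strong` at or
#' above 6, `intermediate` between.
#'
#' @param neg_log_ba numeric vector of -log-transformed binding affinities.
#' @return character vector of bin labels.
#' @export
bin_affinity <- function(neg_log_ba) {
  stopifnot(all(is.finite(neg_log_ba)))
  ifelse(neg_log_ba < 4, "weak",
         ifelse(neg_log_ba >= 6, "medium_strong", "intermediate"))
}

#' Select near-native MD frames for training-set supersampling
#'
#' Frames qualify when their symmetry-corrected ligand RMSD to the reference
#' crystal pose is strictly below `rmsd_cutoff` (dissociated complexes and
#' binding-mode changes are thereby excluded); `n_select` qualifying frames
#' are then drawn uniformly without replacement (seeded). When fewer than
#' `n_select` qualify, all qualifying frames are returned with a warning.
#'
#' @param frames list of heavy-atom coordinate matrices sharing the
#'   reference topology.
#' @param reference a `LigandInstance` with crystal coordinates.
#' @param n_select frames to select (default 2, tripling a dataset when the
#'   original pose is kept alongside).
#' @param seed integer seed.
#' @param rmsd_cutoff qualification threshold in Angstrom (default 2).
#' @return list with `frames` (selected coordinate matrices), `indices`
#'   (into the input list) and `rmsd` (their RMSDs).
#' @export
md_frame_filter <- function(frames, reference, n_select = 2L, seed = 1L,
                            rmsd_cutoff = 2) {
  rmsds <- vapply(frames, symmetry_corrected_rmsd, reference = reference,
                  numeric(1))
  qual <- which(rmsds < rmsd_cutoff)
  if (length(qual) < n_select)
    warning("only ", length(qual), " of ", length(frames),
            " frames qualify (< ", rmsd_cutoff, " A); selecting all of them")
  set.seed(seed)
  take <- if (length(qual) <= n_select) qual
          else sort(sample(qual, n_select))
  list(frames = frames[take], indices = take, rmsd = rmsds[take])
}
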