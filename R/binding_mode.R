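#' Binding-mode labels
#'
#' The six Modi-Dunbrack binding modes: Type I (ATP-site, active
#' conformation), Type I1/2 front/back (back-pocket extenders), Type II
#' (DFG-out), Type III (alpha-C-out back pocket, non-ATP-competitive) and
#' Type IV (remote allosteric).
#' @export
BINDING_MODES <- c("I", "I12F", "I12B", "II", "III", "IV")

.REGIONS <- c("hinge", "back_pocket", "type2_pocket", "alphaC_nterm",
              "alphaC_glu_plus4")

#' Construct a kinase region map
#'
#' Named residue-number sets locating the functional regions used by the
#' binding-mode heuristics, plus the ordered 84 KLIFS residues used for
#' pocket fingerprinting.
#'
#' @param hinge,back_pocket,type2_pocket,alphaC_nterm,alphaC_glu_plus4
#'   integer vectors of residue numbers.
#' @param klifs_residues ordered integer vector of exactly 84 residue
#'   numbers, no duplicates.
#' @return object of class `KinaseRegionMap`.
#' @export
kinase_region_map <- function(hinge, back_pocket, type2_pocket,
                              alphaC_nterm, alphaC_glu_plus4,
                              klifs_residues) {
  klifs_residues <- as.integer(klifs_residues)
  if (length(klifs_residues) != 84 || anyDuplicated(klifs_residues))
    stop("klifs_residues must contain exactly 84 distinct residue numbers")
  for (nm in c("hinge", "back_pocket", "alphaC_nterm", "alphaC_glu_plus4")) {
    if (length(get(nm)) == 0) stop(nm, " residue set must be non-empty")
  }
  structure(list(hinge = as.integer(hinge),
                 back_pocket = as.integer(back_pocket),
                 type2_pocket = as.integer(type2_pocket),
                 alphaC_nterm = as.integer(alphaC_nterm),
                 alphaC_glu_plus4 = as.integer(alphaC_glu_plus4),
                 klifs_residues = klifs_residues),
            class = "KinaseRegionMap")
}

#' Default region map (Aurora A numbering)
#'
#' Hinge 211-213; back pocket 166-193, 196-204, 205-207 and 273-275 (the
#' alpha-C helix, parts of the beta4-beta5 strands, the X-DFG/DFG-Asp
#' backbone and the DFG-Phe side chain); Type-II-only pocket 184, 188, 247,
#' 254 (exposed in DFG-out structures). The alpha-C positions are anchored
#' at the Aurora A alpha-C glutamate (Glu181): Glu(+4) = 185, N-terminal
#' region 176-180. The 84 KLIFS-style fingerprint residues default to a
#' generic catalytic-cleft span; for real kinases supply the curated list
#' via [read_region_maps()].
#'
#' @return a `KinaseRegionMap`.
#' @export
default_region_map <- function() {
  kinase_region_map(
    hinge = 211:213,
    back_pocket = c(166:193, 196:204, 205:207, 273:275),
    type2_pocket = c(184L, 188L, 247L, 254L),
    alphaC_nterm = 176:180,
    alphaC_glu_plus4 = 185L,
    klifs_residues = c(142:193, 196:207, 211:225, 247L, 254L, 273:275))
}

#' Region thresholds for binding-mode classification
#'
#' @param contact_cutoff heavy-atom distance below which a residue counts as
#'   a contact (default 4.5 A).
#' @param type4_min_dist Type IV remoteness threshold on hinge and
#'   alpha-C-Glu(+4) distances (default 6.5 A).
#' @param type3_hinge_min_dist Type III hinge-distance threshold
#'   (default 6.0 A).
#' @param back_pocket_min_contacts back-pocket contact count shared by the
#'   I1/2, II and III rules (default 3).
#' @return object of class `RegionThresholds`.
#' @export
region_thresholds <- function(contact_cutoff = 4.5, type4_min_dist = 6.5,
                              type3_hinge_min_dist = 6.0,
                              back_pocket_min_contacts = 3L) {
  stopifnot(contact_cutoff > 0, type4_min_dist > 0,
            type3_hinge_min_dist > 0, back_pocket_min_contacts > 0)
  structure(list(contact_cutoff = contact_cutoff,
                 type4_min_dist = type4_min_dist,
                 type3_hinge_min_dist = type3_hinge_min_dist,
                 back_pocket_min_contacts = as.integer(back_pocket_min_contacts)),
            class = "RegionThresholds")
}

#' Region-resolved ligand contacts
#'
#' For each region in the map, computes the minimum heavy-atom distance
#' between the ligand and the region's resolved residues, and the number of
#' region residues whose minimum heavy-atom distance to the ligand is
#' strictly below the contact cutoff. Regions with no resolved residue get
#' `Inf` distance and zero contacts (a warning is raised, since a disordered
#' hinge weakens the Type IV call).
#'
#' @param receptor a `ReceptorStructure`.
#' @param ligand a `LigandInstance` with at least one heavy atom.
#' @param map a `KinaseRegionMap`.
#' @param thr a `RegionThresholds`.
#' @return object of class `ContactProfile`: list with `min_dist` and
#'   `contact_count`, each named by region.
#' @export
compute_contacts <- function(receptor, ligand, map = default_region_map(),
                             thr = region_thresholds()) {
  lig_xyz <- heavy_coords(ligand)
  if (nrow(lig_xyz) == 0) stop("ligand has zero heavy atoms")
  ra <- receptor$atoms[receptor$atoms$element != "H", , drop = FALSE]
  if (!any(unlist(map[.REGIONS]) %in% ra$resno))
    stop("no mapped residue present in receptor")
  min_dist <- setNames(rep(Inf, length(.REGIONS)), .REGIONS)
  contact_count <- setNames(integer(length(.REGIONS)), .REGIONS)
  for (rg in .REGIONS) {
    resnos <- intersect(map[[rg]], unique(ra$resno))
    if (length(resnos) == 0) {
      warning("region '", rg, "' has no resolved residues; using Inf")
      next
    }
    sub <- ra[ra$resno %in% resnos, , drop = FALSE]
    d <- .cross_dist(lig_xyz, as.matrix(sub[, c("x", "y", "z")]))
    per_res <- vapply(split(seq_len(nrow(sub)), sub$resno),
                      function(ix) min(d[, ix]), numeric(1))
    min_dist[rg] <- min(per_res)
    contact_count[rg] <- sum(per_res < thr$contact_cutoff)
  }
  structure(list(min_dist = min_dist, contact_count = contact_count,
                 contact_cutoff = thr$contact_cutoff),
            class = "ContactProfile")
}

#' Classify a contact profile into a binding mode
#'
#' Applies the geometric heuristics in a fixed precedence order
#' IV -> II -> III -> I1/2-front -> I1/2-back -> I:
#' \itemize{
#'   \item Type IV: hinge and alpha-C-Glu(+4) minimum distances both
#'     > 6.5 A (remote allosteric).
#'   \item Type II: >= 3 back-pocket contacts and >= 1 Type-II-only pocket
#'     contact (DFG-out).
#'   \item Type III: hinge minimum distance > 6 A and >= 3 back-pocket
#'     contacts (alpha-C-out trapping, non-ATP-competitive).
#'   \item Type I1/2 front/back: >= 3 back-pocket contacts with/without an
#'     alpha-C N-terminal contact.
#'   \item Type I: everything else (ATP-site, active conformation).
#' }
#' Type-II-pocket contact is the more specific structural evidence, so II
#' precedes III; III precedes I1/2 because its hinge condition is strictly
#' more restrictive.
#'
#' @param profile a `ContactProfile`.
#' @param thr a `RegionThresholds`.
#' @return single character label, one of [BINDING_MODES].
#' @export
classify_binding_mode <- function(profile, thr = region_thresholds()) {
  md <- profile$min_dist; cc <- profile$contact_count
  missing <- setdiff(.REGIONS, intersect(names(md), names(cc)))
  if (length(missing))
    stop("profile missing region(s): ", paste(missing, collapse = ", "))
  nb <- thr$back_pocket_min_contacts
  if (md[["hinge"]] > thr$type4_min_dist &&
      md[["alphaC_glu_plus4"]] > thr$type4_min_dist) return("IV")
  if (cc[["back_pocket"]] >= nb && cc[["type2_pocket"]] >= 1) return("II")
  if (md[["hinge"]] > thr$type3_hinge_min_dist &&
      cc[["back_pocket"]] >= nb) return("III")
  if (cc[["back_pocket"]] >= nb && cc[["alphaC_nterm"]] >= 1) return("I12F")
  if (cc[["back_pocket"]] >= nb) return("I12B")
  "I"
}

#' Annotate one receptor/ligand pair
#'
#' Convenience wrapper: contacts plus classification, flattened to one row.
#'
#' @inheritParams compute_contacts
#' @return one-row data.frame with label and per-region distances/counts.
#' @export
annotate_complex <- function(receptor, ligand, map = default_region_map(),
                             thr = region_thresholds()) {
  prof <- compute_contacts(receptor, ligand, map, thr)
  label <- classify_binding_mode(prof, thr)
  out <- data.frame(structure_id = receptor$structure_id,
                    comp_id = ligand$comp_id, label = label,
                    stringsAsFactors = FALSE)
  for (rg in .REGIONS) {
    out[[paste0("min_dist_", rg)]] <- unname(prof$min_dist[rg])
    out[[paste0("contacts_", rg)]] <- unname(prof$contact_count[rg])
  }
  out
}

#' Read per-kinase region maps from a table
#'
#' Accepts CSV (columns `kinase_id`, `region`, `residues`; residues
#' semicolon- or space-separated, ranges like `166-193` allowed) or JSON
#' (object keyed by kinase id, each with one array per region).
#'
#' @param path CSV or JSON file path.
#' @return named list of `KinaseRegionMap`.
#' @export
read_region_maps <- function(path) {
  parse_res <- function(x) {
    tok <- unlist(strsplit(as.character(x), "[;, ]+"))
    tok <- tok[nzchar(tok)]
    unlist(lapply(tok, function(t) {
      if (grepl("-", t, fixed = TRUE)) {
        ab <- as.integer(strsplit(t, "-", fixed = TRUE)[[1]])
        seq(ab[1], ab[2])
      } else as.integer(t)
    }))
  }
  fields <- c(.REGIONS, "klifs_residues")
  if (tolower(tools::file_ext(path)) == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    maps <- lapply(raw, function(m) {
      do.call(kinase_region_map, lapply(setNames(fields, fields),
                                        function(f) parse_res(m[[f]])))
    })
    return(maps)
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  maps <- lapply(split(tab, tab$kinase_id), function(sub) {
    args <- lapply(setNames(fields, fields), function(f)
      parse_res(sub$residues[sub$region == f]))
    do.call(kinase_region_map, args)
  })
  maps
}
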