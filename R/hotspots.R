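ENSEMBLE_CATEGORIES <- c("covalent", "strong_noncovalent", "weak", "unspecified")

#' One complex of the recognition ensemble
#'
#' Records which receptor residues are interface contacts in one complex and
#' how the interaction was categorised experimentally (covalent = released by
#' DTT, i.e. disulfide linked; strong non-covalent = released by acid
#' elution; weak = e.g. yeast two-hybrid evidence). A complex may carry
#' several categories (a ligand can bind both covalently and non-covalently).
#'
#' @param complex_id,ligand_id identifiers.
#' @param category character vector, subset of `covalent`,
#'   `strong_noncovalent`, `weak`, `unspecified`.
#' @param contacts integer vector of receptor contact-residue numbers (may be
#'   empty).
#' @return an `ensemble_record`.
#' @export
ensemble_record <- function(complex_id, ligand_id = complex_id,
                            category = "unspecified", contacts = integer(0)) {
  bad <- setdiff(category, ENSEMBLE_CATEGORIES)
  if (length(bad)) stopf("unknown category label(s): %s",
                         paste(bad, collapse = ", "))
  structure(list(complex_id = complex_id, ligand_id = ligand_id,
                 category = category,
                 contacts = sort(unique(as.integer(contacts)))),
            class = "ensemble_record")
}

#' Per-residue contact frequencies across a complex ensemble
#'
#' A residue scores one hit per complex in which it appears as a contact
#' (per-complex presence, not per-atom-pair multiplicity); its percentage in
#' a category is 100 x hits / total hits of all residues in that category.
#' The `all` category pools every record regardless of its labels.
#'
#' @param records list of [ensemble_record()]s.
#' @param categories categories to tabulate (plus `all`).
#' @param count_mode `"presence"` (default) or `"pairs"`; with `"pairs"`, a
#'   record's `contacts` may contain repeats and each repeat counts.
#' @return a `contact_frequency_table` data frame: one row per residue,
#'   columns `hits_<cat>` and `pct_<cat>`.
#' @export
aggregate_contacts <- function(records,
                               categories = c(ENSEMBLE_CATEGORIES, "all"),
                               count_mode = c("presence", "pairs")) {
  count_mode <- match.arg(count_mode)
  if (!length(records)) stopf("need at least one ensemble record")
  bad <- setdiff(setdiff(categories, "all"), ENSEMBLE_CATEGORIES)
  if (length(bad)) stopf("unknown category label(s): %s",
                         paste(bad, collapse = ", "))
  universe <- sort(unique(unlist(lapply(records, `[[`, "contacts"))))
  out <- data.frame(residue = universe)
  for (cat in categories) {
    hits <- setNames(numeric(length(universe)), universe)
    for (rec in records) {
      if (cat != "all" && !(cat %in% rec$category)) next
      ct <- rec$contacts
      if (count_mode == "presence") ct <- unique(ct)
      tab <- table(ct)
      hits[names(tab)] <- hits[names(tab)] + as.numeric(tab)
    }
    tot <- sum(hits)
    out[[paste0("hits_", cat)]] <- as.numeric(hits)
    out[[paste0("pct_", cat)]] <- if (tot > 0) 100 * hits / tot else 0 * hits
  }
  class(out) <- c("contact_frequency_table", class(out))
  out
}

#' Call statistical contact hot spots from a frequency table
#'
#' Either residues whose percentage exceeds `percent_threshold` (strict
#' inequality; 1% by default, i.e. just above the uniform share when about a
#' hundred residues participate), or the top `top_fraction` of contact-bearing
#' residues by percentage with ties kept. Exactly one mode is active.
#' Ordering is deterministic: percentage descending, residue number ascending.
#'
#' @param table a `contact_frequency_table`.
#' @param category category column to use.
#' @param percent_threshold percentage threshold (default 1.0).
#' @param top_fraction optional fraction (e.g. 0.15); when given, overrides
#'   the threshold mode.
#' @return integer vector of hot-spot residues, ordered as above.
#' @export
call_hotspots <- function(table, category = "all", percent_threshold = 1.0,
                          top_fraction = NULL) {
  col <- paste0("pct_", category)
  if (!col %in% names(table)) stopf("category '%s' not in table", category)
  pct <- table[[col]]
  if (!any(pct > 0)) stopf("category '%s' has no hits", category)
  keep <- pct > 0
  ord <- order(-pct[keep], table$residue[keep])
  resid <- table$residue[keep][ord]
  pcts <- pct[keep][ord]
  if (is.null(top_fraction)) {
    resid[pcts > percent_threshold]
  } else {
    k <- ceiling(top_fraction * length(resid))
    if (k < 1) return(integer(0))
    cut <- pcts[k]
    resid[pcts >= cut]
  }
}

#' Partition two residue sets into exclusive and common regions
#'
#' Classic two-set Venn arithmetic over residue numbers: residues only in the
#' covalent set, only in the strong non-covalent set, and common to both.
#'
#' @param covalent_set,snc_set integer vectors (residue numbers).
#' @return list with sorted `only_C`, `only_sNC`, `common`.
#' @export
venn_partition <- function(covalent_set, snc_set) {
  covalent_set <- unique(as.integer(covalent_set))
  snc_set <- unique(as.integer(snc_set))
  list(only_C = sort(setdiff(covalent_set, snc_set)),
       only_sNC = sort(setdiff(snc_set, covalent_set)),
       common = sort(intersect(covalent_set, snc_set)))
}

#' Count ligand fingerprints over hot-spot positions
#'
#' How many distinct subsets of size `r_per_ligand` can be drawn from
#' `n_hotspot_positions` available hot-spot positions; delegates to
#' [combinations()].
#'
#' @param n_hotspot_positions,r_per_ligand non-negative integers.
#' @return exact binomial coefficient.
#' @export
hotspot_combination_count <- function(n_hotspot_positions, r_per_ligand) {
  combinations(n_hotspot_positions, r_per_ligand)
}

#' Merge adjacent identical residues into single binding points
#'
#' Residues of the same amino-acid type within `max_gap` sequence positions
#' of each other (e.g. two Asp at positions 94 and 96) can be regarded as a
#' single charged binding point; each run is represented by its lowest
#' residue number. Off by default in all callers.
#'
#' @param residues integer vector of residue numbers.
#' @param resn character vector of 3-letter names, parallel to `residues`.
#' @param max_gap maximum numbering gap inside a merged run (default 2).
#' @return integer vector of representative residues.
#' @export
merge_adjacent_identical <- function(residues, resn, max_gap = 2) {
  stopifnot(length(residues) == length(resn))
  ord <- order(residues)
  residues <- residues[ord]; resn <- resn[ord]
  rep_of <- integer(0)
  i <- 1
  while (i <= length(residues)) {
    j <- i
    while (j < length(residues) && resn[j + 1] == resn[i] &&
           residues[j + 1] - residues[j] <= max_gap) j <- j + 1
    rep_of <- c(rep_of, residues[i])
    i <- j + 1
  }
  rep_of
}
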