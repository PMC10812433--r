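#' Assemble per-category contact areas from hot spots and energy neighbours
#'
#' Each hot-spot set is expanded by its direct energy-network neighbours
#' (seeds included), and the two expanded sets are partitioned by
#' [venn_partition()] into regions used only covalently, only strong
#' non-covalently, or by both; remaining residues get label `none`. Every
#' labelled residue carries a provenance: `hotspot` if it is itself a hot
#' spot, else `energy_neighbor`.
#'
#' @param hotspots_C,hotspots_sNC integer residue sets (must lie on the
#'   network).
#' @param energy_network a `residue_network` of kind `"energy"`.
#' @return a `contact_area_map` data frame over all network residues:
#'   `residue`, `label` in only_C / only_sNC / common / none, `provenance`.
#' @export
assemble_areas <- function(hotspots_C, hotspots_sNC, energy_network) {
  expand <- function(seeds) {
    if (!length(seeds)) return(integer(0))
    energy_neighbors(energy_network, seeds, include_seeds = TRUE)
  }
  exp_C <- expand(hotspots_C)
  exp_sNC <- expand(hotspots_sNC)
  part <- venn_partition(exp_C, exp_sNC)

  residues <- sort(unique(energy_network$nodes$res_seq))
  label <- rep("none", length(residues))
  label[residues %in% part$only_C] <- "only_C"
  label[residues %in% part$only_sNC] <- "only_sNC"
  label[residues %in% part$common] <- "common"
  hot <- residues %in% union(hotspots_C, hotspots_sNC)
  provenance <- rep(NA_character_, length(residues))
  provenance[label != "none"] <- ifelse(hot[label != "none"],
                                        "hotspot", "energy_neighbor")
  out <- data.frame(residue = residues, label = label,
                    provenance = provenance, stringsAsFactors = FALSE)
  attr(out, "expanded") <- list(C = exp_C, sNC = exp_sNC)
  class(out) <- c("contact_area_map", class(out))
  out
}

#' Spatial contiguity of contact areas on a contact network
#'
#' Descriptive extra: for each area label, the sizes of the connected
#' components its residues induce on a C-alpha contact network. Not a filter.
#'
#' @param area_map a `contact_area_map`.
#' @param contact_network a `residue_network` of kind `"contact"`.
#' @return named list of integer component-size vectors per label.
#' @export
area_contiguity <- function(area_map, contact_network) {
  out <- list()
  for (lab in c("only_C", "only_sNC", "common")) {
    res <- area_map$residue[area_map$label == lab]
    if (!length(res)) { out[[lab]] <- integer(0); next }
    idx <- which(contact_network$nodes$res_seq %in% res)
    sub <- igraph::induced_subgraph(contact_network$graph, idx)
    out[[lab]] <- sort(igraph::components(sub)$csize, decreasing = TRUE)
  }
  out
}
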