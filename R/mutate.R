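#' In-silico alanine mutation by side-chain truncation
#'
#' Replaces the target residue by alanine, keeping only its N, CA, C, O and CB
#' atoms (plus backbone hydrogens if present). Glycine is renamed without
#' constructing a CB; alanine targets are a no-op. Coordinates of retained
#' atoms are never modified and the input model is left untouched.
#'
#' @param model a `structure_model`.
#' @param chain_id chain of the target residue.
#' @param res_seq author residue number of the target.
#' @param icode insertion code (default blank).
#' @return a new `structure_model` with the truncated residue.
#' @export
truncate_to_ala <- function(model, chain_id, res_seq, icode = "") {
  stopifnot(inherits(model, "structure_model"))
  key <- res_key(chain_id, res_seq, icode)
  hit <- res_key_df(model$atoms) == key
  if (!any(hit)) stopf("residue %s %d%s not found", chain_id, res_seq, icode)
  keep_names <- c("N", "CA", "C", "O", "CB", "OXT", "H", "HA", "H1", "H2", "H3")
  drop <- hit & !(model$atoms$atom %in% keep_names)
  atoms <- model$atoms[!drop, , drop = FALSE]
  atoms$resn[res_key_df(atoms) == key] <- "ALA"
  m <- new_structure_model(atoms, model$model_id)
  # carry over class annotations; the mutated residue is re-classed lazily
  old <- model$residues
  idx <- match(res_key_df(m$residues), res_key_df(old))
  m$residues$charge_class <- old$charge_class[idx]
  m$residues$hydropathy_class <- old$hydropathy_class[idx]
  if (!all(is.na(old$charge_class))) {
    tgt <- res_key_df(m$residues) == key
    m$residues$charge_class[tgt] <- unname(default_charge_classes()["ALA"])
    m$residues$hydropathy_class[tgt] <- unname(default_hydropathy_classes()["ALA"])
  }
  m
}
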