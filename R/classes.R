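AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

three_to_one <- function(resn) {
  out <- AA1[match(toupper(resn), AA3)]
  out[is.na(out)] <- "X"
  out
}

#' Default residue charge-class table for the IC/NIS bookkeeping
#'
#' Charged: Asp, Glu, Lys, Arg, His. Polar: Asn, Gln, Ser, Thr, Tyr. Apolar:
#' the rest (Ala, Cys, Phe, Gly, Ile, Leu, Met, Pro, Val, Trp). The charged
#' list is fixed by the affinity model; the polar/apolar split is the
#' conventional one and can be overridden wholesale.
#'
#' @return named character vector mapping 3-letter residue names to one of
#'   `"charged"`, `"polar"`, `"apolar"`.
#' @export
default_charge_classes <- function() {
  cls <- setNames(rep("apolar", length(AA3)), AA3)
  cls[c("ASP", "GLU", "LYS", "ARG", "HIS")] <- "charged"
  cls[c("ASN", "GLN", "SER", "THR", "TYR")] <- "polar"
  cls
}

#' Default hydropathy-class table for residue subnetworks
#'
#' Charged: Glu, Lys, Asp, Arg, His. Hydrophobic: Ala, Ile, Leu, Val, Met,
#' Phe, Pro, Trp. Hydrophilic: Ser, Thr, Tyr, Cys, Gln, Asn. Gly (and any
#' non-standard residue) gets class `"none"` and never joins a subnetwork.
#'
#' @return named character vector over the 20 standard residues.
#' @export
default_hydropathy_classes <- function() {
  cls <- setNames(rep("none", length(AA3)), AA3)
  cls[c("GLU", "LYS", "ASP", "ARG", "HIS")] <- "charged"
  cls[c("ALA", "ILE", "LEU", "VAL", "MET", "PHE", "PRO", "TRP")] <- "hydrophobic"
  cls[c("SER", "THR", "TYR", "CYS", "GLN", "ASN")] <- "hydrophilic"
  cls
}

check_class_table <- function(tbl, what) {
  if (is.null(names(tbl)) || any(!nzchar(names(tbl))))
    stopf("%s table must be a named character vector", what)
  if (anyDuplicated(names(tbl)))
    stopf("%s table assigns a residue to two classes: %s", what,
          paste(unique(names(tbl)[duplicated(names(tbl))]), collapse = ", "))
  tbl
}

#' Annotate every residue of a model with charge and hydropathy classes
#'
#' The charge class (charged/polar/apolar) feeds the IC/NIS affinity model;
#' the hydropathy class (charged/hydrophobic/hydrophilic/none) feeds the
#' residue-subnetwork analysis. Non-standard residues fall back to apolar /
#' none with a warning.
#'
#' @param model a `structure_model`.
#' @param charge_table,hydropathy_table optional named-vector overrides
#'   (3-letter residue name to class label).
#' @return the model with `charge_class` and `hydropathy_class` columns filled
#'   in its residue table.
#' @export
assign_residue_classes <- function(model,
                                   charge_table = default_charge_classes(),
                                   hydropathy_table = default_hydropathy_classes()) {
  stopifnot(inherits(model, "structure_model"))
  charge_table <- check_class_table(charge_table, "charge class")
  hydropathy_table <- check_class_table(hydropathy_table, "hydropathy class")
  res <- model$residues
  cc <- unname(charge_table[res$resn])
  hc <- unname(hydropathy_table[res$resn])
  unknown <- unique(res$resn[is.na(cc) | is.na(hc)])
  if (length(unknown))
    warnf("non-standard residues %s assigned apolar/none",
          paste(unknown, collapse = ", "))
  cc[is.na(cc)] <- "apolar"
  hc[is.na(hc)] <- "none"
  model$residues$charge_class <- cc
  model$residues$hydropathy_class <- hc
  model
}
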