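#' Mutation effect on binding free energy
#'
#' The scanning convention reports `ddG = dG_wt - dG_mut`, so a mutation that
#' weakens binding (mutant dG less negative) gives a negative ddG. A residue
#' is a thermodynamic hot spot when alanine replacement changes the
#' interaction energy by more than `threshold` kcal/mol in either direction.
#'
#' @param dg_wt,dg_mut wild-type and mutant binding free energies (kcal/mol).
#' @return `ddG`: the difference in kcal/mol.
#' @export
ddG <- function(dg_wt, dg_mut) dg_wt - dg_mut

#' @rdname ddG
#' @param ddg a ddG value (kcal/mol).
#' @param threshold hot-spot threshold in kcal/mol (default 2).
#' @return `is_thermo_hotspot`: logical.
#' @export
is_thermo_hotspot <- function(ddg, threshold = 2.0) abs(ddg) > threshold

#' Alanine scanning of receptor interface residues
#'
#' Each target residue (or joint set of residues, for multiple mutants) is
#' truncated to alanine, the interface contact profile is recomputed on the
#' mutated complex, and the IC/NIS model is re-evaluated. Truncation may flip
#' the residue's charge class (e.g. Lys to Ala turns charged into apolar),
#' which changes both the IC classing and the NIS composition; both effects
#' are deliberately included, since the scan reruns the full profile.
#'
#' @param complex a `structure_model` with charge classes assigned.
#' @param receptor_chains,ligand_chains the two sides.
#' @param residues `"all-interface"` to scan every receptor contact residue
#'   singly, or a list whose elements are integer vectors of residue numbers
#'   (a length-2 element makes a double mutant).
#' @param chain chain carrying the targets (default: first receptor chain).
#' @param coeffs [binding_coefficients()].
#' @param contact_cutoff heavy-atom contact cutoff (A).
#' @param sasa_cfg list of [compute_sasa()] settings.
#' @param temperature K, for the mutant dissociation constant.
#' @param threshold thermodynamic hot-spot threshold (kcal/mol).
#' @return data frame with one row per mutant: `mutant` label, `dg_wt`,
#'   `dg_mut`, `ddg`, `kd_mut` (mol/L) and `thermo_hotspot`.
#' @export
ala_scan <- function(complex, receptor_chains, ligand_chains,
                     residues = "all-interface",
                     chain = receptor_chains[1],
                     coeffs = binding_coefficients(),
                     contact_cutoff = 5.5, sasa_cfg = list(),
                     temperature = 298.15, threshold = 2.0) {
  prof_wt <- contact_profile(complex, receptor_chains, ligand_chains,
                             contact_cutoff, sasa_cfg)
  dg_wt <- predict_dG(prof_wt, coeffs)

  if (identical(residues, "all-interface")) {
    tgt <- prof_wt$contact_residues_receptor
    residues <- lapply(seq_len(nrow(tgt)), function(i) tgt$res_seq[i])
    chains <- lapply(seq_len(nrow(tgt)), function(i) tgt$chain[i])
  } else {
    if (!is.list(residues)) residues <- as.list(residues)
    chains <- lapply(residues, function(r) rep(chain, length(r)))
  }

  res_tab <- complex$residues
  rows <- lapply(seq_along(residues), function(i) {
    rs <- residues[[i]]; chs <- chains[[i]]
    mut <- complex
    labs <- character(length(rs))
    for (j in seq_along(rs)) {
      hit <- res_tab$chain == chs[j] & res_tab$res_seq == rs[j]
      if (!any(hit)) stopf("residue %s %d not found on receptor side",
                           chs[j], rs[j])
      if (!res_tab$chain[hit][1] %in% receptor_chains)
        stopf("residue %s %d is not on the receptor side", chs[j], rs[j])
      labs[j] <- sprintf("%s%dA", three_to_one(res_tab$resn[hit][1]), rs[j])
      mut <- truncate_to_ala(mut, chs[j], rs[j])
    }
    prof_mut <- contact_profile(mut, receptor_chains, ligand_chains,
                                contact_cutoff, sasa_cfg)
    dg_mut <- predict_dG(prof_mut, coeffs)
    data.frame(mutant = paste(labs, collapse = " "),
               dg_wt = dg_wt, dg_mut = dg_mut,
               ddg = ddG(dg_wt, dg_mut),
               kd_mut = dG_to_KD(dg_mut, temperature),
               thermo_hotspot = is_thermo_hotspot(ddG(dg_wt, dg_mut), threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
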