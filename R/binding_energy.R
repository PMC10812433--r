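#' Gas constant in kcal K^-1 mol^-1
#' @export
R_KCAL <- 0.0019872

#' Coefficients of the contact-based binding-affinity model
#'
#' The linear IC/NIS model combines four interfacial-contact counts
#' (charged/charged, charged/apolar, polar/polar, polar/apolar) and two
#' non-interacting-surface percentages (apolar, charged) with an intercept.
#' With the published magnitudes taken verbatim, realistic inputs (NIS
#' percentages in the tens) give a positive right-hand side, whereas the
#' model is reported with uniformly negative binding energies; the default
#' `sign_convention = "negated"` therefore multiplies the whole right-hand
#' side by -1, and `"as_printed"` is retained for audit.
#'
#' @param w_cc,w_ca,w_pp,w_pa kcal/mol per contact (signed as printed).
#' @param w_nis_apolar,w_nis_charged kcal/mol per NIS percentage point.
#' @param intercept kcal/mol.
#' @param sign_convention `"negated"` (default) or `"as_printed"`.
#' @return a `binding_model_coefficients` list.
#' @export
binding_coefficients <- function(w_cc = 0.09459, w_ca = 0.10007,
                                 w_pp = -0.19577, w_pa = 0.22671,
                                 w_nis_apolar = -0.18681,
                                 w_nis_charged = -0.13810,
                                 intercept = 15.9433,
                                 sign_convention = c("negated", "as_printed")) {
  sign_convention <- match.arg(sign_convention)
  structure(list(w_cc = w_cc, w_ca = w_ca, w_pp = w_pp, w_pa = w_pa,
                 w_nis_apolar = w_nis_apolar, w_nis_charged = w_nis_charged,
                 intercept = intercept, sign_convention = sign_convention),
            class = "binding_model_coefficients")
}

#' Predict binding free energy from an interface contact profile
#'
#' Linear combination of the charged/charged, charged/apolar, polar/polar and
#' polar/apolar IC counts and the apolar and charged %NIS values plus an
#' intercept, under the active sign convention (see
#' [binding_coefficients()]).
#'
#' @param profile an `interface_contact_profile` (or a bare list with
#'   `ic_counts` and `nis_percent` in the same layout).
#' @param coeffs model coefficients.
#' @return predicted Delta G in kcal/mol.
#' @export
predict_dG <- function(profile, coeffs = binding_coefficients()) {
  ic <- profile$ic_counts
  nis <- profile$nis_percent
  rhs <- coeffs$w_cc * ic[["charged_charged"]] +
    coeffs$w_ca * ic[["charged_apolar"]] +
    coeffs$w_pp * ic[["polar_polar"]] +
    coeffs$w_pa * ic[["polar_apolar"]] +
    coeffs$w_nis_apolar * nis[["apolar"]] +
    coeffs$w_nis_charged * nis[["charged"]] +
    coeffs$intercept
  if (coeffs$sign_convention == "negated") -rhs else rhs
}

#' Convert binding free energy to a dissociation constant (and back)
#'
#' `Delta G = R T ln K_D` with R = 0.0019872 kcal K^-1 mol^-1, evaluated at
#' room temperature (298.15 K) unless stated otherwise. The two functions are
#' exact inverses.
#'
#' @param delta_g binding free energy in kcal/mol.
#' @param temperature absolute temperature in K.
#' @return `dG_to_KD`: dissociation constant in mol/L.
#' @export
dG_to_KD <- function(delta_g, temperature = 298.15) {
  stopifnot(temperature > 0)
  exp(delta_g / (R_KCAL * temperature))
}

#' @rdname dG_to_KD
#' @param k_d dissociation constant in mol/L (must be > 0).
#' @return `KD_to_dG`: free energy in kcal/mol.
#' @export
KD_to_dG <- function(k_d, temperature = 298.15) {
  stopifnot(temperature > 0, all(k_d > 0))
  R_KCAL * temperature * log(k_d)
}

#' Exact binomial coefficient C(n, r)
#'
#' Exact integer arithmetic via incremental products; used to count how many
#' distinct ligand "fingerprints" a set of hot-spot positions can host.
#'
#' @param n,r non-negative integers with `r <= n`.
#' @return the binomial coefficient as a (double-stored) exact integer.
#' @export
combinations <- function(n, r) {
  stopifnot(length(n) == 1, length(r) == 1, n >= 0, r >= 0, n == round(n),
            r == round(r))
  if (r > n) stopf("r (%d) exceeds n (%d)", r, n)
  r <- min(r, n - r)
  out <- 1
  for (k in seq_len(r)) out <- out * (n - r + k) / k
  round(out)
}
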