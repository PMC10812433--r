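VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
DEFAULT_VDW <- 1.70

# theoretical per-residue maximum accessible areas (A^2), Gly-X-Gly based
MAX_SASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
              GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
              LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
              SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

# deterministic quasi-uniform sphere points (golden-spiral lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(elements) {
  r <- VDW_RADII[elements]
  r[is.na(r)] <- DEFAULT_VDW
  unname(r)
}

#' Solvent-accessible surface area by Shrake-Rupley sphere sampling
#'
#' Heavy atoms only (hydrogens ignored). Deterministic for a fixed `n_points`
#' because the sampling lattice is a fixed golden-spiral point set. Relative
#' SASA divides each residue's absolute area by a tabulated theoretical
#' maximum for its type; it may exceed 1 for extended termini. A residue is
#' flagged as surface when its relative SASA reaches `surface_threshold`.
#'
#' @param model a `structure_model` with at least one heavy atom.
#' @param probe_radius solvent probe radius in Angstrom (water: 1.4).
#' @param n_points sampling points per atom sphere (960 gives ~1% accuracy).
#' @param surface_threshold relative-SASA cutoff for the surface flag.
#' @return a `sasa_result`: per-residue data frame with `abs_sasa` (A^2),
#'   `rel_sasa` and `surface`; per-atom areas in `attr(, "atom_sasa")`.
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_points = 960,
                         surface_threshold = 0.25) {
  stopifnot(inherits(model, "structure_model"))
  at <- heavy_atoms(model)
  if (!nrow(at)) stopf("model has no heavy atoms")
  xyz <- atom_coords(at)
  rad <- atom_radii(at$element) + probe_radius
  pts <- sphere_points(n_points)
  n <- nrow(at)

  # neighbour lists from squared distances (atoms are few; full matrix is fine)
  d2 <- cross_dist2(xyz, xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    p <- pts * rad[i] + rep(xyz[i, ], each = n_points)
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
            (p[, 3] - xyz[j, 3])^2
      accessible <- accessible & dj >= rad[j]^2
      if (!any(accessible)) break
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(accessible) / n_points
  }

  key <- res_key_df(at)
  res <- model$residues
  per_res <- tapply(area, key, sum)
  res$abs_sasa <- as.numeric(per_res[res_key_df(res)])
  res$abs_sasa[is.na(res$abs_sasa)] <- 0
  ref <- MAX_SASA[res$resn]
  ref[is.na(ref)] <- mean(MAX_SASA)
  res$rel_sasa <- res$abs_sasa / unname(ref)
  res$surface <- res$rel_sasa >= surface_threshold
  out <- res[, c("chain", "res_seq", "icode", "resn",
                 "abs_sasa", "rel_sasa", "surface")]
  attr(out, "atom_sasa") <- data.frame(at[, c("chain", "res_seq", "icode",
                                              "resn", "atom", "element")],
                                       sasa = area)
  attr(out, "params") <- list(probe_radius = probe_radius,
                              n_points = n_points,
                              surface_threshold = surface_threshold)
  class(out) <- c("sasa_result", class(out))
  out
}
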