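IC_PAIRS <- c("charged_charged", "charged_polar", "charged_apolar",
              "polar_polar", "polar_apolar", "apolar_apolar")

ic_pair_key <- function(class_a, class_b) {
  lv <- c("charged", "polar", "apolar")
  a <- pmin(match(class_a, lv), match(class_b, lv))
  b <- pmax(match(class_a, lv), match(class_b, lv))
  paste(lv[a], lv[b], sep = "_")
}

split_sides <- function(complex, receptor_chains, ligand_chains) {
  if (!length(receptor_chains) || !length(ligand_chains))
    stopf("both chain sets must be non-empty")
  if (length(intersect(receptor_chains, ligand_chains)))
    stopf("receptor and ligand chain sets overlap")
  at <- heavy_atoms(complex)
  list(rec = at[at$chain %in% receptor_chains, , drop = FALSE],
       lig = at[at$chain %in% ligand_chains, , drop = FALSE])
}

#' Find interfacial residue contacts in a two-sided complex
#'
#' A contact is any cross-side residue pair whose minimum heavy-atom distance
#' is at most `contact_cutoff` (5.5 Angstrom by default, the interfacial
#' contact convention of the IC/NIS affinity model). Each qualifying pair
#' contributes exactly one contact row.
#'
#' @param complex a `structure_model` holding both sides.
#' @param receptor_chains,ligand_chains disjoint, non-empty chain-id vectors.
#' @param contact_cutoff heavy-atom distance cutoff in Angstrom.
#' @return data frame of class `interface_contacts` with one row per contact:
#'   receptor and ligand residue identifiers and the minimum heavy-atom
#'   distance `min_dist`.
#' @export
find_interface_contacts <- function(complex, receptor_chains, ligand_chains,
                                    contact_cutoff = 5.5) {
  sides <- split_sides(complex, receptor_chains, ligand_chains)
  empty <- data.frame(rec_chain = character(0), rec_seq = integer(0),
                      rec_icode = character(0), rec_resn = character(0),
                      lig_chain = character(0), lig_seq = integer(0),
                      lig_icode = character(0), lig_resn = character(0),
                      min_dist = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("interface_contacts", class(empty))
  attr(empty, "contact_cutoff") <- contact_cutoff
  if (!nrow(sides$rec) || !nrow(sides$lig)) return(empty)

  d2 <- cross_dist2(atom_coords(sides$rec), atom_coords(sides$lig))
  within <- which(d2 <= contact_cutoff^2, arr.ind = TRUE)
  if (!nrow(within)) return(empty)
  rk <- res_key_df(sides$rec)[within[, 1]]
  lk <- res_key_df(sides$lig)[within[, 2]]
  pair <- paste(rk, lk, sep = "::")
  mind <- tapply(sqrt(pmax(d2[within], 0)), pair, min)
  first <- !duplicated(pair)
  ord <- match(names(mind), pair[first])
  ri <- within[first, 1][ord]; li <- within[first, 2][ord]
  out <- data.frame(rec_chain = sides$rec$chain[ri],
                    rec_seq = sides$rec$res_seq[ri],
                    rec_icode = sides$rec$icode[ri],
                    rec_resn = sides$rec$resn[ri],
                    lig_chain = sides$lig$chain[li],
                    lig_seq = sides$lig$res_seq[li],
                    lig_icode = sides$lig$icode[li],
                    lig_resn = sides$lig$resn[li],
                    min_dist = as.numeric(mind),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rec_chain, out$rec_seq, out$lig_chain, out$lig_seq), ]
  rownames(out) <- NULL
  class(out) <- c("interface_contacts", class(out))
  attr(out, "contact_cutoff") <- contact_cutoff
  out
}

CHARGED_GROUP_ATOMS <- list(
  ASP = c(OD1 = -1, OD2 = -1), GLU = c(OE1 = -1, OE2 = -1),
  LYS = c(NZ = +1), ARG = c(NE = +1, NH1 = +1, NH2 = +1),
  HIS = c(ND1 = +1, NE2 = +1))

#' Classify the interaction types of interface contacts
#'
#' Geometric typing rules: a salt bridge needs charged-group N/O atoms of
#' oppositely signed charged residues within 4.0 Angstrom; a hydrogen bond
#' needs a cross-side N/O-N/O pair within 3.5 Angstrom; a hydrophobic contact
#' needs both residues apolar with a C-C pair within 4.5 Angstrom. Contacts
#' matching none of these are typed `other`; multiple labels are allowed.
#'
#' @param contacts result of [find_interface_contacts()].
#' @param complex the same `structure_model` the contacts came from (classes
#'   assigned via [assign_residue_classes()]).
#' @param hbond_cutoff,salt_cutoff,hydrophobic_cutoff distance thresholds (A).
#' @return `contacts` with a list-column `types`.
#' @export
classify_interaction_types <- function(contacts, complex,
                                       hbond_cutoff = 3.5,
                                       salt_cutoff = 4.0,
                                       hydrophobic_cutoff = 4.5) {
  stopifnot(inherits(contacts, "interface_contacts"))
  at <- heavy_atoms(complex)
  res <- complex$residues
  akey <- res_key_df(at)
  charge_of <- setNames(res$charge_class, res_key_df(res))

  atom_charge <- function(sub) {
    q <- numeric(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      grp <- CHARGED_GROUP_ATOMS[[sub$resn[i]]]
      if (!is.null(grp) && sub$atom[i] %in% names(grp))
        q[i] <- grp[[sub$atom[i]]]
    }
    q
  }

  types <- vector("list", nrow(contacts))
  for (i in seq_len(nrow(contacts))) {
    ra <- at[akey == res_key(contacts$rec_chain[i], contacts$rec_seq[i],
                             contacts$rec_icode[i]), , drop = FALSE]
    la <- at[akey == res_key(contacts$lig_chain[i], contacts$lig_seq[i],
                             contacts$lig_icode[i]), , drop = FALSE]
    d <- sqrt(pmax(cross_dist2(atom_coords(ra), atom_coords(la)), 0))
    lab <- character(0)

    no_r <- ra$element %in% c("N", "O"); no_l <- la$element %in% c("N", "O")
    if (any(no_r) && any(no_l) &&
        min(d[no_r, no_l, drop = FALSE]) <= hbond_cutoff)
      lab <- c(lab, "hydrogen_bond")

    qr <- atom_charge(ra); ql <- atom_charge(la)
    if (any(qr != 0) && any(ql != 0)) {
      sgn <- outer(sign(qr[qr != 0]), sign(ql[ql != 0]))
      dd <- d[qr != 0, ql != 0, drop = FALSE]
      if (any(dd[sgn < 0] <= salt_cutoff)) lab <- c(lab, "salt_bridge")
    }

    cc_r <- unname(charge_of[res_key(contacts$rec_chain[i], contacts$rec_seq[i],
                                     contacts$rec_icode[i])])
    cc_l <- unname(charge_of[res_key(contacts$lig_chain[i], contacts$lig_seq[i],
                                     contacts$lig_icode[i])])
    if (identical(cc_r, "apolar") && identical(cc_l, "apolar")) {
      c_r <- ra$element == "C"; c_l <- la$element == "C"
      if (any(c_r) && any(c_l) &&
          min(d[c_r, c_l, drop = FALSE]) <= hydrophobic_cutoff)
        lab <- c(lab, "hydrophobic")
    }

    if (!length(lab)) lab <- "other"
    types[[i]] <- sort(lab)
  }
  contacts$types <- types
  contacts
}

#' Unique contact residues on one side of the interface
#'
#' @param complex a `structure_model`.
#' @param receptor_chains,ligand_chains chain sets defining the two sides.
#' @param side `"receptor"` or `"ligand"`.
#' @param contact_cutoff heavy-atom cutoff in Angstrom.
#' @return data frame of unique residues (chain, res_seq, icode, resn).
#' @export
contact_residues <- function(complex, receptor_chains, ligand_chains,
                             side = c("receptor", "ligand"),
                             contact_cutoff = 5.5) {
  side <- match.arg(side)
  contacts <- find_interface_contacts(complex, receptor_chains, ligand_chains,
                                      contact_cutoff)
  contact_residues_from(contacts, side)
}

contact_residues_from <- function(contacts, side = c("receptor", "ligand")) {
  side <- match.arg(side)
  p <- if (side == "receptor") "rec_" else "lig_"
  df <- contacts[, paste0(p, c("chain", "seq", "icode", "resn"))]
  names(df) <- c("chain", "res_seq", "icode", "resn")
  df <- df[!duplicated(res_key_df(df)), , drop = FALSE]
  df <- df[order(df$chain, df$res_seq, df$icode), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Interface contact profile: IC counts by class pair and %NIS by class
#'
#' Tallies interfacial contacts by the unordered charge-class pair of the two
#' residues, and computes the percentage composition of the non-interacting
#' surface (NIS): residues of the assembled complex (both sides pooled) that
#' are surface-exposed yet not part of either contact-residue set. These are
#' exactly the inputs of the IC/NIS binding-affinity model ([predict_dG()]).
#'
#' @param complex a `structure_model` with charge classes assigned.
#' @param receptor_chains,ligand_chains the two sides.
#' @param contact_cutoff heavy-atom contact cutoff (A).
#' @param sasa_cfg list of [compute_sasa()] arguments (`probe_radius`,
#'   `n_points`, `surface_threshold`).
#' @return an `interface_contact_profile`: list with `ic_counts` (named over
#'   the six class pairs), `nis_percent` (charged/polar/apolar, summing to
#'   100 when any NIS residue exists), the two contact-residue sets, and the
#'   parameters used.
#' @export
contact_profile <- function(complex, receptor_chains, ligand_chains,
                            contact_cutoff = 5.5, sasa_cfg = list()) {
  if (all(is.na(complex$residues$charge_class)))
    stopf("assign_residue_classes() must be run before contact_profile()")
  contacts <- find_interface_contacts(complex, receptor_chains, ligand_chains,
                                      contact_cutoff)
  res <- complex$residues
  charge_of <- setNames(res$charge_class, res_key_df(res))

  ic <- setNames(integer(length(IC_PAIRS)), IC_PAIRS)
  if (nrow(contacts)) {
    keys <- ic_pair_key(
      charge_of[res_key(contacts$rec_chain, contacts$rec_seq, contacts$rec_icode)],
      charge_of[res_key(contacts$lig_chain, contacts$lig_seq, contacts$lig_icode)])
    tab <- table(keys)
    ic[names(tab)] <- as.integer(tab)
  }

  sub <- subset_chains(complex, c(receptor_chains, ligand_chains))
  sasa <- do.call(compute_sasa, c(list(sub), sasa_cfg))
  rec_set <- contact_residues_from(contacts, "receptor")
  lig_set <- contact_residues_from(contacts, "ligand")
  iface_keys <- c(res_key_df(rec_set), res_key_df(lig_set))
  nis <- sasa[sasa$surface & !(res_key_df(sasa) %in% iface_keys), , drop = FALSE]
  nis_class <- unname(charge_of[res_key_df(nis)])
  nis_percent <- setNames(numeric(3), c("charged", "polar", "apolar"))
  if (nrow(nis)) {
    tab <- table(factor(nis_class, levels = names(nis_percent)))
    nis_percent[] <- 100 * as.numeric(tab) / nrow(nis)
  }

  structure(list(ic_counts = ic,
                 nis_percent = nis_percent,
                 contact_residues_receptor = rec_set,
                 contact_residues_ligand = lig_set,
                 n_contacts = nrow(contacts),
                 params = list(contact_cutoff = contact_cutoff,
                               sasa = attr(sasa, "params"))),
            class = "interface_contact_profile")
}

#' @export
print.interface_contact_profile <- function(x, ...) {
  cat("<interface_contact_profile>\n  ICs:",
      paste(sprintf("%s=%d", names(x$ic_counts), x$ic_counts), collapse = " "),
      sprintf("\n  %%NIS: charged=%.1f polar=%.1f apolar=%.1f\n",
              x$nis_percent["charged"], x$nis_percent["polar"],
              x$nis_percent["apolar"]),
      sprintf("  contacts: %d (receptor residues %d, ligand residues %d)\n",
              x$n_contacts, nrow(x$contact_residues_receptor),
              nrow(x$contact_residues_ligand)))
  invisible(x)
}
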