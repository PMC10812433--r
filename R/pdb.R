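WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

new_structure_model <- function(atoms, model_id = "model") {
  needed <- c("chain", "res_seq", "icode", "resn", "atom", "element",
              "x", "y", "z", "occupancy")
  missing <- setdiff(needed, names(atoms))
  if (length(missing)) stopf("atom table lacks columns: %s",
                             paste(missing, collapse = ", "))
  atoms$element <- toupper(trimws(atoms$element))
  rownames(atoms) <- NULL
  m <- structure(list(model_id = model_id, atoms = atoms),
                 class = "structure_model")
  m$residues <- build_residue_table(atoms)
  m
}

build_residue_table <- function(atoms) {
  key <- res_key_df(atoms)
  first <- !duplicated(key)
  res <- data.frame(chain = atoms$chain[first],
                    res_seq = atoms$res_seq[first],
                    icode = atoms$icode[first],
                    resn = atoms$resn[first],
                    stringsAsFactors = FALSE)
  has_ca <- tapply(atoms$atom == "CA", key, any)
  res$complete <- as.logical(has_ca[res_key_df(res)])
  res$charge_class <- NA_character_
  res$hydropathy_class <- NA_character_
  rownames(res) <- NULL
  res
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- table(x$residues$chain)
  cat(sprintf("<structure_model '%s'> %d chain(s), %d residues, %d atoms\n",
              x$model_id, length(ch), nrow(x$residues), nrow(x$atoms)))
  for (nm in names(ch)) cat(sprintf("  chain %s: %d residues\n", nm, ch[[nm]]))
  invisible(x)
}

heavy_atoms <- function(model) model$atoms[model$atoms$element != "H", , drop = FALSE]

atom_coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

guess_element <- function(name) {
  nm <- trimws(name)
  # two-letter elements in amino acids are rare; first alpha char wins unless
  # the name starts with a digit (e.g. "1HB" hydrogens)
  nm <- sub("^[0-9]+", "", nm)
  el <- substr(nm, 1, 1)
  ifelse(el %in% c("H", "C", "N", "O", "S", "P"), el, toupper(el))
}

#' Read a PDB file into a structure model
#'
#' Parses ATOM/HETATM records (fixed-column PDB v3 layout), drops waters and
#' non-protein heteroatoms, resolves alternate locations to the highest
#' occupancy (ties broken in favour of altloc "A"), and optionally restricts
#' to a chain subset. Hydrogens are retained in the atom table but ignored by
#' every distance-based operation.
#'
#' @param path PDB file path.
#' @param keep_chains optional character vector of chain ids to retain; each
#'   must exist in the file.
#' @param model_id label stored on the result (defaults to the file name).
#' @return a `structure_model`: a list with `model_id`, an `atoms` data frame
#'   and a per-residue `residues` table.
#' @export
read_pdb <- function(path, keep_chains = NULL, model_id = NULL) {
  if (!file.exists(path)) stopf("PDB file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  if (!length(lines)) stopf("no ATOM/HETATM records in %s", path)
  fw <- function(from, to) trimws(substr(lines, from, to))
  atoms <- data.frame(
    record = substr(lines, 1, 6),
    atom = fw(13, 16),
    altloc = substr(lines, 17, 17),
    resn = fw(18, 20),
    chain = substr(lines, 22, 22),
    res_seq = as.integer(fw(23, 26)),
    icode = trimws(substr(lines, 27, 27)),
    x = as.numeric(fw(31, 38)),
    y = as.numeric(fw(39, 46)),
    z = as.numeric(fw(47, 54)),
    occupancy = suppressWarnings(as.numeric(fw(55, 60))),
    element = fw(77, 78),
    stringsAsFactors = FALSE)
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$element[!nzchar(atoms$element)] <-
    guess_element(atoms$atom[!nzchar(atoms$element)])

  # preparation: drop waters and non-protein heteroatoms
  atoms <- atoms[!(atoms$resn %in% WATER_NAMES), , drop = FALSE]
  atoms <- atoms[atoms$record == "ATOM" | atoms$resn %in% AA3, , drop = FALSE]
  if (!nrow(atoms)) stopf("no protein residues in %s", path)

  if (!is.null(keep_chains)) {
    absent <- setdiff(keep_chains, unique(atoms$chain))
    if (length(absent)) stopf("requested chain(s) absent: %s",
                              paste(absent, collapse = ", "))
    atoms <- atoms[atoms$chain %in% keep_chains, , drop = FALSE]
  }

  # altloc resolution: per (residue, atom name) keep highest occupancy,
  # tie -> altloc "A" (blank sorts before letters so plain atoms win)
  akey <- paste(res_key_df(atoms), atoms$atom)
  if (any(nzchar(trimws(atoms$altloc)))) {
    ord <- order(akey, -atoms$occupancy, atoms$altloc)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(res_key_df(atoms), atoms$atom)), , drop = FALSE]
  }
  atoms <- atoms[order(atoms$chain, atoms$res_seq, atoms$icode), , drop = FALSE]
  atoms$record <- NULL
  atoms$altloc <- NULL
  new_structure_model(atoms, model_id %||% basename(path))
}

#' Write a structure model to a PDB file
#'
#' Emits ATOM records in fixed-column PDB v3 layout with TER records between
#' chains. Coordinates are written to 3 decimals, so a read/write/read round
#' trip preserves them at that precision.
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  out <- character(0)
  serial <- 1L
  for (ch in unique(a$chain)) {
    sub <- a[a$chain == ch, , drop = FALSE]
    name_fmt <- ifelse(nchar(sub$atom) < 4 & nchar(sub$element) == 1,
                       sprintf(" %-3s", sub$atom), sprintf("%-4s", sub$atom))
    recs <- sprintf("ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    serial + seq_len(nrow(sub)) - 1L, name_fmt, sub$resn, ch,
                    sub$res_seq,
                    ifelse(nzchar(sub$icode), sub$icode, " "),
                    sub$x, sub$y, sub$z, sub$occupancy, 0, sub$element)
    serial <- serial + nrow(sub) + 1L
    out <- c(out, recs, "TER")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Restrict a model to a chain subset
#' @param model a `structure_model`.
#' @param chains chain ids to keep.
#' @return a `structure_model` containing only those chains.
#' @export
subset_chains <- function(model, chains) {
  stopifnot(inherits(model, "structure_model"))
  absent <- setdiff(chains, unique(model$atoms$chain))
  if (length(absent)) stopf("chain(s) absent: %s", paste(absent, collapse = ", "))
  keep <- model$atoms$chain %in% chains
  m <- new_structure_model(model$atoms[keep, , drop = FALSE], model$model_id)
  rk <- res_key_df(m$residues)
  old <- model$residues[match(rk, res_key_df(model$residues)), ]
  m$residues$charge_class <- old$charge_class
  m$residues$hydropathy_class <- old$hydropathy_class
  m
}
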