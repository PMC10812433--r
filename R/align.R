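blosum_cache <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix
#'
#' Loaded from a plain-text copy shipped with the package (25 x 25, including
#' ambiguity codes and X).
#'
#' @return integer matrix with amino-acid single-letter dimnames.
#' @export
blosum62 <- function() {
  if (is.null(blosum_cache$m)) {
    path <- system.file("extdata", "blosum62.tsv", package = "contactmap")
    m <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                              check.names = FALSE, row.names = 1))
    storage.mode(m) <- "integer"
    blosum_cache$m <- m
  }
  blosum_cache$m
}

#' Global sequence alignment (Needleman-Wunsch, affine gaps)
#'
#' Gotoh's three-state dynamic program. A gap of length L costs
#' `gap_open + (L - 1) * gap_extend`. Ties are broken deterministically,
#' preferring match over deletion (gap in `seq_b`) over insertion (gap in
#' `seq_a`). Unknown letters are mapped to X with a warning.
#'
#' @param seq_a,seq_b non-empty amino-acid strings.
#' @param matrix substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend gap penalties (negative).
#' @return list with `score`, `aligned_a`/`aligned_b` (gapped strings) and
#'   `pairs`, a data frame of 1-based aligned positions (`NA` at gaps).
#' @export
needleman_wunsch <- function(seq_a, seq_b, matrix = blosum62(),
                             gap_open = -11, gap_extend = -1) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (!length(a) || !length(b)) stopf("sequences must be non-empty")
  fix <- function(x) {
    bad <- !(x %in% rownames(matrix))
    if (any(bad)) {
      warnf("unknown residue letter(s) %s mapped to X",
            paste(unique(x[bad]), collapse = ", "))
      x[bad] <- "X"
    }
    x
  }
  a <- fix(a); b <- fix(b)
  n <- length(a); m <- length(b)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); D <- matrix(NEG, n + 1, m + 1)
  I <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n) D[2:(n + 1), 1] <- gap_open + (seq_len(n) - 1) * gap_extend
  if (m) I[1, 2:(m + 1)] <- gap_open + (seq_len(m) - 1) * gap_extend
  # traceback state choices; 1 = M, 2 = D, 3 = I (preference order)
  ptrM <- matrix(0L, n + 1, m + 1); ptrD <- matrix(0L, n + 1, m + 1)
  ptrI <- matrix(0L, n + 1, m + 1)
  best3 <- function(vm, vd, vi) {  # index of max with M > D > I preference
    if (vm >= vd && vm >= vi) 1L else if (vd >= vi) 2L else 3L
  }
  for (i in seq_len(n)) {
    si <- matrix[a[i], ]
    for (j in seq_len(m)) {
      k <- best3(M[i, j], D[i, j], I[i, j])
      M[i + 1, j + 1] <- c(M[i, j], D[i, j], I[i, j])[k] + si[b[j]]
      ptrM[i + 1, j + 1] <- k
      k <- best3(M[i, j + 1] + gap_open, D[i, j + 1] + gap_extend,
                 I[i, j + 1] + gap_open)
      D[i + 1, j + 1] <- c(M[i, j + 1] + gap_open, D[i, j + 1] + gap_extend,
                           I[i, j + 1] + gap_open)[k]
      ptrD[i + 1, j + 1] <- k
      k <- best3(M[i + 1, j] + gap_open, D[i + 1, j] + gap_open,
                 I[i + 1, j] + gap_extend)
      I[i + 1, j + 1] <- c(M[i + 1, j] + gap_open, D[i + 1, j] + gap_open,
                           I[i + 1, j] + gap_extend)[k]
      ptrI[i + 1, j + 1] <- k
    }
  }
  state <- best3(M[n + 1, m + 1], D[n + 1, m + 1], I[n + 1, m + 1])
  score <- c(M[n + 1, m + 1], D[n + 1, m + 1], I[n + 1, m + 1])[state]
  # traceback
  i <- n; j <- m
  pa <- integer(0); pb <- integer(0)
  while (i > 0 || j > 0) {
    if (i == 0) { pa <- c(NA, pa); pb <- c(j, pb); j <- j - 1; next }
    if (j == 0) { pa <- c(i, pa); pb <- c(NA, pb); i <- i - 1; next }
    if (state == 1L) {
      prev <- ptrM[i + 1, j + 1]
      pa <- c(i, pa); pb <- c(j, pb); i <- i - 1; j <- j - 1
      state <- prev
    } else if (state == 2L) {
      prev <- ptrD[i + 1, j + 1]
      pa <- c(i, pa); pb <- c(NA, pb); i <- i - 1
      state <- prev
    } else {
      prev <- ptrI[i + 1, j + 1]
      pa <- c(NA, pa); pb <- c(j, pb); j <- j - 1
      state <- prev
    }
  }
  gap <- function(x, s) ifelse(is.na(x), "-", s[x])
  list(score = score,
       aligned_a = paste(gap(pa, a), collapse = ""),
       aligned_b = paste(gap(pb, b), collapse = ""),
       pairs = data.frame(pos_a = pa, pos_b = pb))
}

#' Optimal rigid superposition of paired point sets (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD of
#' `coords_a %*% t(R) + t` against `coords_b` (rows are paired points).
#'
#' @param coords_a,coords_b n x 3 matrices, n >= 3, not all collinear.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3)
#'   and `rmsd` over the input pairs.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  stopifnot(ncol(A) == 3, ncol(B) == 3, nrow(A) == nrow(B))
  if (nrow(A) < 3) stopf("need at least 3 point pairs")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sv <- svd(crossprod(Ac, Bc))
  if (sv$d[2] < 1e-10) stopf("degenerate (collinear) point configuration")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- as.numeric(cb - R %*% ca)
  fitted <- Ac %*% t(R) + matrix(cb, nrow(A), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

model_sequence <- function(model, chain) {
  nodes <- network_nodes_ca(model)
  nodes <- nodes[nodes$chain == chain, , drop = FALSE]
  list(seq = paste(three_to_one(nodes$resn), collapse = ""), nodes = nodes)
}

#' Sequence-guided rigid superposition of two structures
#'
#' Aligns the C-alpha sequences with [needleman_wunsch()] (BLOSUM62), fits
#' the aligned C-alpha pairs with [kabsch_superpose()], then iteratively
#' drops pairs whose residual exceeds `prune_cutoff` and refits until stable
#' (matchmaker-style). Operates on the coordinates as supplied; no energy
#' minimisation is performed.
#'
#' @param model_a,model_b `structure_model`s with C-alpha traces.
#' @param chain_a,chain_b chains to align (default: first chain of each).
#' @param prune_cutoff residual cutoff in Angstrom (`Inf` disables pruning).
#' @param max_iter maximum prune/refit rounds.
#' @param gap_open,gap_extend alignment gap penalties.
#' @return an `alignment_result`: aligned residue `pairs` (residue numbers,
#'   NA at gaps), logical `used` flag per non-gap pair, `rotation`,
#'   `translation`, `rmsd`, `n_pairs_used`, alignment `score` and parameters.
#' @export
align_structures <- function(model_a, model_b,
                             chain_a = model_a$atoms$chain[1],
                             chain_b = model_b$atoms$chain[1],
                             prune_cutoff = 2.0, max_iter = 20,
                             gap_open = -11, gap_extend = -1) {
  sa <- model_sequence(model_a, chain_a)
  sb <- model_sequence(model_b, chain_b)
  if (!nrow(sa$nodes) || !nrow(sb$nodes)) stopf("missing C-alpha trace")
  aln <- needleman_wunsch(sa$seq, sb$seq, gap_open = gap_open,
                          gap_extend = gap_extend)
  pairs <- data.frame(
    res_a = ifelse(is.na(aln$pairs$pos_a), NA_integer_,
                   sa$nodes$res_seq[aln$pairs$pos_a]),
    res_b = ifelse(is.na(aln$pairs$pos_b), NA_integer_,
                   sb$nodes$res_seq[aln$pairs$pos_b]))
  both <- !is.na(aln$pairs$pos_a) & !is.na(aln$pairs$pos_b)
  A <- as.matrix(sa$nodes[aln$pairs$pos_a[both], c("x", "y", "z")])
  B <- as.matrix(sb$nodes[aln$pairs$pos_b[both], c("x", "y", "z")])
  used <- rep(TRUE, nrow(A))
  fit <- NULL
  for (iter in seq_len(max_iter)) {
    if (sum(used) < 3) stopf("fewer than 3 pairs survive pruning")
    fit <- kabsch_superpose(A[used, , drop = FALSE], B[used, , drop = FALSE])
    if (!is.finite(prune_cutoff)) break
    fitted <- A %*% t(fit$rotation) +
      matrix(fit$translation, nrow(A), 3, byrow = TRUE)
    resid <- sqrt(rowSums((fitted - B)^2))
    drop <- used & resid > prune_cutoff
    if (!any(drop)) break
    used <- used & !drop
  }
  structure(list(pairs = pairs, aligned_a = aln$aligned_a,
                 aligned_b = aln$aligned_b, used = used,
                 rotation = fit$rotation, translation = fit$translation,
                 rmsd = fit$rmsd, n_pairs_used = sum(used),
                 score = aln$score,
                 params = list(matrix = "BLOSUM62", gap_open = gap_open,
                               gap_extend = gap_extend,
                               prune_cutoff = prune_cutoff,
                               minimized_inputs = FALSE)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> score %g, rmsd %.3f A over %d pairs\n",
              x$score, x$rmsd, x$n_pairs_used))
  invisible(x)
}

#' Project a residue set across a structural alignment
#'
#' Each source residue maps to its aligned partner; residues aligned to a gap
#' (or absent from the alignment) are reported as unmapped, never silently
#' dropped.
#'
#' @param alignment an `alignment_result`.
#' @param residues integer source residue numbers.
#' @param from `"a"` (project A onto B, default) or `"b"`.
#' @return sorted integer vector of target residues, with the unmapped source
#'   residues in `attr(, "unmapped")`.
#' @export
project_residues <- function(alignment, residues, from = c("a", "b")) {
  from <- match.arg(from)
  p <- alignment$pairs
  src <- if (from == "a") p$res_a else p$res_b
  dst <- if (from == "a") p$res_b else p$res_a
  idx <- match(residues, src)
  mapped <- dst[idx]
  unmapped <- residues[is.na(idx) | is.na(mapped)]
  out <- sort(unique(mapped[!is.na(mapped) & !is.na(idx)]))
  attr(out, "unmapped") <- sort(unique(unmapped))
  out
}
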