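#' Parse a residue-range string into an integer vector
#'
#' Accepts comma- or whitespace-separated tokens where each token is either a
#' single residue number ("33") or an inclusive range ("28-32", en-dashes
#' tolerated). Useful for entering published residue lists.
#'
#' @param x character scalar (or vector, concatenated).
#' @return sorted unique integer vector.
#' @examples
#' parse_residue_ranges("28-32, 34-36, 38, 39, 70")
#' @export
parse_residue_ranges <- function(x) {
  x <- gsub("–|—", "-", paste(x, collapse = ","))
  tokens <- unlist(strsplit(x, "[,[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  out <- lapply(tokens, function(tok) {
    if (grepl("^-?[0-9]+--?[0-9]+$", tok) && grepl("^[0-9]", tok)) {
      parts <- as.integer(strsplit(tok, "(?<=[0-9])-", perl = TRUE)[[1]])
      seq(parts[1], parts[2])
    } else {
      as.integer(tok)
    }
  })
  sort(unique(unlist(out)))
}

# residue identity key: "chain|res_seq|icode"
res_key <- function(chain, res_seq, icode = "") {
  paste(chain, res_seq, icode, sep = "|")
}

res_key_df <- function(df) res_key(df$chain, df$res_seq, df$icode)

`%||%` <- function(a, b) if (is.null(a)) b else a

# squared euclidean distances between rows of a (n x 3) and rows of b (m x 3)
cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

min_cross_dist <- function(a, b) sqrt(max(0, min(cross_dist2(a, b))))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
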