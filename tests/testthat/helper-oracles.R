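# independent brute-force oracles, deliberately written against different
# algorithms than the package implementation

# all-pairs shortest paths by Floyd-Warshall, shortest-path counts by
# distance-layer dynamic programming, betweenness by pair-dependency sums
bf_centralities <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0; d[adj == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]

  sigma <- matrix(0, n, n)  # sigma[s, v]: number of shortest s-v paths
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    reach <- which(is.finite(d[s, ]) & seq_len(n) != s)
    for (v in reach[order(d[s, reach])]) {
      pred <- which(adj[, v] == 1 & d[s, ] == d[s, v] - 1)
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }

  btw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
      if (s == v || t == v || !is.finite(d[s, t])) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t])
        tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    btw[v] <- tot
  }

  reach_n <- rowSums(is.finite(d)) - 1
  dsum <- apply(d, 1, function(r) sum(r[is.finite(r) & r > 0]))
  clo <- ifelse(reach_n > 0, (reach_n / (n - 1)) * (reach_n / dsum), 0)

  deg <- rowSums(adj)
  ann <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    if (!length(nb)) 0 else mean(deg[nb])
  }, numeric(1))
  list(closeness = clo, betweenness = btw, ann_degree = ann)
}

# exhaustive global-alignment score: enumerates every alignment path,
# applying open/extend per gap run (length-L gap costs open + (L-1) extend)
nw_enum_score <- function(a, b, mat, go, ge) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    if (i > n) {  # forced gap in a over the rest of b
      L <- m - j + 1
      return(if (prev == "i") L * ge else go + (L - 1) * ge)
    }
    if (j > m) {
      L <- n - i + 1
      return(if (prev == "d") L * ge else go + (L - 1) * ge)
    }
    best <- mat[a[i], b[j]] + rec(i + 1, j + 1, "m")
    best <- max(best, (if (prev == "d") ge else go) + rec(i + 1, j, "d"))
    max(best, (if (prev == "i") ge else go) + rec(i, j + 1, "i"))
  }
  rec(1, 1, "m")
}

# term-by-term arithmetic for the simplified pair potential (single atom pair)
lj_pair_oracle <- function(el_a, el_b, d, q_a = 0, q_b = 0) {
  radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  eps <- c(C = 0.07, N = 0.17, O = 0.16, S = 0.25, P = 0.20)
  rmin <- radii[[el_a]] + radii[[el_b]]
  e <- sqrt(eps[[el_a]] * eps[[el_b]])
  x6 <- (rmin / d)^6
  e * (x6^2 - 2 * x6) + 332.0636 * q_a * q_b / (4 * d^2)
}
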