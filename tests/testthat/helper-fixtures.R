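# hand-built atom tables -> structure models, and PDB text fixtures

`%||%` <- function(a, b) if (is.null(a)) b else a

make_model <- function(...) {
  rows <- list(...)
  atoms <- do.call(rbind, lapply(rows, function(r)
    data.frame(chain = r$chain, res_seq = r$res_seq, icode = "",
               resn = r$resn, atom = r$atom, element = r$element,
               x = r$x, y = r$y, z = r$z, occupancy = 1,
               stringsAsFactors = FALSE)))
  contactmap:::new_structure_model(atoms)
}

atom_row <- function(chain, res_seq, resn, atom, element, x, y, z) {
  list(chain = chain, res_seq = res_seq, resn = resn, atom = atom,
       element = element, x = x, y = y, z = z)
}

# a residue as a tight 5-atom cluster at a centre (same template idea as the
# generator, but local to the tests)
cluster_res <- function(chain, res_seq, resn, centre) {
  atoms <- c("N", "CA", "C", "O", if (resn != "GLY") "CB")
  offs <- rbind(c(-0.4, 0), c(0, 0), c(0.4, 0), c(0, 0.4), c(0, -0.4))
  lapply(seq_along(atoms), function(i)
    atom_row(chain, res_seq, resn, atoms[i], substr(atoms[i], 1, 1),
             centre[1] + offs[i, 1], centre[2] + offs[i, 2], centre[3]))
}

model_from_residues <- function(...) {
  do.call(make_model, do.call(c, list(...)))
}

pdb_ala_lines <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.986  -0.760  -1.210  1.00  0.00           C",
    "END")
}

write_pdb_text <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

rigid_move <- function(model, angle = 0.6, axis = c(0, 0, 1), shift = c(3, -4, 7)) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  at <- model$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R) +
    matrix(shift, nrow(at), 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  m <- contactmap:::new_structure_model(at, model$model_id)
  m$residues$charge_class <- model$residues$charge_class
  m$residues$hydropathy_class <- model$residues$hydropathy_class
  m
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Erdos-Renyi adjacency matrix
random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(runif(n * (n - 1) / 2) < p)
  adj + t(adj)
}
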