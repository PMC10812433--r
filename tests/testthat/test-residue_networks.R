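ca_chain <- function(positions, resn = NULL, chain = "A") {
  resn <- resn %||% rep("ALA", nrow(positions))
  atoms <- do.call(rbind, lapply(seq_len(nrow(positions)), function(i)
    data.frame(chain = chain, res_seq = i, icode = "", resn = resn[i],
               atom = "CA", element = "C", x = positions[i, 1],
               y = positions[i, 2], z = positions[i, 3], occupancy = 1)))
  assign_residue_classes(contactmap:::new_structure_model(atoms))
}

test_that("contact network applies strict cutoff and separation rules", {
  near <- ca_chain(rbind(c(0, 0, 0), c(6.9, 0, 0)))
  expect_equal(igraph::ecount(build_contact_network(near)$graph), 1)
  far <- ca_chain(rbind(c(0, 0, 0), c(7.1, 0, 0)))
  expect_equal(igraph::ecount(build_contact_network(far)$graph), 0)
  # extended chain at 3.8 A spacing: min_separation = 2 kills all |i-j| = 1
  ext <- ca_chain(cbind(3.8 * (0:9), 0, 0))
  expect_equal(igraph::ecount(build_contact_network(ext, min_separation = 2)$graph), 0)
  expect_equal(igraph::ecount(build_contact_network(ext, min_separation = 1)$graph), 9)
})

test_that("toy folds realise their target graph exactly at 7 A", {
  cyc <- make_toy_fold(toy_fold_spec(cbind(1:6, c(2:6, 1)), seed = 2))
  net <- build_contact_network(cyc$model)
  edges <- igraph::as_edgelist(net$graph)
  got <- t(apply(matrix(match(edges, paste0("A:", 1:6)), ncol = 2), 1, sort))
  expect_setequal(paste(got[, 1], got[, 2]),
                  paste(cyc$graph[, 1], cyc$graph[, 2]))
  # rigid-motion invariance
  net2 <- build_contact_network(rigid_move(cyc$model))
  expect_equal(igraph::as_edgelist(net2$graph), edges)
  # edgeless spec
  lone <- make_toy_fold(toy_fold_spec(matrix(integer(0), 0, 2), n_nodes = 4,
                                      seed = 3))
  expect_equal(igraph::ecount(build_contact_network(lone$model)$graph), 0)
})

test_that("pair interaction energy is symmetric, decaying and term-correct", {
  f <- make_toy_fold(toy_fold_spec(cbind(1:11, 2:12),
                                   resn = rep(c("LYS", "GLU", "SER"), 4),
                                   seed = 7))
  set.seed(1)
  for (k in 1:25) {
    ij <- sample(12, 2)
    expect_equal(pair_interaction_energy(f$model, ij[1], ij[2]),
                 pair_interaction_energy(f$model, ij[2], ij[1]))
  }
  # residues far apart interact negligibly
  far <- make_model(atom_row("A", 1, "ALA", "CA", "C", 0, 0, 0),
                    atom_row("A", 2, "ALA", "CA", "C", 26, 0, 0))
  expect_lt(abs(pair_interaction_energy(far, 1, 2)), 0.001)

  # isolated Lys NZ / Glu carboxylate: term-by-term arithmetic oracle
  m <- make_model(atom_row("A", 1, "LYS", "CA", "C", 0, 0, 0),
                  atom_row("A", 1, "LYS", "NZ", "N", 0, 0, 3),
                  atom_row("A", 2, "GLU", "CA", "C", 0, 0, 10),
                  atom_row("A", 2, "GLU", "OE1", "O", 0, 0, 6.5),
                  atom_row("A", 2, "GLU", "OE2", "O", 0, 1, 6.5))
  d <- function(a, b) sqrt(sum((a - b)^2))
  expected <-
    lj_pair_oracle("C", "C", 10) +
    lj_pair_oracle("C", "O", 6.5) +
    lj_pair_oracle("C", "O", d(c(0, 0, 0), c(0, 1, 6.5))) +
    lj_pair_oracle("N", "C", 7, q_a = 1, q_b = 0) +
    lj_pair_oracle("N", "O", 3.5, q_a = 1, q_b = -0.5) +
    lj_pair_oracle("N", "O", d(c(0, 0, 3), c(0, 1, 6.5)), q_a = 1, q_b = -0.5)
  expect_equal(pair_interaction_energy(m, 1, 2), expected, tolerance = 1e-12)
})

test_that("energy network band-filters and normalises hand-computed energies", {
  # single-CA residues on a line: adjacent pair energies are single LJ terms
  pos <- c(0, 3.6, 7.4, 10.6)
  m <- ca_chain(cbind(pos, 0, 0))
  e_hand <- vapply(1:3, function(i)
    lj_pair_oracle("C", "C", pos[i + 1] - pos[i]), numeric(1))
  # also the 1-3 and 2-4 and 1-4 interactions
  e_all <- c(e_hand, lj_pair_oracle("C", "C", 7.4),
             lj_pair_oracle("C", "C", 7.0), lj_pair_oracle("C", "C", 10.6))
  lo <- 0.02; hi <- 0.062
  keep <- abs(e_all) >= lo & abs(e_all) <= hi
  net <- build_energy_network(m, energy_lower = lo, energy_upper = hi)
  expect_equal(igraph::ecount(net$graph), sum(keep))
  w <- sort(igraph::E(net$graph)$weight)
  expect_equal(w, sort(abs(e_all[keep]) / max(abs(e_all[keep]))),
               tolerance = 1e-12)
  expect_equal(max(w), 1)
  # everything below the band: empty network with a warning
  expect_warning(empty <- build_energy_network(m, energy_lower = 5,
                                               energy_upper = 10), "band")
  expect_equal(igraph::ecount(empty$graph), 0)
})

test_that("energy neighbours follow the engineered adjacency", {
  star <- toy_fold_spec(cbind(rep(1, 4), 2:5), seed = 11)
  f <- make_toy_fold(star)
  en <- build_energy_network(f$model)
  expect_setequal(energy_neighbors(en, 1), 2:5)
  expect_setequal(energy_neighbors(en, 2), 1)
  expect_setequal(energy_neighbors(en, c(1, 2)), 3:5)
  expect_setequal(energy_neighbors(en, c(1, 2), include_seeds = TRUE), 1:5)
  # isolated seed has no neighbours
  iso <- make_toy_fold(toy_fold_spec(cbind(1, 2), n_nodes = 3, seed = 12))
  en2 <- build_energy_network(iso$model)
  expect_equal(energy_neighbors(en2, 3), integer(0))
  expect_error(energy_neighbors(en2, 99), "not in network")
  # full engineered-adjacency agreement on a mixed fold
  mixed <- make_toy_fold(toy_fold_spec(rbind(c(1, 2), c(2, 3), c(1, 3),
                                             c(3, 4), c(4, 5), c(5, 6)),
                                       seed = 13))
  en3 <- build_energy_network(mixed$model)
  for (v in 1:6)
    expect_setequal(energy_neighbors(en3, v), mixed$adjacency[[v]])
})

test_that("class subnetworks select the right residues and components", {
  # chain of 8: charged at 1,2 and 5,6 -> two disjoint charged edges
  resn <- c("LYS", "GLU", "SER", "SER", "ASP", "ARG", "SER", "SER")
  f <- make_toy_fold(toy_fold_spec(cbind(1:7, 2:8), resn = resn, seed = 14))
  net <- build_contact_network(f$model)
  comps <- class_subnetworks(net, "charged")
  expect_equal(length(comps), 2)
  expect_setequal(vapply(comps, paste, collapse = ",", FUN.VALUE = ""),
                  c("1,2", "5,6"))
  # Gly never participates
  g <- make_toy_fold(toy_fold_spec(cbind(1:3, 2:4), resn = rep("GLY", 4),
                                   seed = 15))
  gnet <- build_contact_network(g$model)
  expect_equal(class_subnetworks(gnet, "none"), list())
  expect_equal(class_subnetworks(gnet, "charged"), list())
  # engineered 14-membered charged component
  resn2 <- c(rep("LYS", 7), rep("ASP", 7), rep("SER", 4))
  f2 <- make_toy_fold(toy_fold_spec(cbind(1:17, 2:18), resn = resn2, seed = 16))
  comps2 <- class_subnetworks(build_contact_network(f2$model), "charged")
  expect_equal(length(comps2), 1)
  expect_equal(comps2[[1]], 1:14)
})

test_that("centralities match closed forms and the brute-force oracle", {
  path3 <- ca_chain(cbind(c(0, 6, 12), 0, 0))
  cent <- centralities(build_contact_network(path3))
  expect_equal(cent$closeness, c(2 / 3, 1, 2 / 3))
  star5 <- make_toy_fold(toy_fold_spec(cbind(rep(1, 4), 2:5), seed = 17))
  cs <- centralities(build_contact_network(star5$model))
  expect_equal(cs$betweenness[cs$res_seq == 1], 6)
  expect_equal(cs$ann_degree[cs$res_seq == 1], 1)  # centre: leaves have deg 1
  expect_equal(cs$ann_degree[cs$res_seq == 2], 4)  # leaf: its neighbour is the hub

  # random graphs against the independent oracle (full 50-graph sweep in the
  # acceptance suite; spot-check here)
  set.seed(5)
  for (k in 1:8) {
    n <- sample(4:12, 1)
    adj <- random_adjacency(n, 0.3)
    g <- igraph::graph_from_adjacency_matrix(adj, "undirected")
    g <- igraph::set_vertex_attr(g, "name", value = paste0("A:", 1:n))
    net <- contactmap:::new_residue_network(
      "contact", g, data.frame(chain = "A", res_seq = 1:n, icode = "",
                               resn = "ALA"), list())
    got <- centralities(net)
    want <- bf_centralities(adj)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-12)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-12)
    expect_equal(got$ann_degree, want$ann_degree, tolerance = 1e-12)
  }
})
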