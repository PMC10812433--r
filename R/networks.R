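node_label <- function(chain, res_seq, icode = "") {
  paste0(chain, ":", res_seq, ifelse(nzchar(icode), icode, ""))
}

new_residue_network <- function(kind, graph, nodes, params) {
  structure(list(kind = kind, graph = graph, nodes = nodes, params = params),
            class = "residue_network")
}

#' @export
print.residue_network <- function(x, ...) {
  cat(sprintf("<residue_network kind=%s> %d nodes, %d edges\n",
              x$kind, igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

network_nodes_ca <- function(model) {
  ca <- model$atoms[model$atoms$atom == "CA", , drop = FALSE]
  res <- model$residues
  miss <- setdiff(res_key_df(res), res_key_df(ca))
  if (length(miss))
    warnf("%d residue(s) without C-alpha skipped", length(miss))
  idx <- match(res_key_df(ca), res_key_df(res))
  nodes <- res[idx, , drop = FALSE]
  nodes$x <- ca$x; nodes$y <- ca$y; nodes$z <- ca$z
  rownames(nodes) <- NULL
  nodes
}

#' Build a C-alpha contact network
#'
#' Nodes are residues with a C-alpha; an edge is drawn when the C-alpha
#' distance is strictly less than `distance_cutoff` (7 Angstrom by default)
#' and the sequence separation `|i - j|` is at least `min_separation`
#' (default 1, i.e. adjacent residues may link, capturing short-range
#' interactions). Residues on different chains are never separation-excluded.
#'
#' @param model a `structure_model`.
#' @param distance_cutoff C-alpha distance threshold in Angstrom (strict `<`).
#' @param min_separation minimum `|i - j|` along the chain.
#' @return a `residue_network` of kind `"contact"` (edge weight 1).
#' @export
build_contact_network <- function(model, distance_cutoff = 7.0,
                                  min_separation = 1) {
  nodes <- network_nodes_ca(model)
  if (!nrow(nodes)) stopf("model has no C-alpha atoms")
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  d <- sqrt(pmax(cross_dist2(xyz, xyz), 0))
  sep_ok <- outer(nodes$chain, nodes$chain, "!=") |
    abs(outer(nodes$res_seq, nodes$res_seq, "-")) >= min_separation
  adj <- d < distance_cutoff & sep_ok
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  ij <- which(adj, arr.ind = TRUE)
  labs <- node_label(nodes$chain, nodes$res_seq, nodes$icode)
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = labs)
  if (nrow(ij)) g <- igraph::add_edges(g, rbind(ij[, 1], ij[, 2]))
  igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  new_residue_network("contact", g, nodes,
                      list(distance_cutoff = distance_cutoff,
                           min_separation = min_separation))
}

# simplified pairwise potential: Lennard-Jones on element radii/epsilons plus
# Coulomb with distance-dependent dielectric eps(r) = 4r and unit formal
# charges on charged-group atoms
LJ_EPS <- c(C = 0.07, N = 0.17, O = 0.16, S = 0.25, P = 0.20)
LJ_EPS_DEFAULT <- 0.10
COULOMB_K <- 332.0636

ENERGY_CHARGES <- list(
  ASP = c(OD1 = -0.5, OD2 = -0.5), GLU = c(OE1 = -0.5, OE2 = -0.5),
  LYS = c(NZ = 1), ARG = c(NH1 = 0.5, NH2 = 0.5))

default_potential_params <- function() {
  list(radii = VDW_RADII, eps = LJ_EPS, eps_default = LJ_EPS_DEFAULT,
       coulomb_k = COULOMB_K, dielectric_scale = 4,
       charges = ENERGY_CHARGES)
}

atom_formal_charges <- function(atoms, charges = ENERGY_CHARGES) {
  q <- numeric(nrow(atoms))
  for (resn in names(charges)) {
    grp <- charges[[resn]]
    for (an in names(grp)) {
      hit <- atoms$resn == resn & atoms$atom == an
      q[hit] <- grp[[an]]
    }
  }
  q
}

pair_energy_atoms <- function(a, b, params) {
  d <- sqrt(pmax(cross_dist2(atom_coords(a), atom_coords(b)), 0))
  d[d < 0.5] <- 0.5  # guard against clashes blowing up the potential
  ri <- atom_radii(a$element); rj <- atom_radii(b$element)
  rmin <- outer(ri, rj, "+")
  ei <- params$eps[a$element]; ei[is.na(ei)] <- params$eps_default
  ej <- params$eps[b$element]; ej[is.na(ej)] <- params$eps_default
  epsij <- sqrt(outer(unname(ei), unname(ej)))
  x6 <- (rmin / d)^6
  e_lj <- epsij * (x6^2 - 2 * x6)
  qi <- atom_formal_charges(a, params$charges)
  qj <- atom_formal_charges(b, params$charges)
  e_coul <- params$coulomb_k * outer(qi, qj) /
    (params$dielectric_scale * d^2)
  sum(e_lj) + sum(e_coul)
}

#' Pairwise residue-residue interaction energy
#'
#' Approximate van der Waals plus electrostatic energy between two residues,
#' summed over heavy-atom pairs: a Lennard-Jones term with element-based
#' radii and well depths and a Coulomb term with distance-dependent
#' dielectric eps(r) = 4r and unit formal charges on charged-group atoms
#' (Asp/Glu carboxylate oxygens -0.5 each, Lys NZ +1, Arg NH1/NH2 +0.5 each;
#' His neutral). Symmetric and deterministic; absolute values are only
#' order-of-magnitude realistic and serve to weight the energy network.
#'
#' @param model a `structure_model`.
#' @param res_i,res_j residue numbers (author numbering).
#' @param chain_i,chain_j chains (default: first chain of the model).
#' @param params potential parameters (see `default_potential_params`).
#' @return interaction energy in kcal/mol.
#' @export
pair_interaction_energy <- function(model, res_i, res_j,
                                    chain_i = model$atoms$chain[1],
                                    chain_j = chain_i,
                                    params = default_potential_params()) {
  at <- heavy_atoms(model)
  a <- at[at$chain == chain_i & at$res_seq == res_i, , drop = FALSE]
  b <- at[at$chain == chain_j & at$res_seq == res_j, , drop = FALSE]
  if (!nrow(a) || !nrow(b)) stopf("residue(s) not found or without heavy atoms")
  pair_energy_atoms(a, b, params)
}

all_pair_energies <- function(model, params = default_potential_params(),
                              nodes = network_nodes_ca(model),
                              reach = 16) {
  at <- heavy_atoms(model)
  keys <- res_key_df(nodes)
  n <- nrow(nodes)
  E <- matrix(0, n, n)
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  dca <- sqrt(pmax(cross_dist2(xyz, xyz), 0))
  akey <- res_key_df(at)
  split_atoms <- split(seq_len(nrow(at)), akey)
  for (i in seq_len(n - 1)) {
    ai <- at[split_atoms[[keys[i]]], , drop = FALSE]
    for (j in seq(i + 1, n)) {
      if (dca[i, j] > reach) next  # beyond reach both terms are < 1e-3
      e <- pair_energy_atoms(ai, at[split_atoms[[keys[j]]], , drop = FALSE],
                             params)
      E[i, j] <- E[j, i] <- e
    }
  }
  dimnames(E) <- list(keys, keys)
  E
}

#' Build an energy-weighted residue network
#'
#' An edge joins two residues when the absolute pairwise interaction energy
#' (see [pair_interaction_energy()]) falls inside the inclusive band
#' `[energy_lower, energy_upper]` (defaults 0.1 and 1 kcal/mol). Edge weights
#' are the absolute energies normalised by the largest retained one, so the
#' strongest edge has weight exactly 1.
#'
#' @param model a `structure_model`.
#' @param energy_lower,energy_upper band limits in kcal/mol (inclusive).
#' @param params potential parameters.
#' @return a `residue_network` of kind `"energy"`; empty (with a warning)
#'   when no pair falls inside the band.
#' @export
build_energy_network <- function(model, energy_lower = 0.1,
                                 energy_upper = 1.0,
                                 params = default_potential_params()) {
  nodes <- network_nodes_ca(model)
  if (!nrow(nodes)) stopf("model has no C-alpha atoms")
  E <- all_pair_energies(model, params, nodes)
  absE <- abs(E)
  keep <- absE >= energy_lower & absE <= energy_upper
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  ij <- which(keep, arr.ind = TRUE)
  labs <- node_label(nodes$chain, nodes$res_seq, nodes$icode)
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = labs)
  if (nrow(ij)) {
    g <- igraph::add_edges(g, rbind(ij[, 1], ij[, 2]))
    w <- absE[ij]
    igraph::E(g)$weight <- w / max(w)
    igraph::E(g)$energy <- E[ij]
  } else {
    warnf("no residue pair inside the [%g, %g] kcal/mol band",
          energy_lower, energy_upper)
    igraph::E(g)$weight <- numeric(0)
  }
  new_residue_network("energy", g, nodes,
                      list(energy_lower = energy_lower,
                           energy_upper = energy_upper))
}

resolve_nodes <- function(network, residues, chain = NULL) {
  nm <- igraph::V(network$graph)$name
  if (is.character(residues)) {
    idx <- match(residues, nm)
  } else {
    nodes <- network$nodes
    hit <- nodes$res_seq %in% residues
    if (!is.null(chain)) hit <- hit & nodes$chain %in% chain
    idx <- match(node_label(nodes$chain[hit], nodes$res_seq[hit],
                            nodes$icode[hit]), nm)
    found <- nodes$res_seq[hit]
    if (length(setdiff(residues, found)))
      stopf("residue(s) not in network: %s",
            paste(setdiff(residues, found), collapse = ", "))
  }
  if (anyNA(idx)) stopf("residue(s) not in network")
  idx
}

#' Energy neighbours of seed residues
#'
#' Union of the direct graph neighbours of all seed residues in an
#' energy-weighted network, excluding the seeds themselves.
#'
#' @param network a `residue_network` (normally kind `"energy"`).
#' @param seeds integer residue numbers (or vertex labels `"A:72"`).
#' @param include_seeds if TRUE, return seeds union neighbours.
#' @return sorted integer vector of residue numbers.
#' @export
energy_neighbors <- function(network, seeds, include_seeds = FALSE) {
  idx <- resolve_nodes(network, seeds)
  nb <- unique(unlist(lapply(idx, function(v)
    as.integer(igraph::neighbors(network$graph, v)))))
  res <- network$nodes$res_seq[nb]
  seeds_res <- network$nodes$res_seq[idx]
  out <- if (include_seeds) union(res, seeds_res) else setdiff(res, seeds_res)
  sort(unique(out))
}

#' Hydropathy-class subnetworks of a contact network
#'
#' Induced subgraph on the residues of one hydropathy class; returns its
#' connected components with at least two members, largest first. Glycine
#' (class `none`) never participates.
#'
#' @param network a `residue_network` of kind `"contact"` built from a model
#'   with classes assigned.
#' @param hydropathy_class `"charged"`, `"hydrophobic"` or `"hydrophilic"`.
#' @return list of sorted integer vectors (residue numbers), size descending.
#' @export
class_subnetworks <- function(network, hydropathy_class) {
  nodes <- network$nodes
  if (all(is.na(nodes$hydropathy_class)))
    stopf("assign_residue_classes() must be run before class_subnetworks()")
  if (hydropathy_class == "none") return(list())  # Gly never participates
  keep <- which(nodes$hydropathy_class == hydropathy_class)
  if (length(keep) < 2) return(list())
  sub <- igraph::induced_subgraph(network$graph, keep)
  comp <- igraph::components(sub)
  out <- lapply(which(comp$csize >= 2), function(k) {
    labs <- igraph::V(sub)$name[comp$membership == k]
    sort(nodes$res_seq[match(labs, node_label(nodes$chain, nodes$res_seq,
                                              nodes$icode))])
  })
  out[order(-vapply(out, length, integer(1)))]
}

#' Node centralities of a residue network
#'
#' Closeness uses the component-scaled convention
#' `closeness(v) = (reach(v)/(n-1)) * (reach(v)/sum of d(v,u))` over the
#' nodes reachable from `v`, which equals the classic `(n-1)/sum d` on a
#' connected graph and degrades gracefully on disconnected ones (isolated
#' nodes score 0). Betweenness is exact shortest-path counting, unnormalised.
#' ANN degree is the mean degree of a node's neighbours (0 if isolated).
#' Contact networks are treated as unweighted; with `weighted = TRUE` an
#' energy network uses 1/weight as edge length.
#'
#' @param network a `residue_network`.
#' @param weighted use inverse edge weights as path lengths.
#' @return a `centrality_report` data frame: `node`, `res_seq`, `closeness`,
#'   `betweenness`, `ann_degree`; component sizes in `attr(, "components")`.
#' @export
centralities <- function(network, weighted = FALSE) {
  g <- network$graph
  n <- igraph::vcount(g)
  if (n < 2) stopf("network needs at least 2 nodes")
  w <- if (weighted && network$kind == "energy" && igraph::ecount(g) > 0)
    1 / igraph::E(g)$weight else rep(1, igraph::ecount(g))
  d <- igraph::distances(g, weights = w)
  reach <- rowSums(is.finite(d)) - 1
  sums <- apply(d, 1, function(r) sum(r[is.finite(r) & r > 0]))
  closeness <- ifelse(reach > 0, (reach / (n - 1)) * (reach / sums), 0)
  btw <- igraph::betweenness(g, weights = w, directed = FALSE,
                             normalized = FALSE)
  deg <- igraph::degree(g)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  nbsum <- as.numeric(adj %*% deg)
  ann <- ifelse(deg > 0, nbsum / deg, 0)
  out <- data.frame(node = igraph::V(g)$name,
                    res_seq = network$nodes$res_seq,
                    closeness = as.numeric(closeness),
                    betweenness = as.numeric(btw),
                    ann_degree = ann,
                    stringsAsFactors = FALSE)
  comp <- igraph::components(g)
  attr(out, "components") <- sort(comp$csize, decreasing = TRUE)
  attr(out, "convention") <- "component-scaled closeness; unnormalized betweenness"
  class(out) <- c("centrality_report", class(out))
  out
}
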