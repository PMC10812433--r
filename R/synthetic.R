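# evaluate code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# compact planar residue template: heavy atoms within `spread` of the centre,
# all at the same z, so inter-residue atom distances track centre distances
residue_template <- function(resn, chain, res_seq, centre, spread = 0.5) {
  atoms <- c("N", "CA", "C", "O", if (resn != "GLY") "CB")
  offs <- rbind(N = c(-1, 0), CA = c(0, 0), C = c(1, 0),
                O = c(0, 1), CB = c(0, -1)) * spread
  offs <- offs[atoms, , drop = FALSE]
  data.frame(chain = chain, res_seq = res_seq, icode = "", resn = resn,
             atom = atoms,
             element = substr(atoms, 1, 1),
             x = centre[1] + offs[, 1], y = centre[2] + offs[, 2],
             z = centre[3], occupancy = 1, stringsAsFactors = FALSE)
}

CLASS_MEMBERS <- list(
  charged = c("ASP", "GLU", "LYS", "ARG", "HIS"),
  polar = c("ASN", "GLN", "SER", "THR", "TYR"),
  apolar = c("ALA", "VAL", "LEU", "ILE", "PHE", "MET", "PRO", "TRP"))

sample_resn <- function(class) sample(CLASS_MEMBERS[[class]], 1)

#' Specification for a synthetic two-chain "pegboard" complex
#'
#' Residues sit on two parallel sparse grids. Each requested interfacial
#' contact is realised by a ligand residue placed directly above its receptor
#' partner at `contact_distance` (5 Angstrom, inside the 5.5 cutoff); every
#' other cross-side residue pair is at least `noncontact_distance` apart
#' (9 Angstrom or more). Extra non-contact residues realise a prescribed
#' non-interacting-surface composition: on the sparse grid every residue is
#' fully exposed, so the NIS set is exactly the non-contact residues.
#'
#' @param ic_counts named numeric over `cc, cp, ca, pp, pa, aa` (class-pair
#'   contact counts: charged/charged, charged/polar, ...).
#' @param nis_counts named numeric over `charged, polar, apolar`: extra
#'   non-contact residues (split between the two chains).
#' @param contact_distance,noncontact_distance geometry parameters (A).
#' @param seed RNG seed (residue-name sampling).
#' @return a `toy_complex_spec`.
#' @export
toy_complex_spec <- function(ic_counts = c(cc = 2, cp = 0, ca = 3, pp = 1,
                                           pa = 4, aa = 0),
                             nis_counts = c(charged = 4, polar = 4, apolar = 4),
                             contact_distance = 5.0,
                             noncontact_distance = 9.0,
                             seed = 1) {
  short <- c(cc = "charged_charged", cp = "charged_polar",
             ca = "charged_apolar", pp = "polar_polar",
             pa = "polar_apolar", aa = "apolar_apolar")
  ic <- setNames(numeric(6), names(short))
  ic[names(ic_counts)] <- ic_counts
  bad <- setdiff(names(ic_counts), names(short))
  if (length(bad)) stopf("unknown ic_counts keys: %s", paste(bad, collapse = ", "))
  nis <- setNames(numeric(3), c("charged", "polar", "apolar"))
  nis[names(nis_counts)] <- nis_counts
  stopifnot(all(ic >= 0), all(nis >= 0), contact_distance < 5.5,
            noncontact_distance >= 9)
  structure(list(ic_counts = ic, ic_long = unname(short),
                 nis_counts = nis, contact_distance = contact_distance,
                 noncontact_distance = noncontact_distance, seed = seed),
            class = "toy_complex_spec")
}

#' Generate a pegboard complex with an exactly known contact profile
#'
#' @param spec a [toy_complex_spec()].
#' @return list with `model` (chains A = receptor, B = ligand, classes
#'   assigned), `profile` (the oracle `interface_contact_profile`, computed
#'   from the spec's bookkeeping rather than from geometry), and the chain
#'   assignments.
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  with_seed(spec$seed, {
    pair_classes <- do.call(rbind, lapply(seq_along(spec$ic_counts), function(k) {
      n <- spec$ic_counts[k]
      if (n == 0) return(NULL)
      cls <- strsplit(spec$ic_long[k], "_")[[1]]
      # randomise which side carries which class of an unordered pair
      t(vapply(seq_len(n), function(i) sample(cls), character(2)))
    }))
    n_pairs <- if (is.null(pair_classes)) 0 else nrow(pair_classes)

    grid_x <- function(i) 10 * (i - 1)
    rec <- list(); lig <- list()
    for (i in seq_len(n_pairs)) {
      rec[[i]] <- residue_template(sample_resn(pair_classes[i, 1]), "A", i,
                                   c(grid_x(i), 0, 0))
      lig[[i]] <- residue_template(sample_resn(pair_classes[i, 2]), "B", i,
                                   c(grid_x(i), 0, spec$contact_distance))
    }
    # extra (NIS) residues, alternating sides, far from every cross-side atom
    extra_classes <- rep(names(spec$nis_counts), times = spec$nis_counts)
    n_rec_extra <- 0; n_lig_extra <- 0
    for (k in seq_along(extra_classes)) {
      resn <- sample_resn(extra_classes[k])
      if (k %% 2 == 1) {
        n_rec_extra <- n_rec_extra + 1
        i <- n_pairs + n_rec_extra
        rec[[i]] <- residue_template(resn, "A", i, c(grid_x(i), 0, 0))
      } else {
        n_lig_extra <- n_lig_extra + 1
        i <- n_pairs + n_lig_extra
        lig[[i]] <- residue_template(resn, "B", i,
                                     c(grid_x(n_lig_extra), 0, 14))
      }
    }
    if (!length(rec)) stopf("spec generates an empty receptor chain")
    atoms <- do.call(rbind, c(rec, lig))
    model <- assign_residue_classes(new_structure_model(atoms, "toy_complex"))

    rt <- model$residues
    ckey <- res_key_df(rt)
    as_set <- function(chain, idx) {
      hit <- rt$chain == chain & rt$res_seq %in% idx
      out <- rt[hit, c("chain", "res_seq", "icode", "resn")]
      rownames(out) <- NULL
      out
    }
    nis_tab <- table(factor(rep(names(spec$nis_counts),
                                times = spec$nis_counts),
                            levels = c("charged", "polar", "apolar")))
    nis_percent <- setNames(numeric(3), c("charged", "polar", "apolar"))
    if (sum(nis_tab) > 0) nis_percent[] <- 100 * as.numeric(nis_tab) / sum(nis_tab)
    oracle <- structure(list(
      ic_counts = setNames(as.integer(spec$ic_counts), spec$ic_long),
      nis_percent = nis_percent,
      contact_residues_receptor = as_set("A", seq_len(n_pairs)),
      contact_residues_ligand = as_set("B", seq_len(n_pairs)),
      n_contacts = n_pairs,
      params = list(contact_cutoff = 5.5, source = "generator bookkeeping")),
      class = "interface_contact_profile")
    list(model = model, profile = oracle,
         receptor_chains = "A", ligand_chains = "B")
  })
}

#' Specification for a synthetic single-chain fold realising a target graph
#'
#' C-alpha positions are laid out so that the 7-Angstrom contact graph equals
#' the requested adjacency exactly: edge pairs end up at 5.5-6.1 Angstrom and
#' non-edges at 8.5 Angstrom or more (margins inside the 5.5-6.5 / >= 8
#' guarantees). The layout is found by stress minimisation from a spectral
#' start and verified; unrealizable graphs are rejected.
#'
#' @param edges 2-column integer matrix (or data frame) of node pairs, or an
#'   empty matrix for an edgeless graph.
#' @param n_nodes number of residues (defaults to the largest node index).
#' @param resn character vector of 3-letter residue names per node (default
#'   all ALA).
#' @param seed RNG seed for layout restarts.
#' @return a `toy_fold_spec`.
#' @export
toy_fold_spec <- function(edges, n_nodes = if (length(edges)) max(edges) else 0,
                          resn = NULL, seed = 1) {
  edges <- if (length(edges)) {
    e <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(e) <- "integer"
    t(apply(e, 1, sort))
  } else matrix(integer(0), 0, 2)
  if (nrow(edges) && (any(edges < 1) || any(edges > n_nodes)))
    stopf("edge endpoints outside 1..n_nodes")
  if (nrow(edges) && any(edges[, 1] == edges[, 2])) stopf("self edges not allowed")
  edges <- unique(edges)
  resn <- resn %||% rep("ALA", n_nodes)
  stopifnot(length(resn) == n_nodes, n_nodes >= 1)
  structure(list(edges = edges, n_nodes = n_nodes, resn = toupper(resn),
                 seed = seed),
            class = "toy_fold_spec")
}

fold_layout <- function(spec, edge_target = 5.7, edge_lo = 5.5, edge_hi = 6.1,
                        nonedge_min = 8.5, restarts = 25) {
  n <- spec$n_nodes
  if (n == 1) return(matrix(0, 1, 3))
  g <- igraph::make_graph(t(spec$edges), n = n, directed = FALSE)
  gd <- igraph::distances(g)
  gd[!is.finite(gd)] <- max(gd[is.finite(gd)]) + 2
  target <- gd * edge_target
  is_edge <- matrix(FALSE, n, n)
  if (nrow(spec$edges)) is_edge[spec$edges] <- is_edge[spec$edges[, 2:1]] <- TRUE
  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) seq(i + 1, n)))
  e_flag <- is_edge[cbind(pair_i, pair_j)]
  rest <- nonedge_min + 0.7  # aim comfortably past the verification margin

  objective <- function(par) {
    X <- matrix(par, n, 3)
    dx <- X[pair_i, ] - X[pair_j, ]
    d <- sqrt(rowSums(dx^2)); d[d < 1e-6] <- 1e-6
    fe <- (d[e_flag] - edge_target)^2
    dn <- d[!e_flag]
    fn <- pmax(0, rest - dn)^2
    val <- sum(fe) + sum(fn)
    gcoef <- numeric(length(d))
    gcoef[e_flag] <- 2 * (d[e_flag] - edge_target) / d[e_flag]
    gcoef[!e_flag] <- ifelse(dn < rest, -2 * (rest - dn) / dn, 0)
    gv <- dx * gcoef
    G <- matrix(0, n, 3)
    idx <- factor(c(pair_i, pair_j), levels = seq_len(n))
    for (k in 1:3) {
      s <- tapply(c(gv[, k], -gv[, k]), idx, sum)
      s[is.na(s)] <- 0
      G[, k] <- as.numeric(s)
    }
    attr(val, "gradient") <- as.numeric(G)
    val
  }
  fn <- function(p) as.numeric(objective(p))
  gr <- function(p) attr(objective(p), "gradient")

  verify <- function(X) {
    d <- sqrt(pmax(cross_dist2(X, X), 0))
    de <- d[cbind(pair_i, pair_j)]
    all(de[e_flag] >= edge_lo & de[e_flag] <= edge_hi) &&
      all(de[!e_flag] >= nonedge_min)
  }

  mds <- suppressWarnings(stats::cmdscale(target, k = min(3, n - 1)))
  if (ncol(mds) < 3) mds <- cbind(mds, matrix(0, n, 3 - ncol(mds)))
  for (r in seq_len(restarts)) {
    X0 <- mds + matrix(stats::rnorm(n * 3, sd = if (r == 1) 0.01 else r * 0.4),
                       n, 3)
    opt <- stats::optim(as.numeric(X0), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = 1000))
    X <- matrix(opt$par, n, 3)
    if (verify(X)) return(X)
  }
  stopf("target graph could not be realised in 3-D under the placement rule")
}

#' Generate a single-chain fold whose contact graph is known exactly
#'
#' @param spec a [toy_fold_spec()].
#' @return list with `model` (chain A, classes assigned), `graph` (the oracle
#'   edge matrix) and `adjacency` (oracle neighbour list per residue).
#' @export
make_toy_fold <- function(spec) {
  stopifnot(inherits(spec, "toy_fold_spec"))
  with_seed(spec$seed, {
    X <- fold_layout(spec)
    atoms <- do.call(rbind, lapply(seq_len(spec$n_nodes), function(i)
      residue_template(spec$resn[i], "A", i, X[i, ], spread = 0.4)))
    model <- assign_residue_classes(new_structure_model(atoms, "toy_fold"))
    adj <- lapply(seq_len(spec$n_nodes), function(i) {
      nb <- c(spec$edges[spec$edges[, 1] == i, 2],
              spec$edges[spec$edges[, 2] == i, 1])
      sort(unique(nb))
    })
    list(model = model, graph = spec$edges, adjacency = adj)
  })
}

#' Specification for a synthetic recognition ensemble with planted hot spots
#'
#' Emulates an ensemble of receptor-ligand complexes (default 38, the size of
#' the experimentally confirmed ligand set) over a receptor of
#' `receptor_length` residues (default 107). In each complex, a planted
#' hot-spot residue becomes a contact with probability `p_hot` and any other
#' residue with `p_bg`; one interaction category is drawn per complex.
#'
#' @param n_complexes number of complexes.
#' @param receptor_length receptor size in residues.
#' @param planted integer residue numbers of the planted hot spots.
#' @param p_hot,p_bg per-complex contact probabilities.
#' @param category_probs named probabilities over the interaction categories.
#' @param seed RNG seed.
#' @return an `ensemble_spec`.
#' @export
ensemble_spec <- function(n_complexes = 38, receptor_length = 107,
                          planted = c(1, 3, 10, 14, 30, 35, 72, 88, 96, 103),
                          p_hot = 0.8, p_bg = 0.05,
                          category_probs = c(covalent = 0.35,
                                             strong_noncovalent = 0.45,
                                             weak = 0.20),
                          seed = 1) {
  stopifnot(p_hot >= 0, p_hot <= 1, p_bg >= 0, p_bg <= 1,
            all(planted >= 1), all(planted <= receptor_length))
  bad <- setdiff(names(category_probs), ENSEMBLE_CATEGORIES)
  if (length(bad)) stopf("unknown category label(s): %s",
                         paste(bad, collapse = ", "))
  structure(list(n_complexes = n_complexes,
                 receptor_length = receptor_length,
                 planted = sort(unique(as.integer(planted))),
                 p_hot = p_hot, p_bg = p_bg,
                 category_probs = category_probs / sum(category_probs),
                 seed = seed),
            class = "ensemble_spec")
}

#' Draw a synthetic ensemble of per-complex contact sets
#'
#' @param spec an [ensemble_spec()].
#' @return list of [ensemble_record()]s; identical for identical specs.
#' @export
make_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  with_seed(spec$seed, {
    p <- rep(spec$p_bg, spec$receptor_length)
    p[spec$planted] <- spec$p_hot
    lapply(seq_len(spec$n_complexes), function(k) {
      hit <- stats::runif(spec$receptor_length) < p
      cat <- sample(names(spec$category_probs), 1,
                    prob = spec$category_probs)
      ensemble_record(complex_id = sprintf("cplx%02d", k),
                      ligand_id = sprintf("ligand%02d", k),
                      category = cat,
                      contacts = which(hit))
    })
  })
}
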