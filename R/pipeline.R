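RUN_CONFIG_KEYS <- c("complexes", "receptor_model", "receptor_chain",
                     "contact_cutoff", "network_cutoff", "min_separation",
                     "energy_lower", "energy_upper", "hotspot_threshold",
                     "sasa", "sign_convention", "temperature", "align_to",
                     "seed", "out_dir")

#' Validate and normalise a pipeline run configuration
#'
#' @param config a named list (or path to a JSON file holding one). Required:
#'   `complexes` (list of entries with `path`, `receptor_chains`,
#'   `ligand_chains`, optional `category` and `id`) and `out_dir`. All
#'   thresholds default to the package-wide conventions and are echoed into
#'   the output metadata. Unknown keys are rejected.
#' @return a `run_config` list.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown)) stopf("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  if (!length(config$complexes)) stopf("config must list at least one complex")
  defaults <- list(contact_cutoff = 5.5, network_cutoff = 7.0,
                   min_separation = 1, energy_lower = 0.1, energy_upper = 1.0,
                   hotspot_threshold = 1.0,
                   sasa = list(probe_radius = 1.4, n_points = 480,
                               surface_threshold = 0.25),
                   sign_convention = "negated", temperature = 298.15,
                   seed = 1, receptor_model = NULL, receptor_chain = NULL,
                   align_to = NULL)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (is.null(config$out_dir)) stopf("config must set out_dir")
  config$complexes <- lapply(seq_along(config$complexes), function(i) {
    cx <- config$complexes[[i]]
    for (k in c("path", "receptor_chains", "ligand_chains"))
      if (is.null(cx[[k]])) stopf("complex %d lacks '%s'", i, k)
    cx$receptor_chains <- unlist(cx$receptor_chains)
    cx$ligand_chains <- unlist(cx$ligand_chains)
    cx$category <- unlist(cx$category) %||% "unspecified"
    cx$id <- cx$id %||% sprintf("complex%02d", i)
    cx
  })
  structure(config, class = "run_config")
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  message(sprintf("[contactmap] stage %s ...", name))
  out <- tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  message(sprintf("[contactmap] stage %s done (%.2fs)", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full interface-analysis pipeline
#'
#' Stages: per-complex contact profiling and binding-energy prediction;
#' ensemble contact-frequency aggregation and hot-spot calling (per
#' interaction category); receptor contact and energy networks with
#' centralities; contact-area assembly (hot spots + energy neighbours,
#' partitioned by category); optional projection onto a homolog. All
#' thresholds in effect are echoed into `summary.json`.
#'
#' @param config a [run_config()] (or list / JSON path accepted by it).
#' @return invisibly, a list with the in-memory results and the paths of the
#'   TSV/JSON files written under `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  coeffs <- binding_coefficients(sign_convention = cfg$sign_convention)
  paths <- list()

  profiles <- stage("profile", {
    rows <- list(); records <- list()
    for (cx in cfg$complexes) {
      model <- assign_residue_classes(read_pdb(cx$path))
      prof <- contact_profile(model, cx$receptor_chains, cx$ligand_chains,
                              cfg$contact_cutoff, cfg$sasa)
      dg <- predict_dG(prof, coeffs)
      rows[[cx$id]] <- data.frame(
        id = cx$id, category = paste(cx$category, collapse = "+"),
        t(as.matrix(prof$ic_counts)),
        nis_charged = prof$nis_percent[["charged"]],
        nis_polar = prof$nis_percent[["polar"]],
        nis_apolar = prof$nis_percent[["apolar"]],
        n_contacts = prof$n_contacts, dG = dg,
        KD = dG_to_KD(dg, cfg$temperature),
        stringsAsFactors = FALSE, check.names = FALSE)
      records[[cx$id]] <- ensemble_record(
        cx$id, cx$id, cx$category,
        prof$contact_residues_receptor$res_seq)
    }
    list(table = do.call(rbind, rows), records = records)
  })
  paths$profiles <- write_tsv(profiles$table, file.path(cfg$out_dir, "profiles.tsv"))

  freq <- stage("hotspots", {
    tab <- aggregate_contacts(profiles$records)
    hs <- list()
    for (cat in c("covalent", "strong_noncovalent", "all")) {
      col <- paste0("pct_", cat)
      hs[[cat]] <- if (any(tab[[col]] > 0))
        call_hotspots(tab, cat, cfg$hotspot_threshold) else integer(0)
      tab[[paste0("hotspot_", cat)]] <- tab$residue %in% hs[[cat]]
    }
    list(table = tab, hotspots = hs)
  })
  paths$frequency <- write_tsv(freq$table, file.path(cfg$out_dir, "frequency.tsv"))

  rec_path <- cfg$receptor_model %||% cfg$complexes[[1]]$path
  rec_chain <- cfg$receptor_chain %||% cfg$complexes[[1]]$receptor_chains[1]
  receptor <- assign_residue_classes(read_pdb(rec_path, keep_chains = rec_chain))

  nets <- stage("network", {
    cn <- build_contact_network(receptor, cfg$network_cutoff, cfg$min_separation)
    en <- build_energy_network(receptor, cfg$energy_lower, cfg$energy_upper)
    list(contact = cn, energy = en, cent = centralities(cn))
  })
  edge_df <- function(net) {
    e <- igraph::as_data_frame(net$graph, what = "edges")
    if (!nrow(e)) e <- data.frame(from = character(0), to = character(0),
                                  weight = numeric(0))
    e[, c("from", "to", "weight")]
  }
  paths$contact_edges <- write_tsv(edge_df(nets$contact),
                                   file.path(cfg$out_dir, "network_contact_edges.tsv"))
  paths$energy_edges <- write_tsv(edge_df(nets$energy),
                                  file.path(cfg$out_dir, "network_energy_edges.tsv"))
  paths$centralities <- write_tsv(as.data.frame(nets$cent),
                                  file.path(cfg$out_dir, "centralities.tsv"))

  areas <- stage("areas", {
    on_net <- function(x) intersect(x, nets$energy$nodes$res_seq)
    assemble_areas(on_net(freq$hotspots$covalent),
                   on_net(freq$hotspots$strong_noncovalent), nets$energy)
  })
  paths$areas <- write_tsv(as.data.frame(areas), file.path(cfg$out_dir, "areas.tsv"))
  annot <- data.frame(chain = rec_chain, resnum = areas$residue,
                      label = areas$label)
  paths$annotations <- write_tsv(annot, file.path(cfg$out_dir, "areas_annotations.tsv"))

  projection <- NULL
  if (!is.null(cfg$align_to)) {
    projection <- stage("align", {
      target <- read_pdb(cfg$align_to$path)
      aln <- align_structures(receptor, target, chain_a = rec_chain,
                              chain_b = cfg$align_to$chain %||%
                                target$atoms$chain[1])
      rows <- lapply(c("only_C", "only_sNC", "common"), function(lab) {
        src <- areas$residue[areas$label == lab]
        if (!length(src)) return(NULL)
        proj <- project_residues(aln, src)
        data.frame(label = lab,
                   source = paste(src, collapse = ","),
                   target = paste(proj, collapse = ","),
                   unmapped = paste(attr(proj, "unmapped"), collapse = ","))
      })
      list(alignment = aln, table = do.call(rbind, rows))
    })
    paths$alignment <- write_tsv(projection$table,
                                 file.path(cfg$out_dir, "alignment.tsv"))
  }

  summary <- list(
    package = "contactmap",
    config = cfg[setdiff(RUN_CONFIG_KEYS, c("complexes", "align_to"))],
    n_complexes = length(cfg$complexes),
    hotspots = lapply(freq$hotspots, as.integer),
    area_counts = as.list(table(areas$label)),
    rmsd = if (!is.null(projection)) projection$alignment$rmsd else NULL,
    conventions = list(
      ddg = "dG_wt - dG_mut; |ddG| > 2 kcal/mol flags a thermodynamic hot spot",
      closeness = "component-scaled", nis = "surface non-interface residues, both chains pooled"))
  paths$summary <- file.path(cfg$out_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = 6, pretty = TRUE, null = "null")
  message("[contactmap] pipeline complete")
  invisible(list(profiles = profiles$table, frequency = freq$table,
                 hotspots = freq$hotspots, networks = nets, areas = areas,
                 projection = projection, paths = paths))
}
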