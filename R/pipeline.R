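#' Default run configuration
#'
#' Nested parameter list for [run_pipeline()]; every value defaults to the
#' module's declared default. Unknown keys in a user config are rejected.
#'
#' @return nested list of stage parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "cna", "segment", "enrich"),
    out_dir = "tumorevo_run",
    simulate = list(cells_per_clone = 200L, n_normal_cells = 150L),
    cna = list(min_mean_expression = 1.0, window = 5L,
               winsorize = c(-3, 3), cc_threshold = 1.0,
               n_components = 20L, k = NULL,
               gamma_grid = seq(0.4, 1.6, by = 0.2), n_runs = 10L),
    segment = list(n_meta = 5L, frac = 0.5, delta = 0.5, tau = 1e-3,
                   sigma = NULL, min_seg_bins = 5L, flank = Inf,
                   min_community_size = 10L)
  )
}

merge_config <- function(user, base = default_config(), path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) stop("unknown config key: ", full)
    if (is.list(base[[key]]) && is.list(user[[key]])) {
      base[[key]] <- merge_config(user[[key]], base[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Read a JSON run configuration
#'
#' @param path JSON file with (a subset of) the [default_config()] keys;
#'   unknown keys are rejected with the key named.
#' @return merged configuration list.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  merge_config(user)
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in order (simulate, cna, segment, enrich)
#' on the default planted-CNA scenario, writing all artifacts plus a JSON
#' run manifest (seed, parameters, md5 checksums of outputs) under
#' `config$out_dir`. Identical configs produce identical outputs.
#'
#' @param config a configuration list (see [default_config()] /
#'   [read_config()]).
#' @return list of in-memory stage results, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- merge_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  res <- list()
  manifest <- list(seed = config$seed, stages = stages,
                   parameters = config[c("simulate", "cna", "segment")])

  if ("simulate" %in% stages) {
    scen <- default_cna_scenario(seed = stage_seed(config$seed, "simulate"),
                                 cells_per_clone = config$simulate$cells_per_clone,
                                 n_normal_cells = config$simulate$n_normal_cells)
    res$sim <- simulate_expression(scen)
    write_counts(res$sim$counts, file.path(config$out_dir, "counts"))
  }
  if ("cna" %in% stages) {
    if (is.null(res$sim)) stop("stage 'cna' needs stage 'simulate' first")
    cc <- config$cna
    nm <- normalize_to_reference(res$sim$counts)
    phases <- score_cell_cycle(nm, res$sim$truth$g1s_genes,
                               res$sim$truth$g2m_genes,
                               threshold = cc$cc_threshold)
    binned <- bin_genes(nm, cc$min_mean_expression)
    z <- winsorize(rolling_median_smooth(zscore_bins(binned), cc$window),
                   cc$winsorize[1], cc$winsorize[2])
    emb <- pca_project(z, phases$cycling, cc$n_components)
    g <- build_knn_graph(emb, cc$k)
    part <- detect_communities(g, cc$gamma_grid, cc$n_runs,
                               seed = stage_seed(config$seed, "communities"))
    res$cna <- list(normalized = nm, phases = phases, z = z,
                    embedding = emb, partition = part)
    write_tsv(data.frame(cell = names(part$membership),
                         community = part$membership,
                         gamma = part$gamma, row.names = NULL),
              file.path(config$out_dir, "communities.tsv"))
    write_tsv(phases, file.path(config$out_dir, "cell_cycle.tsv"))
  }
  if ("segment" %in% stages) {
    if (is.null(res$cna)) stop("stage 'segment' needs stage 'cna' first")
    sc <- config$segment
    baseline <- res$sim$truth$cells$cell[res$sim$truth$cells$clone == "normal"]
    mc <- make_metacells(res$sim$counts, res$cna$partition, baseline,
                         n_meta = sc$n_meta, frac = sc$frac,
                         seed = stage_seed(config$seed, "metacells"),
                         min_community_size = sc$min_community_size,
                         min_mean_expression = config$cna$min_mean_expression,
                         window = config$cna$window,
                         wins_lo = config$cna$winsorize[1],
                         wins_hi = config$cna$winsorize[2])
    prof <- call_cna_profiles(mc, hmm_params(sc$delta, sc$sigma, sc$tau),
                              min_seg_bins = sc$min_seg_bins,
                              flank = sc$flank)
    res$segment <- list(metacells = mc, profiles = prof)
    write_segments_bed(prof, file.path(config$out_dir, "segments.tsv"))
  }
  if ("enrich" %in% stages) {
    if (is.null(res$cna)) stop("stage 'enrich' needs stage 'cna' first")
    memb <- res$cna$partition$membership
    clusters <- setNames(res$sim$truth$cells$clone, res$sim$truth$cells$cell)
    res$enrich <- enrich_communities(memb, clusters[names(memb)])
    write_tsv(res$enrich, file.path(config$out_dir, "enrichment.tsv"))
  }

  outs <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  outs <- outs[!grepl("manifest\\.json$", outs)]
  manifest$checksums <- as.list(tools::md5sum(outs))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(res)
}
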