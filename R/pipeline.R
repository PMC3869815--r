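#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis. The defaults
#' reproduce the conventional study design: sparsity sweep 0.36-0.50 in
#' steps of 0.01, hub summary at sparsity 0.36, FDR level 0.05 for the
#' edge tests, 100 matched random networks and 1000 permutations.
#'
#' @param cohort a [cohort_spec()] for synthetic input, or `NULL` when
#'   `inputs` is given.
#' @param inputs `NULL`, or a list of two lists (`group1`, `group2`), each
#'   with `thickness`, `covariates`, `atlas` file paths for
#'   [load_thickness_table()].
#' @param grid sparsity sweep, a [sparsity_grid()].
#' @param hub_sparsity single sparsity for the hub summary.
#' @param fdr_q FDR level for the edge-wise comparison.
#' @param n_random matched-random-network ensemble size.
#' @param n_perm permutation count.
#' @param global_metrics,nodal_metrics metrics for the permutation sweep.
#' @param tail pre-declared tail for the permutation tests.
#' @param ranking edge-ranking mode for binarization.
#' @param eglob_ratio_min small-world comparability tolerance.
#' @param seed master seed; every random stage derives its own stream from
#'   it via [derive_seed()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, inputs = NULL,
                            grid = sparsity_grid(), hub_sparsity = 0.36,
                            fdr_q = 0.05, n_random = 100, n_perm = 1000,
                            global_metrics = c("E_glob", "E_loc", "B", "V_glob"),
                            nodal_metrics = c("betweenness", "regional_efficiency"),
                            tail = "upper",
                            ranking = c("signed", "absolute"),
                            eglob_ratio_min = 0.5, seed = 1L) {
  ranking <- match.arg(ranking)
  if (is.null(cohort) && is.null(inputs))
    stop_covnet("pipeline_config needs either a cohort spec or input paths")
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_spec"))
  if (any(c(n_random, n_perm) < 1)) stop_covnet("counts must be positive")
  if (hub_sparsity <= 0 || hub_sparsity > 1)
    stop_covnet("hub_sparsity must be in (0, 1]")
  sparsity_grid(grid[1], grid[length(grid)],
                by = if (length(grid) > 1) grid[2] - grid[1] else 0.01)
  structure(list(cohort = cohort, inputs = inputs, grid = grid,
                 hub_sparsity = hub_sparsity, fdr_q = fdr_q,
                 n_random = as.integer(n_random), n_perm = as.integer(n_perm),
                 global_metrics = global_metrics, nodal_metrics = nodal_metrics,
                 tail = tail, ranking = ranking,
                 eglob_ratio_min = eglob_ratio_min, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()] arguments; a `cohort:` block is
#' passed to [cohort_spec()] (with `planted_edges:` as a list of
#' `[i, j, r1, r2]` rows), `grid:` as `[from, to, by]`.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- NULL
  if (!is.null(y$cohort)) {
    ca <- y$cohort
    if (!is.null(ca$planted_edges)) {
      pe <- do.call(rbind, lapply(ca$planted_edges, function(r)
        data.frame(i = r[[1]], j = r[[2]], r1 = r[[3]], r2 = r[[4]])))
      ca$planted_edges <- pe
    }
    if (!is.null(ca$n_subjects)) ca$n_subjects <- unlist(ca$n_subjects)
    if (!is.null(ca$age_range)) ca$age_range <- unlist(ca$age_range)
    cohort <- do.call(cohort_spec, ca)
  }
  grid <- if (!is.null(y$grid)) do.call(sparsity_grid, as.list(unlist(y$grid)))
          else sparsity_grid()
  args <- y[setdiff(names(y), c("cohort", "grid"))]
  do.call(pipeline_config, c(list(cohort = cohort, inputs = y$inputs,
                                  grid = grid),
                             args[setdiff(names(args), "inputs")]))
}

#' Run the full structural covariance network analysis
#'
#' Executes every stage in order - data (simulate or load), per-group
#' residualization and correlation, edge-wise group comparison with FDR
#' control, sparsity sweep of binarized networks with largest-component
#' and global-metric curves, hub identification and hemisphere/lobe
#' summary at the hub sparsity, small-world assessment against matched
#' random networks at every grid sparsity, and the permutation inference
#' sweep - writing all intermediate artifacts plus a machine-readable
#' `report.json` and a deterministic `run.log` under `out_dir`. Given the
#' same configuration (including the master seed) two runs produce
#' byte-identical bundles.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param quiet suppress per-stage messages.
#' @return invisibly, the report list (also written as
#'   `<out_dir>/report.json`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  stage <- function(name, code) {
    if (!quiet) message("[covnet] stage: ", name)
    t0 <- Sys.time()
    out <- tryCatch(force(code), error = function(e)
      stop_covnet(sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
    if (!quiet)
      message(sprintf("[covnet]   done in %.2fs",
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    log_lines <<- c(log_lines, paste0("stage: ", name))
    out
  }

  data <- stage("data", {
    if (!is.null(config$cohort)) {
      cohort <- generate_cohort(config$cohort)
    } else {
      cohort <- list(
        group1 = do.call(load_thickness_table, config$inputs$group1),
        group2 = do.call(load_thickness_table, config$inputs$group2))
    }
    write_thickness_dataset(cohort$group1, out_dir, "group1")
    write_thickness_dataset(cohort$group2, out_dir, "group2")
    cohort
  })
  atlas <- data$group1$atlas

  cors <- stage("correlation", {
    cors <- lapply(data, function(d) correlation_matrix(residualize(d)))
    write_correlation_matrix(cors$group1, file.path(out_dir, "group1_correlation.tsv"))
    write_correlation_matrix(cors$group2, file.path(out_dir, "group2_correlation.tsv"))
    cors
  })

  edges <- stage("edge_comparison", {
    e <- compare_edges(cors$group1, cors$group2, q = config$fdr_q)
    write_edge_comparison(e, file.path(out_dir, "edge_comparison.tsv"))
    e
  })

  sweeps <- stage("network_sweep", {
    sw <- lapply(cors, function(cm)
      sweep_networks(cm, config$grid, config$ranking))
    curves <- do.call(rbind, lapply(names(sw), function(g) {
      do.call(rbind, lapply(sw[[g]], function(net) {
        gm <- global_metrics(net)
        data.frame(group = g, sparsity = net$sparsity,
                   largest_component = largest_component_size(net),
                   E_glob = gm$E_glob, E_loc = gm$E_loc,
                   mean_betweenness = gm$mean_betweenness, V_glob = gm$V_glob)
      }))
    }))
    rownames(curves) <- NULL
    write_tsv(curves, file.path(out_dir, "sparsity_curves.tsv"))
    list(networks = sw, curves = curves)
  })

  hubs <- stage("hubs", {
    hub_sets <- lapply(names(cors), function(g) {
      net <- binarize_at_sparsity(cors[[g]], config$hub_sparsity, config$ranking)
      write_network(net, file.path(out_dir, sprintf("network_s%0.2f_%s.tsv",
                                                    config$hub_sparsity, g)))
      list(net = net, table = nodal_metrics(net, atlas),
           hubs = identify_hubs(normalized_betweenness(betweenness(net))))
    })
    names(hub_sets) <- names(cors)
    write_tsv(hub_sets$group1$table, file.path(out_dir, "group1_nodal_metrics.tsv"))
    write_tsv(hub_sets$group2$table, file.path(out_dir, "group2_nodal_metrics.tsv"))
    summary <- summarize_hubs(hub_sets$group1$hubs, atlas, hub_sets$group2$hubs)
    write_json_report(summary, file.path(out_dir, "hub_summary.json"))
    list(sets = hub_sets, summary = summary)
  })

  smallworld <- stage("small_world", {
    res <- lapply(seq_along(config$grid), function(k) {
      lapply(c(group1 = 1, group2 = 2), function(g) {
        net <- sweeps$networks[[g]][[k]]
        sw <- small_world_test(net, n_random = config$n_random,
                               seed = derive_seed(config$seed, 100 + 2 * k + g),
                               eglob_ratio_min = config$eglob_ratio_min)
        sw[c("E_glob_real", "E_loc_real", "E_glob_rand_mean",
             "E_loc_rand_mean", "gamma_loc", "lambda_glob", "is_small_world")]
      })
    })
    names(res) <- formatC(config$grid, format = "f", digits = 4)
    write_json_report(res, file.path(out_dir, "small_world.json"))
    res
  })

  inference <- stage("permutation_inference", {
    prof <- sweep_inference(data$group1, data$group2, config$grid,
                            global_metrics = config$global_metrics,
                            nodal_metrics = config$nodal_metrics,
                            n_perm = config$n_perm,
                            seed = derive_seed(config$seed, 200),
                            tail = config$tail, ranking = config$ranking)
    write_tsv(prof$global, file.path(out_dir, "permutation_global.tsv"))
    for (m in names(prof$nodal))
      write_tsv(prof$nodal[[m]],
                file.path(out_dir, sprintf("permutation_nodal_%s.tsv", m)))
    prof
  })

  report <- stage("report", {
    rep <- list(
      covnet_version = as.character(packageVersion("covnet")),
      settings = list(
        grid = config$grid, hub_sparsity = config$hub_sparsity,
        fdr_q = config$fdr_q, n_random = config$n_random,
        n_perm = config$n_perm, ranking = config$ranking,
        tail = config$tail, eglob_ratio_min = config$eglob_ratio_min,
        master_seed = config$seed,
        derived_seeds = list(
          small_world = "derive_seed(master, 100 + 2*grid_index + group)",
          permutation = "derive_seed(master, 200)")),
      data = list(
        n_subjects = c(nrow(data$group1$thickness), nrow(data$group2$thickness)),
        n_regions = ncol(data$group1$thickness),
        groups = c(data$group1$group[1], data$group2$group[1]),
        synthetic = !is.null(config$cohort)),
      edge_comparison = list(
        n_edges = nrow(edges),
        n_fdr_significant = sum(edges$fdr_significant),
        n_increased = sum(edges$fdr_significant & edges$direction == "increased"),
        n_decreased = sum(edges$fdr_significant & edges$direction == "decreased")),
      sparsity_curves = sweeps$curves,
      hubs = hubs$summary,
      small_world = smallworld,
      permutation = list(
        global = inference$global,
        nodal_mean_p = lapply(inference$nodal, function(tab)
          tab[, c("region_id", "mean_p")]))
    )
    validate_report(rep)
    write_json_report(rep, file.path(out_dir, "report.json"))
    rep
  })

  writeLines(c(paste0("covnet ", as.character(packageVersion("covnet"))),
               paste0("master_seed: ", config$seed), log_lines),
             file.path(out_dir, "run.log"))
  invisible(report)
}

# Check the report against the shipped JSON schema's required keys.
validate_report <- function(rep) {
  schema_path <- system.file("schema", "report-schema.json", package = "covnet")
  required <- if (nzchar(schema_path))
    jsonlite::read_json(schema_path)$required
  else list("covnet_version", "settings", "data", "edge_comparison",
            "sparsity_curves", "hubs", "small_world", "permutation")
  missing <- setdiff(unlist(required), names(rep))
  if (length(missing))
    stop_covnet("report is missing required section(s): ",
                paste(missing, collapse = ", "))
  invisible(TRUE)
}
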