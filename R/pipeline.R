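# End-to-end pipeline: config validation, stage orchestration, reporting.

.pipeline_defaults <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    synthetic = NULL,
    inputs = NULL,
    sweep = list(d_min = 0.02, d_max = 0.2, d_step = 0.02,
                 n_random_refs = 20, rewire_iterations_per_edge = 10),
    permutation = list(n_permutations = 1000, alpha = 0.05,
                       two_sided = TRUE, hub_rule = "permutation_2sd"),
    residualize = "edges",
    comparison_mode = "subject",
    analyses = list(global = TRUE, regional = TRUE, hubs = TRUE,
                    clinical = TRUE, volume_regression = TRUE,
                    global_metrics = c("small_world_index",
                                       "normalized_clustering",
                                       "local_efficiency", "transitivity",
                                       "modularity", "global_efficiency",
                                       "char_path_length"),
                    regional_metrics = c("degree", "betweenness"))
  )
}

.check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    abort(sprintf("unknown key(s) in %s: %s", where,
                  paste(unknown, collapse = ", ")),
          class = "netsweep_config_error")
  }
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a plain list; fills defaults (density
#' grid 0.02-0.2 by 0.02, 1000 permutations, alpha 0.05) and rejects unknown
#' keys with the offending name.
#'
#' @param config File path or list.
#' @return A validated `pipeline_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config),
            class = "netsweep_io_error")
    }
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    if (is.null(config)) config <- list()
  }
  defaults <- .pipeline_defaults()
  .check_keys(config, names(defaults), "config")
  .check_keys(config$sweep %||% list(), names(defaults$sweep), "sweep")
  .check_keys(config$permutation %||% list(), names(defaults$permutation),
              "permutation")
  .check_keys(config$analyses %||% list(), names(defaults$analyses),
              "analyses")
  if (!is.null(config$synthetic)) {
    .check_keys(config$synthetic,
                setdiff(names(formals(cohort_config)), "seed"), "synthetic")
    # surface cohort range errors at validation time
    do.call(cohort_config, c(config$synthetic, list(seed = 0L)))
  }
  if (!is.null(config$inputs)) {
    .check_keys(config$inputs,
                c("counts_dir", "node_table", "clinical", "volumes"),
                "inputs")
    for (p in unlist(config$inputs)) {
      if (!file.exists(p)) {
        abort(paste0("input path does not exist: ", p),
              class = "netsweep_config_error")
      }
    }
  }
  cfg <- defaults
  for (k in names(config)) {
    cfg[[k]] <- if (is.list(defaults[[k]]) && !is.null(config[[k]])) {
      modifyList(defaults[[k]], config[[k]])
    } else config[[k]]
  }
  if (!cfg$residualize %in% c("edges", "none")) {
    abort("residualize must be 'edges' or 'none'",
          class = "netsweep_config_error")
  }
  if (!cfg$comparison_mode %in% c("subject", "group")) {
    abort("comparison_mode must be 'subject' or 'group'",
          class = "netsweep_config_error")
  }
  # construct the stage configs now so range errors surface at validation
  cfg$sweep_cfg <- do.call(sweep_config, cfg$sweep)
  cfg$perm_cfg <- do.call(perm_config, cfg$permutation)
  if (is.null(cfg$synthetic) && is.null(cfg$inputs)) {
    abort("config needs either 'synthetic' or 'inputs'",
          class = "netsweep_config_error")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

# one master seed fans out to fixed per-stage offsets so stages can be
# re-run in isolation; kept below 2^31
.stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 1L, sweep = 2L, global = 3L, regional = 4L,
               volume = 5L)
  (as.integer(seed) + 1000003L * offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Executes build -> residualize -> density sweep -> group inference ->
#' associations on synthetic or user-supplied data, writes all result tables
#' as TSV plus a JSON report when `output_dir` is set, and returns the run
#' report. Identical seeds give identical result tables.
#'
#' @param config A `pipeline_config` from [validate_config()] (or anything
#'   it accepts).
#' @return A `run_report` list of result tibbles.
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  timing <- list()
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)

  # ---- stage: inputs -------------------------------------------------------
  if (!is.null(config$synthetic)) {
    ccfg <- do.call(cohort_config, c(config$synthetic,
                                     list(seed = .stage_seed(config$seed,
                                                             "cohort"))))
    cohort <- generate_cohort(ccfg)
  } else {
    atlas <- load_node_table(config$inputs$node_table)
    files <- sort(list.files(config$inputs$counts_dir, pattern = "\\.tsv$",
                             full.names = TRUE))
    counts <- purrr::map(files, load_counts, atlas = atlas)
    clinical <- load_clinical(config$inputs$clinical)
    volumes <- if (!is.null(config$inputs$volumes)) {
      v <- load_volumes(config$inputs$volumes, atlas)
      if (!"group" %in% names(v)) {
        v <- dplyr::left_join(v, clinical[, c("subject_id", "group")],
                              by = "subject_id")
      }
      v
    }
    cohort <- list(counts = counts, clinical = clinical, volumes = volumes,
                   atlas = atlas)
  }
  clinical <- cohort$clinical
  timing$inputs <- proc.time()[["elapsed"]] - t0

  # ---- stage: connectivity matrices + residualization ----------------------
  t1 <- proc.time()[["elapsed"]]
  matrices <- purrr::map(cohort$counts, compute_probability_matrix)
  ids <- purrr::map_chr(matrices, attr, "subject_id")
  clinical <- clinical[match(ids, clinical$subject_id), ]
  if (identical(config$residualize, "edges")) {
    matrices <- residualize_edges(matrices, clinical)
  }
  timing$build <- proc.time()[["elapsed"]] - t1

  # ---- stage: density sweep ------------------------------------------------
  t2 <- proc.time()[["elapsed"]]
  swp <- config$sweep_cfg
  swp$seed <- .stage_seed(config$seed, "sweep")
  want_global <- config$analyses$global_metrics
  want_nodal <- paste0("nodal_", config$analyses$regional_metrics)
  curves <- sweep_cohort(matrices, cfg = swp,
                         metrics = c(want_global, want_nodal))
  curves <- dplyr::left_join(curves, clinical[, c("subject_id", "group")],
                             by = "subject_id")
  auc <- curve_auc(curves) |>
    dplyr::left_join(clinical[, c("subject_id", "group")], by = "subject_id")
  # realized edge counts and components per density, the silent failure
  # modes of a density sweep
  diag_tbl <- curves |>
    dplyr::filter(.data$metric == "n_components") |>
    dplyr::group_by(.data$density) |>
    dplyr::summarise(mean_components = mean(.data$value), .groups = "drop")
  timing$sweep <- proc.time()[["elapsed"]] - t2

  report <- list(config = config, version = "0.1.0", seed = config$seed,
                 density_diagnostics = diag_tbl)

  # ---- stage: global inference ---------------------------------------------
  t3 <- proc.time()[["elapsed"]]
  if (isTRUE(config$analyses$global)) {
    pc <- config$perm_cfg
    pc$seed <- .stage_seed(config$seed, "global")
    gl <- purrr::map(config$analyses$global_metrics, function(mn) {
      cur <- dplyr::filter(curves, .data$metric == mn,
                           .data$node_id == "GLOBAL")
      if (nrow(cur) == 0) return(NULL)
      tst <- fda_auc_test(cur, pc, groups = c("patient", "control"),
                          metric = mn)
      glance(tst)
    })
    report$global_tests <- dplyr::bind_rows(gl)
  }
  if (isTRUE(config$analyses$regional) || isTRUE(config$analyses$hubs)) {
    pc <- config$perm_cfg
    regional <- list()
    hubs <- list()
    for (mn in config$analyses$regional_metrics) {
      pc$seed <- .stage_seed(config$seed, "regional")
      cur <- dplyr::filter(curves, .data$metric == mn,
                           .data$node_id != "GLOBAL")
      rt <- regional_tests(cur, pc, groups = c("patient", "control"),
                           metric = mn)
      regional[[mn]] <- rt
      if (isTRUE(config$analyses$hubs) && mn %in% c("degree", "betweenness")) {
        for (grp in c("a", "b")) {
          hs <- identify_hubs(rt, group = grp)
          hubs[[paste(mn, attr(hs, "group"), sep = "_")]] <-
            dplyr::mutate(tibble::as_tibble(hs),
                          group = attr(hs, "group"), criterion = mn,
                          rule = attr(hs, "rule"))
        }
      }
    }
    if (isTRUE(config$analyses$regional)) {
      report$regional_tests <- dplyr::bind_rows(
        purrr::map(regional, tibble::as_tibble))
    }
    if (isTRUE(config$analyses$hubs)) {
      report$hubs <- dplyr::bind_rows(hubs)
    }
  }
  timing$inference <- proc.time()[["elapsed"]] - t3

  # ---- stage: clinical + volumetric associations ---------------------------
  t4 <- proc.time()[["elapsed"]]
  if (isTRUE(config$analyses$clinical) &&
      all(c("bmi_lowest", "bmi_scan") %in% names(clinical))) {
    ga <- auc |>
      dplyr::filter(.data$node_id == "GLOBAL") |>
      tidyr::pivot_wider(names_from = "metric", values_from = "auc") |>
      dplyr::left_join(clinical, by = c("subject_id", "group"))
    topo_cols <- intersect(c("small_world_index", "normalized_clustering"),
                           names(ga))
    assoc <- list()
    for (grp in unique(ga$group)) {
      sub <- dplyr::filter(ga, .data$group == grp)
      for (tc in topo_cols) {
        for (cc in c("bmi_lowest", "bmi_scan")) {
          res <- tryCatch(spearman_assoc(sub, tc, cc),
                          error = function(e) NULL)
          if (!is.null(res)) assoc[[length(assoc) + 1]] <-
              dplyr::mutate(res, group = grp, .before = 1)
        }
      }
    }
    report$associations <- dplyr::bind_rows(assoc)
    report$clinical_comparison <- dplyr::bind_rows(purrr::map(
      intersect(c("age", "bmi_scan", "bmi_lowest"), names(clinical)),
      function(v) {
        res <- tryCatch(mann_whitney(
          clinical[[v]][clinical$group == "patient"],
          clinical[[v]][clinical$group == "control"]),
          error = function(e) NULL)
        if (!is.null(res)) dplyr::mutate(res, variable = v, .before = 1)
      }))
  }
  if (isTRUE(config$analyses$volume_regression) && !is.null(cohort$volumes)) {
    crit <- intersect(c("degree", "betweenness", "clustering",
                        "local_efficiency"),
                      config$analyses$regional_metrics)
    regs <- list()
    for (mn in crit) {
      nodal_auc <- dplyr::filter(auc, .data$metric == mn,
                                 .data$node_id != "GLOBAL")
      diffs <- group_differences(nodal_auc, cohort$volumes)
      scopes <- c("overall", intersect(unique(cohort$atlas$lobe),
                                       cohort$atlas$lobe))
      for (sc in unique(scopes)) {
        r <- tryCatch(volume_topology_regression(diffs, cohort$atlas, sc),
                      error = function(e) NULL)
        if (!is.null(r)) regs[[length(regs) + 1]] <-
            dplyr::mutate(r, metric = mn, .before = 1)
      }
    }
    report$volume_regressions <- dplyr::bind_rows(regs)
  }
  timing$associations <- proc.time()[["elapsed"]] - t4

  report$curves <- curves
  report$auc <- auc
  report$warnings <- warnings
  report$timing <- timing
  class(report) <- "run_report"

  if (!is.null(config$output_dir)) {
    .write_report(report, config$output_dir)
  }
  report
}

.write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("global_tests", "regional_tests", "hubs", "associations",
              "clinical_comparison", "volume_regressions", "curves", "auc",
              "density_diagnostics")
  for (tb in tables) {
    if (!is.null(report[[tb]]) && nrow(report[[tb]]) > 0) {
      readr::write_tsv(tibble::as_tibble(report[[tb]]),
                       file.path(dir, paste0(tb, ".tsv")))
    }
  }
  meta <- list(version = report$version, seed = report$seed,
               timing = report$timing, warnings = report$warnings,
               sweep = report$config$sweep, permutation = report$config$permutation,
               residualize = report$config$residualize,
               comparison_mode = report$config$comparison_mode)
  jsonlite::write_json(meta, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  if (!is.null(x$global_tests)) {
    cat("Global measures (AUC permutation test):\n")
    print(x$global_tests, n = Inf)
  }
  if (!is.null(x$hubs)) {
    hb <- dplyr::filter(x$hubs, .data$is_hub)
    cat(sprintf("Hubs: %d node-group-criterion flags\n", nrow(hb)))
  }
  invisible(x)
}
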