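STEP_DIRS <- c(
  preprocess = "1_preprocessing",
  diagnostics = "2_diagnostics",
  explore = "3_exploration",
  diversity = "4_chemodiversity",
  stats = "5_statistics",
  networks = "6_networks"
)

write_tbl <- function(tbl, dir, name, manifest_env) {
  path <- file.path(dir, name)
  df <- as.data.frame(tbl)
  list_cols <- vapply(df, is.list, logical(1))
  df <- df[, !list_cols, drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  manifest_env$outputs <- c(manifest_env$outputs, path)
  invisible(path)
}

matrix_tbl <- function(mat, id = "peak_id") {
  dplyr::bind_cols(tibble::tibble(!!id := rownames(mat)),
                   tibble::as_tibble(as.data.frame(mat)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the six analysis steps on one dataset: (1) pre-processing
#' (filtering, annotation, normalization), (2) diagnostics, (3) exploration,
#' (4) chemodiversity, (5) multivariate statistics, (6) transformation
#' networks. Each requested step writes its tables into a numbered
#' subdirectory of `output_dir`; a run manifest (configuration snapshot,
#' seed, per-step status, outputs, timings) is always written, even on
#' partial failure. The network step only runs when explicitly requested, as
#' it is the costly part for large datasets.
#'
#' @param report An `ftms_report` or a path to a report CSV.
#' @param metadata A metadata tibble or a path to a metadata CSV.
#' @param config An [run_config()] object.
#' @param output_dir Output directory (created if needed).
#' @param steps Subset of `c("preprocess", "diagnostics", "explore",
#'   "diversity", "stats", "networks")`. Pre-processing always runs (it feeds
#'   everything else) but only writes output when requested.
#' @return Invisibly, the manifest list (`status` per step, `outputs`,
#'   `config`, `seed`, `failed`).
#' @export
run_pipeline <- function(report, metadata, config = run_config(),
                         output_dir = "ftmsflow_output",
                         steps = c("preprocess", "diagnostics", "explore",
                                   "diversity", "stats")) {
  steps <- match.arg(steps, names(STEP_DIRS), several.ok = TRUE)
  if (is.character(report)) report <- read_report(report)
  if (is.character(metadata)) metadata <- read_metadata(metadata, config$grouping)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  env <- new.env(); env$outputs <- character()
  status <- setNames(rep("skipped", length(STEP_DIRS)), names(STEP_DIRS))
  timings <- setNames(rep(NA_real_, length(STEP_DIRS)), names(STEP_DIRS))

  run_step <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    status[[name]] <<- tryCatch({
      fun()
      "ok"
    }, error = function(e) paste0("failed: ", conditionMessage(e)))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }

  x <- NULL
  run_step("preprocess", function() {
    d <- ftms_data(report, metadata, config$grouping)
    d <- filter_peaks(d, config)
    d <- annotate_peaks(d)
    d <- normalize_intensities(d, config = config)
    x <<- d
    if ("preprocess" %in% steps) {
      dir <- file.path(output_dir, STEP_DIRS[["preprocess"]])
      dir.create(dir, showWarnings = FALSE)
      write_tbl(d$peaks, dir, "filtered_peaks.csv", env)
      write_tbl(matrix_tbl(d$intensities), dir, "raw_intensities.csv", env)
      write_tbl(matrix_tbl(d$normalized), dir, "normalized_intensities.csv", env)
      write_tbl(d$filter_audit, dir, "filter_audit.csv", env)
    }
  })

  if (status[["preprocess"]] == "ok") {
    if ("diagnostics" %in% steps) run_step("diagnostics", function() {
      dir <- file.path(output_dir, STEP_DIRS[["diagnostics"]])
      dir.create(dir, showWarnings = FALSE)
      write_tbl(diagnostics_counts(x), dir, "peak_counts.csv", env)
      write_tbl(assignment_error_table(x), dir, "assignment_errors.csv", env)
    })
    if ("explore" %in% steps) run_step("explore", function() {
      dir <- file.path(output_dir, STEP_DIRS[["explore"]])
      dir.create(dir, showWarnings = FALSE)
      write_tbl(van_krevelen_data(x), dir, "van_krevelen.csv", env)
      comp <- composition_summary(x)
      write_tbl(comp$compound_class, dir, "composition_classes.csv", env)
      write_tbl(comp$element_class, dir, "composition_elements.csv", env)
      tests <- index_group_tests(x)
      write_tbl(tests$anova, dir, "index_anova.csv", env)
      write_tbl(tests$tukey, dir, "index_tukey.csv", env)
      pw <- pairwise_compare(x)
      write_tbl(pw$comparisons, dir, "pairwise_comparisons.csv", env)
      write_tbl(pw$class_breakdown, dir, "pairwise_class_breakdown.csv", env)
      write_tbl(pw$membership, dir, "group_membership.csv", env)
    })
    if ("diversity" %in% steps) run_step("diversity", function() {
      dir <- file.path(output_dir, STEP_DIRS[["diversity"]])
      dir.create(dir, showWarnings = FALSE)
      div <- diversity_summary(x)
      long <- dplyr::bind_rows(
        tidyr::pivot_longer(div$abundance, -"sample_id", names_to = "metric",
                            values_to = "value") |>
          dplyr::mutate(trait_set = NA_character_),
        div$functional |>
          dplyr::transmute(.data$sample_id, metric = "rao_q", .data$trait_set,
                           value = .data$rao_q)
      )
      write_tbl(long, dir, "diversity_indices.csv", env)
      write_tbl(rank_abundance(x), dir, "rank_abundance.csv", env)
    })
    if ("stats" %in% steps) run_step("stats", function() {
      dir <- file.path(output_dir, STEP_DIRS[["stats"]])
      dir.create(dir, showWarnings = FALSE)
      d <- compute_distance(x)
      dm <- as.matrix(d)
      write_tbl(matrix_tbl(dm, id = "sample_id"), dir, "distance_matrix.csv", env)
      pm <- permanova(d, x$metadata, x$grouping, n_perm = 999,
                      seed = config$rng_seed)
      write_tbl(pm, dir, "permanova.csv", env)
      nm <- nmds(d, k = 2, seed = config$rng_seed)
      sc <- matrix_tbl(nm$scores, id = "sample_id")
      sc$stress <- nm$stress
      write_tbl(sc, dir, "nmds_scores.csv", env)
      pca <- pca_summaries(x)
      for (nm2 in names(pca)) {
        p <- pca[[nm2]]
        write_tbl(matrix_tbl(p$scores, id = "sample_id"), dir,
                  paste0("pca_", nm2, "_scores.csv"), env)
        write_tbl(matrix_tbl(p$loadings, id = "variable"), dir,
                  paste0("pca_", nm2, "_loadings.csv"), env)
        write_tbl(tibble::tibble(component = seq_along(p$explained_variance),
                                 explained_variance = p$explained_variance),
                  dir, paste0("pca_", nm2, "_variance.csv"), env)
      }
    })
    if ("networks" %in% steps) run_step("networks", function() {
      dir <- file.path(output_dir, STEP_DIRS[["networks"]])
      dir.create(dir, showWarnings = FALSE)
      key <- read_transformation_key(config$transformation_key)
      nets <- sample_networks(x, key, ppm_tolerance = config$ppm_tolerance)
      write_tbl(nets$stats, dir, "network_stats.csv", env)
      summ <- transformation_summary(nets$edges)
      write_tbl(summ$per_sample, dir, "transformations_per_sample.csv", env)
      write_tbl(summ$category_split, dir, "transformation_categories.csv", env)
      write_tbl(summ$totals, dir, "transformation_totals.csv", env)
      for (s in names(nets$edges)) {
        write_tbl(nets$edges[[s]], dir, paste0("edges_", s, ".csv"), env)
        if (igraph::vcount(nets$networks[[s]]$graph) > 0) {
          gpath <- file.path(dir, paste0("network_", s, ".graphml"))
          igraph::write_graph(nets$networks[[s]]$graph, gpath, format = "graphml")
          env$outputs <- c(env$outputs, gpath)
        }
      }
    })
  }

  manifest <- list(
    package_version = as.character(packageVersion("ftmsflow")),
    seed = config$rng_seed,
    config = unclass(config),
    steps_requested = steps,
    status = as.list(status),
    timings_s = as.list(timings),
    outputs = env$outputs
  )
  manifest_path <- file.path(output_dir, "manifest.txt")
  writeLines(c(
    paste0("ftmsflow ", manifest$package_version),
    paste0("seed: ", manifest$seed),
    paste0("config: ", paste(names(manifest$config),
                             vapply(manifest$config, function(v)
                               paste(v, collapse = ","), ""),
                             sep = "=", collapse = "; ")),
    paste0("steps: ", paste(steps, collapse = ", ")),
    paste0("status: ", paste(names(status), unname(status), sep = "=",
                             collapse = "; ")),
    paste0("timings_s: ", paste(names(timings), unname(timings), sep = "=",
                                collapse = "; ")),
    "outputs:", paste0("  ", env$outputs)
  ), manifest_path)

  failed <- grepl("^failed", status[names(status) %in% c("preprocess", steps)])
  manifest$failed <- any(failed)
  if (manifest$failed) {
    warning("pipeline step(s) failed: ",
            paste(names(status)[grepl("^failed", status)], collapse = ", "),
            call. = FALSE)
  }
  invisible(manifest)
}

#' Score normalization methods and write the SPANS-style grid
#'
#' Companion entry point run before the main pipeline: computes the
#' bias-score grid over subset x normalization combinations on the raw
#' intensities, writes `spans_scores.csv`, and reports the recommended
#' method.
#'
#' @param report An `ftms_report` or path.
#' @param metadata A metadata tibble or path.
#' @param config An [run_config()].
#' @param output_dir Where to write `spans_scores.csv` (`NULL` to skip
#'   writing).
#' @return List with `grid` and `recommended`.
#' @export
run_test_normalization <- function(report, metadata, config = run_config(),
                                   output_dir = NULL) {
  if (is.character(report)) report <- read_report(report)
  if (is.character(metadata)) metadata <- read_metadata(metadata, config$grouping)
  x <- ftms_data(report, metadata, config$grouping)
  grid <- spans_grid(x, grouping = config$grouping[1])
  rec <- recommend_method(grid)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(as.data.frame(grid), file.path(output_dir, "spans_scores.csv"),
              row.names = FALSE)
  }
  message("recommended normalization method: ", rec)
  list(grid = grid, recommended = rec)
}
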