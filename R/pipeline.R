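#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: the input data (a CSV
#' path, a block tibble, or — when `input` is `NULL` — a simulation from
#' `allocation` + `sim`), the permutation and clustering settings, and the
#' output directory. All stochastic steps derive their streams from `seed`,
#' so a rerun with the same configuration is reproducible bit-for-bit.
#'
#' @param out_dir Output directory for the report bundle (created if
#'   needed).
#' @param seed Integer master seed (mandatory).
#' @param input `NULL` (simulate), a CSV path, or a block tibble.
#' @param allocation Wheel allocation used when simulating (default
#'   [default_allocation()]).
#' @param sim A [sim_config()] used when simulating.
#' @param n_perm Permutations per test (default 1000).
#' @param alpha Significance level on adjusted p values (default 0.05).
#' @param variance_threshold Cumulative explained-variance target for
#'   component retention (default 0.85).
#' @param multiplicity Bonferroni family (see [permutation_test()]).
#' @param cluster_factor Factor whose ASCA scores are clustered (default
#'   `"dairy"`).
#' @param k_range,n_restarts,cluster_method Clustering options (see
#'   [cluster_levels()]).
#' @param force_all Run the ASCA stage for all main factors regardless of
#'   significance.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed, input = NULL,
                            allocation = default_allocation(),
                            sim = sim_config(), n_perm = 1000,
                            alpha = 0.05, variance_threshold = 0.85,
                            multiplicity = c("variables", "all"),
                            cluster_factor = "dairy", k_range = 2:8,
                            n_restarts = 25,
                            cluster_method = c("silhouette", "elbow"),
                            force_all = FALSE) {
  if (missing(seed) || is.null(seed)) {
    abort("seed is mandatory: every stochastic stage derives from it",
          class = "lmmasca_config_error")
  }
  stopifnot(n_perm >= 1, alpha > 0, alpha < 1,
            variance_threshold > 0, variance_threshold <= 1)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), input = input,
         allocation = allocation, sim = sim, n_perm = as.integer(n_perm),
         alpha = alpha, variance_threshold = variance_threshold,
         multiplicity = match.arg(multiplicity),
         cluster_factor = cluster_factor, k_range = k_range,
         n_restarts = n_restarts, cluster_method = match.arg(cluster_method),
         force_all = isTRUE(force_all)),
    class = "pipeline_config"
  )
}

stage_log <- function(stage, ...) {
  inform(paste0("[", stage, "] ", paste0(..., collapse = "")))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (read or simulate), QQ diagnostics,
#' standardization, per-variable REML fits, restricted-permutation
#' significance tests, ASCA decomposition of the main factors found
#' significant for at least one variable (all three when `force_all`), and
#' k-means clustering of the chosen factor's scores. Every stage's data is
#' written as CSV into `config$out_dir` together with a JSON manifest
#' (package version, seed, configuration hash, per-file row counts); the
#' manifest suffices to re-run the bundle reproducibly.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  put <- function(name, data) {
    path <- file.path(config$out_dir, name)
    readr::write_csv(data, path, progress = FALSE)
    files[[name]] <<- nrow(data)
    invisible(path)
  }
  put_blocks <- function(name, data) {
    write_blocks(data, file.path(config$out_dir, name))
    files[[name]] <<- nrow(data)
  }

  # -- data ----------------------------------------------------------------
  if (is.null(config$input)) {
    design <- generate_design(config$allocation, config$sim$replicates)
    blocks <- simulate_blocks(design, config$sim, seed = config$seed)
    stage_log("data", "simulated ", nrow(blocks), " blocks, ",
              nlevels(blocks$wheel_id), " wheels")
  } else if (is.character(config$input)) {
    blocks <- read_blocks(config$input)
    stage_log("data", "read ", nrow(blocks), " blocks from ", config$input)
  } else {
    blocks <- validate_blocks(config$input)
    stage_log("data", "validated ", nrow(blocks), " blocks")
  }
  put_blocks("data.csv", blocks)

  # -- preprocessing -------------------------------------------------------
  qq <- qq_summary(blocks)
  put("qq.csv", qq)
  std <- standardize_blocks(blocks)
  put_blocks("standardized.csv", std)
  put("scaling.csv", scaling_params(std))
  stage_log("preprocess", "standardized 6 variables; min QQ correlation ",
            format(min(qq$correlation), digits = 4))

  # -- linear mixed models -------------------------------------------------
  fits <- fit_lmm(std)
  put("effects.csv", tidy(fits))
  put("variance_components.csv", glance(fits))
  stage_log("fit", length(fits$fits), " REML fits, ",
            fits$design$n_coef, " fixed-effect columns")

  # -- permutation significance -------------------------------------------
  perm <- permutation_test(std, n_perm = config$n_perm,
                           seed = config$seed + 1L,
                           multiplicity = config$multiplicity)
  grid <- significance_table(perm, alpha = config$alpha)
  put("pvalues.csv", tidy(perm))
  if (setequal(perm$terms, model_terms())) {
    put("tileplot.csv", export_tileplot_data(grid))
  }
  stage_log("permute", config$n_perm, " permutations; ",
            sum(grid$reject), "/", nrow(grid), " tests significant at ",
            config$alpha)

  # -- ASCA ----------------------------------------------------------------
  main_present <- intersect(c("position", "time", "dairy"),
                            fits$design$terms)
  significant <- grid |>
    dplyr::filter(.data$term %in% main_present) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(any_reject = any(.data$reject)) |>
    dplyr::filter(.data$any_reject) |>
    dplyr::pull("term")
  asca_factors <- if (config$force_all) main_present else significant
  models <- list()
  for (f in setdiff(main_present, asca_factors)) {
    stage_log("asca", "skipping '", f,
              "': not significant for any variable")
  }
  for (f in asca_factors) {
    mod <- asca(fits, f, threshold = config$variance_threshold)
    models[[f]] <- mod
    tag <- gsub(":", "_", f)
    put(paste0("scores_", tag, ".csv"), tidy(mod, "scores"))
    put(paste0("loadings_", tag, ".csv"), tidy(mod, "loadings"))
    put(paste0("variance_", tag, ".csv"), tidy(mod, "variance"))
    put(paste0("contributions_", tag, ".csv"), asca_contributions(mod))
    put(paste0("biplot_", tag, ".csv"), biplot_data(mod))
    stage_log("asca", f, ": ", mod$n_components, " components for >= ",
              100 * config$variance_threshold, "% of effect variance")
  }

  # -- clustering ----------------------------------------------------------
  clusters <- NULL
  if (config$cluster_factor %in% names(models)) {
    clusters <- cluster_levels(models[[config$cluster_factor]],
                               k = "auto", k_range = config$k_range,
                               method = config$cluster_method,
                               n_restarts = config$n_restarts,
                               seed = config$seed + 2L)
    put("clusters.csv", cluster_report(clusters))
    put("silhouette.csv",
        clusters$assignments[, c("level", "cluster", "silhouette")])
    put("wss.csv", clusters$diagnostics)
    stage_log("cluster", config$cluster_factor, ": k = ", clusters$k,
              " (", config$cluster_method, ")")
  } else {
    stage_log("cluster", "skipped: no ASCA model for '",
              config$cluster_factor, "'")
  }

  # -- manifest ------------------------------------------------------------
  manifest <- list(
    package = "lmmasca",
    version = as.character(utils::packageVersion("lmmasca")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_perm = config$n_perm, alpha = config$alpha,
    variance_threshold = config$variance_threshold,
    multiplicity = config$multiplicity,
    asca_factors = as.list(asca_factors),
    skipped_asca = as.list(setdiff(main_present, asca_factors)),
    files = files
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(blocks = blocks, standardized = std, fits = fits,
                 permutation = perm, significance = grid, asca = models,
                 clusters = clusters, manifest = manifest))
}
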