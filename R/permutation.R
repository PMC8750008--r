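#' Exchange unit of a model term under the restricted permutation scheme
#'
#' The permutation null must respect the nesting of blocks within wheels:
#' wheel-level factors (`time`, `dairy`, `time:dairy`) are tested by
#' reassigning the `(dairy, time)` label pair across whole wheels, so every
#' block keeps its wheel-mates; the position factor and its interactions are
#' tested by shuffling position labels among the blocks within each wheel
#' independently.
#'
#' @param term A model term.
#' @return `"wheel"` or `"block"`.
#' @export
exchange_unit <- function(term) {
  units <- c(position = "block", time = "wheel", dairy = "wheel",
             `position:time` = "block", `position:dairy` = "block",
             `time:dairy` = "wheel")
  if (!term %in% names(units)) {
    abort(paste0("unknown term: ", term), class = "lmmasca_config_error")
  }
  unname(units[term])
}

#' Permute factor labels under a restricted scheme
#'
#' `scheme = "wheel"`: the `(dairy, session, time)` label triple is
#' reassigned by a uniform permutation of wheels; every block of a wheel
#' keeps its wheel's new labels and its wheel-mates. `scheme = "block"`:
#' position labels are permuted uniformly among the blocks within each wheel
#' independently (replicate numbers are renumbered within the new
#' wheel-position cells). Response values and the wheel grouping are
#' untouched in both schemes.
#'
#' @param blocks A validated block tibble.
#' @param scheme `"wheel"` or `"block"`.
#' @param seed Integer seed.
#' @return A permuted block tibble (still valid).
#' @export
permute_blocks <- function(blocks, scheme = c("wheel", "block"), seed) {
  scheme <- match.arg(scheme)
  blocks <- validate_blocks(blocks)
  withr::with_seed(as.integer(seed), {
    if (scheme == "wheel") {
      wl <- dplyr::distinct(blocks, .data$wheel_id, .data$dairy,
                            .data$session, .data$time)
      pi <- sample.int(nrow(wl))
      idx <- match(blocks$wheel_id, wl$wheel_id)
      out <- blocks
      out$dairy <- wl$dairy[pi][idx]
      out$session <- wl$session[pi][idx]
      out$time <- wl$time[pi][idx]
      out
    } else {
      out <- blocks |>
        dplyr::group_by(.data$wheel_id) |>
        dplyr::mutate(position = .data$position[sample.int(dplyr::n())]) |>
        dplyr::group_by(.data$wheel_id, .data$position) |>
        dplyr::mutate(replicate = seq_len(dplyr::n())) |>
        dplyr::ungroup()
      out
    }
  })
}

# The permutation engine keeps the design matrix fixed and permutes
# response rows instead: with rows in canonical order and an identical
# position/replicate layout in every wheel, relabeling wheels is equivalent
# to permuting whole-wheel response blocks, and relabeling positions within
# a wheel is equivalent to permuting responses within the wheel. This makes
# a refit a pure numeric operation (no matrix rebuild).
check_balanced_layout <- function(design) {
  tab <- table(design$blocks$wheel_id, design$blocks$position)
  if (length(unique(as.vector(tab))) != 1L) {
    abort(paste0("the permutation engine requires the balanced within-wheel ",
                 "layout of the sampling design (equal replicate counts per ",
                 "position in every wheel)"),
          class = "lmmasca_value_error")
  }
  invisible(design)
}

# n x n_perm matrices of 1-based row indices, rows in canonical order
perm_indices <- function(design, scheme, n_perm) {
  n <- design$n_obs
  W <- design$n_groups
  m <- as.integer(n / W)
  if (scheme == "wheel") {
    vapply(seq_len(n_perm), function(j) {
      pi <- sample.int(W)
      rep((pi - 1L) * m, each = m) + seq_len(m)
    }, integer(n))
  } else {
    offsets <- rep((seq_len(W) - 1L) * m, each = m)
    vapply(seq_len(n_perm), function(j) {
      offsets + as.vector(vapply(seq_len(W), function(w) sample.int(m),
                                 integer(m)))
    }, integer(n))
  }
}

#' Permutation significance test for every model term
#'
#' Refits the full REML model on `n_perm` restricted permutations of the
#' data and compares each term's observed observation-expanded sum of
#' squares with its permutation distribution. Wheel-level terms use
#' whole-wheel relabelings, position terms use within-wheel relabelings
#' (see [exchange_unit()]). The one-sided Monte-Carlo p value uses the +1
#' correction, `p_raw = (1 + #{SS_perm >= SS_obs}) / (n_perm + 1)`, and is
#' Bonferroni-adjusted across the variables tested
#' (`multiplicity = "variables"`, the default) or across all
#' term-by-variable tests (`"all"`).
#'
#' @param blocks A validated block tibble with a balanced within-wheel
#'   layout.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; permutations are reproducible bit-for-bit.
#' @param variables Response columns to test (default all six).
#' @param terms Model terms to test (default: all terms in the design).
#' @param multiplicity Bonferroni family, `"variables"` or `"all"`.
#' @param keep_samples Keep the permuted SS samples (list-column `perm_ss`)
#'   for audit.
#' @return An object of class `perm_test`; `tidy()` returns the tibble
#'   `term`, `code`, `variable`, `ss_obs`, `p_raw`, `p_adj`.
#' @export
permutation_test <- function(blocks, n_perm = 1000, seed,
                             variables = variable_names(), terms = NULL,
                             multiplicity = c("variables", "all"),
                             keep_samples = FALSE) {
  multiplicity <- match.arg(multiplicity)
  fits <- fit_lmm(blocks, variables)
  design <- fits$design
  check_balanced_layout(design)
  terms <- terms %||% design$terms
  bad <- setdiff(terms, design$terms)
  if (length(bad) > 0) {
    abort(paste0("term(s) not in the model: ", paste(bad, collapse = ", ")),
          class = "lmmasca_config_error")
  }
  schemes <- vapply(terms, exchange_unit, character(1))
  n_perm <- as.integer(n_perm)

  perm_sets <- withr::with_seed(as.integer(seed), {
    out <- list()
    for (sc in unique(schemes)) out[[sc]] <- perm_indices(design, sc, n_perm)
    out
  })

  m_adj <- if (multiplicity == "variables") length(variables) else
    length(variables) * length(terms)
  rows <- list()
  n_fail <- 0L
  for (sc in unique(schemes)) {
    sc_terms <- terms[schemes == sc]
    cols <- design$term_cols[sc_terms]
    for (v in variables) {
      y <- design$blocks[[v]]
      res <- perm_ss_cpp(design$X, y, design$group, design$n_groups,
                         perm_sets[[sc]], unname(cols))
      n_fail <- n_fail + res$n_fail
      for (i in seq_along(sc_terms)) {
        tm <- sc_terms[i]
        ss_obs <- fits$fits[[v]]$factor_ss[[tm]]
        samp <- res$ss[, i]
        p_raw <- (1 + sum(samp >= ss_obs)) / (n_perm + 1)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          term = tm, code = unname(term_codes()[tm]), variable = v,
          ss_obs = ss_obs, p_raw = p_raw,
          p_adj = min(1, m_adj * p_raw),
          perm_ss = if (keep_samples) list(samp) else list(NULL)
        )
      }
    }
  }
  if (n_fail > 0.01 * n_perm * length(variables) * length(unique(schemes))) {
    abort(paste0("REML failed to converge on ", n_fail,
                 " permutation refits (more than 1%)"),
          class = "lmmasca_convergence_error")
  }
  results <- dplyr::arrange(dplyr::bind_rows(rows),
                            match(.data$term, model_terms()),
                            match(.data$variable, variable_names()))
  if (!keep_samples) results$perm_ss <- NULL
  structure(list(results = results, n_perm = n_perm, seed = seed,
                 terms = terms, variables = variables,
                 multiplicity = multiplicity, fits = fits),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test>", x$n_perm, "permutations, seed", x$seed,
      ", Bonferroni over", x$multiplicity, "\n")
  print(significance_table(x), n = Inf)
  invisible(x)
}

#' @export
#' @rdname permutation_test
#' @param x A `perm_test` object.
#' @param ... Unused.
tidy.perm_test <- function(x, ...) {
  dplyr::select(x$results, -dplyr::any_of("perm_ss"))
}

#' Factor-by-variable significance grid
#'
#' @param x A `perm_test` object.
#' @param alpha Significance level for the adjusted p values (default 0.05).
#' @return A tibble `term`, `code`, `variable`, `p_adj`, `reject` — the
#'   data behind the significance tile plot.
#' @export
significance_table <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "perm_test"))
  dplyr::transmute(x$results, term = .data$term, code = .data$code,
                   variable = .data$variable, p_adj = .data$p_adj,
                   reject = .data$p_adj < alpha)
}

#' Export the tile-plot data of the significance grid
#'
#' Writes the complete 6-term by 6-variable grid in long format with the
#' short factor codes `T`, `D`, `S`, `S:T`, `D:S`, `D:T`.
#'
#' @param grid A significance tibble (see [significance_table()]) covering
#'   all terms and variables.
#' @param path Optional CSV path; when `NULL` the tibble is returned only.
#' @return The exported tibble (`factor`, `variable`, `p_adjusted`,
#'   `reject`), invisibly when written to file.
#' @export
export_tileplot_data <- function(grid, path = NULL) {
  needed <- tidyr::expand_grid(term = model_terms(),
                               variable = variable_names())
  missing <- dplyr::anti_join(needed, grid, by = c("term", "variable"))
  if (nrow(missing) > 0) {
    abort(paste0("incomplete grid; missing ",
                 paste(paste0(missing$term, "/", missing$variable),
                       collapse = ", ")),
          class = "lmmasca_value_error")
  }
  out <- grid |>
    dplyr::semi_join(needed, by = c("term", "variable")) |>
    dplyr::transmute(factor = unname(term_codes()[.data$term]),
                     variable = .data$variable,
                     p_adjusted = .data$p_adj, reject = .data$reject)
  if (!is.null(path)) {
    readr::write_csv(out, path, progress = FALSE)
    return(invisible(out))
  }
  out
}
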