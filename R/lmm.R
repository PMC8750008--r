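#' Build the fixed-effect design and grouping structure
#'
#' Constructs the sum-to-zero contrast-coded fixed-effect matrix for the
#' block model — intercept, position, time, dairy and their three two-way
#' interactions — together with the wheel grouping vector for the random
#' intercept. The wheel is nested inside the crossed fixed factors, so no
#' interaction involves it. Factors with a single observed level (degenerate
#' sub-designs) are dropped from the model, as are interactions involving
#' them. Rows are put in a canonical order (dairy, session, wheel, position,
#' replicate), which makes fits invariant to the input row order.
#'
#' @param blocks A validated block tibble.
#' @return An object of class `lmm_design`: list with the model matrix `X`,
#'   the reordered `blocks`, term labels and per-term column indices, the
#'   per-factor contrast matrices, the wheel grouping vector and counts.
#' @export
build_design <- function(blocks) {
  blocks <- validate_blocks(blocks)
  if (nrow(blocks) == 0) {
    abort("cannot build a design from an empty table",
          class = "lmmasca_value_error")
  }
  ord <- order(blocks$dairy, blocks$session, blocks$wheel_id,
               blocks$position, blocks$replicate)
  blocks <- blocks[ord, ]
  d <- droplevels(blocks[factor_columns()])
  main <- c("position", "time", "dairy")
  present <- main[vapply(main, function(f) nlevels(d[[f]]) >= 2L, logical(1))]
  if (length(present) == 0) {
    abort("all fixed factors have a single observed level",
          class = "lmmasca_value_error")
  }
  pairs <- list(c("position", "time"), c("position", "dairy"),
                c("time", "dairy"))
  inter <- purrr::map_chr(purrr::keep(pairs, ~ all(.x %in% present)),
                          paste, collapse = ":")
  fml <- stats::reformulate(c(present, inter))
  X <- model.matrix(fml, data = d,
                    contrasts.arg = setNames(rep(list("contr.sum"),
                                                 length(present)), present))
  labels <- attr(stats::terms(fml), "term.labels")
  asn <- attr(X, "assign")
  term_cols <- setNames(lapply(seq_along(labels), function(k) which(asn == k)),
                        labels)
  contrasts <- lapply(setNames(present, present), function(f) {
    C <- contr.sum(nlevels(d[[f]]))
    rownames(C) <- levels(d[[f]])
    C
  })
  structure(
    list(X = X, blocks = blocks, terms = labels, term_cols = term_cols,
         contrasts = contrasts,
         levels = lapply(setNames(present, present),
                         function(f) levels(d[[f]])),
         group = as.integer(d$wheel_id), n_groups = nlevels(d$wheel_id),
         n_obs = nrow(X), n_coef = ncol(X)),
    class = "lmm_design"
  )
}

#' @export
print.lmm_design <- function(x, ...) {
  cat("<lmm_design>", x$n_obs, "blocks,", x$n_groups, "wheels,",
      x$n_coef, "fixed-effect columns\n")
  cat("  terms:", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

#' Fit the block linear mixed model to every response variable
#'
#' For each response, fits
#' `value ~ position + time + dairy + two-way interactions + (1 | wheel)`
#' with sum-to-zero contrasts by restricted maximum likelihood. A single
#' random intercept means REML reduces to a one-dimensional search over the
#' variance ratio `sigma2_wheel / sigma2_eps`; the fixed effects are the
#' generalized-least-squares solution at the optimum. The search is
#' golden-section on the log-ratio in `[1e-8, 1e8]` with tolerance 1e-10 and
#' an iteration cap of 200; a ratio driven to the lower boundary is clamped
#' to `sigma2_wheel = 0` (the ordinary-least-squares solution).
#'
#' Variables are typically standardized first (see [standardize_blocks()])
#' so effects are comparable across responses; the fit itself works on any
#' scale.
#'
#' @param blocks A validated block tibble (at least 2 wheels).
#' @param variables Response columns to fit (default all six).
#' @return An object of class `lmm_fits`: the shared [build_design()]
#'   structure plus one fit per variable (coefficients, variance components,
#'   restricted log-likelihood, reconstructed level effects and per-term
#'   sums of squares). `tidy()` returns the level effects, `glance()` the
#'   variance components.
#' @export
fit_lmm <- function(blocks, variables = variable_names()) {
  design <- build_design(blocks)
  if (design$n_groups < 2L) {
    abort("at least 2 wheels are required to separate the variance components",
          class = "lmmasca_value_error")
  }
  if (design$n_obs <= design$n_coef) {
    abort("no residual degrees of freedom", class = "lmmasca_value_error")
  }
  fits <- lapply(setNames(variables, variables), function(v) {
    y <- design$blocks[[v]]
    res <- reml_fit_cpp(design$X, y, design$group, design$n_groups)
    beta <- drop(res$beta)
    names(beta) <- colnames(design$X)
    list(
      variable = v,
      beta = beta,
      sigma2_wheel = res$sigma2_wheel,
      sigma2_eps = res$sigma2_eps,
      variance_ratio = res$lambda,
      loglik_reml = res$loglik_reml,
      converged = res$converged,
      level_effects = reconstruct_effects(design, beta),
      factor_ss = term_ss(design, beta)
    )
  })
  structure(list(design = design, fits = fits, variables = variables),
            class = "lmm_fits")
}

# level effects from the contrast bases: main factors give C %*% beta_f;
# interactions give C_a %*% B %*% t(C_b) with the coefficient matrix B laid
# out first-factor-fastest, matching model.matrix column order
reconstruct_effects <- function(design, beta) {
  out <- list()
  for (f in names(design$contrasts)) {
    if (!f %in% design$terms) next
    e <- drop(design$contrasts[[f]] %*% beta[design$term_cols[[f]]])
    names(e) <- design$levels[[f]]
    out[[f]] <- e
  }
  for (tm in setdiff(design$terms, names(design$contrasts))) {
    fs <- strsplit(tm, ":", fixed = TRUE)[[1]]
    Ca <- design$contrasts[[fs[1]]]
    Cb <- design$contrasts[[fs[2]]]
    B <- matrix(beta[design$term_cols[[tm]]], nrow = ncol(Ca))
    E <- Ca %*% B %*% t(Cb)
    dimnames(E) <- list(design$levels[[fs[1]]], design$levels[[fs[2]]])
    out[[tm]] <- E
  }
  out
}

# observation-expanded sum of squares per model term: the squared norm of
# the term's effect expanded to the rows it applies to
term_ss <- function(design, beta) {
  vapply(setNames(design$terms, design$terms), function(tm) {
    cols <- design$term_cols[[tm]]
    sum((design$X[, cols, drop = FALSE] %*% beta[cols])^2)
  }, numeric(1))
}

#' @export
print.lmm_fits <- function(x, ...) {
  cat("<lmm_fits>", length(x$fits), "variables,",
      x$design$n_obs, "blocks,", x$design$n_groups, "wheels\n")
  print(glance(x))
  invisible(x)
}

#' @export
#' @rdname fit_lmm
#' @param x An `lmm_fits` object.
#' @param ... Unused.
tidy.lmm_fits <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    purrr::map_dfr(names(x$design$contrasts), function(fac) {
      if (is.null(f$level_effects[[fac]])) return(NULL)
      tibble::tibble(variable = f$variable, factor = fac,
                     level = names(f$level_effects[[fac]]),
                     effect = unname(f$level_effects[[fac]]))
    })
  })
}

#' @export
#' @rdname fit_lmm
glance.lmm_fits <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    tibble::tibble(variable = f$variable, sigma2_wheel = f$sigma2_wheel,
                   sigma2_eps = f$sigma2_eps,
                   variance_ratio = f$variance_ratio,
                   loglik_reml = f$loglik_reml, converged = f$converged)
  })
}

#' Extract reconstructed level effects
#'
#' @param fits An `lmm_fits` object.
#' @param factor One of the model terms (`"position"`, `"time"`, `"dairy"`
#'   or a two-way interaction such as `"position:dairy"`).
#' @return A tibble `variable`, `level`, `effect`; interaction levels are
#'   labelled `levelA:levelB` (first factor varying fastest).
#' @export
level_effects <- function(fits, factor) {
  stopifnot(inherits(fits, "lmm_fits"))
  if (!factor %in% fits$design$terms) {
    abort(paste0("unknown factor: ", factor, "; model terms are ",
                 paste(fits$design$terms, collapse = ", ")),
          class = "lmmasca_config_error")
  }
  purrr::map_dfr(fits$fits, function(f) {
    e <- f$level_effects[[factor]]
    if (is.matrix(e)) {
      labs <- as.vector(outer(rownames(e), colnames(e), paste, sep = ":"))
      tibble::tibble(variable = f$variable, level = labs,
                     effect = as.vector(e))
    } else {
      tibble::tibble(variable = f$variable, level = names(e),
                     effect = unname(e))
    }
  })
}

#' Per-term sums of squares
#'
#' The observation-expanded sum of squares of each model term: every row
#' contributes the square of its level's estimated effect. This is the test
#' statistic of the permutation test.
#'
#' @param fits An `lmm_fits` object.
#' @param terms Terms to report (default all).
#' @return A tibble `variable`, `term`, `ss`.
#' @export
factor_ss <- function(fits, terms = NULL) {
  stopifnot(inherits(fits, "lmm_fits"))
  terms <- terms %||% fits$design$terms
  bad <- setdiff(terms, fits$design$terms)
  if (length(bad) > 0) {
    abort(paste0("unknown term(s): ", paste(bad, collapse = ", ")),
          class = "lmmasca_config_error")
  }
  purrr::map_dfr(fits$fits, function(f) {
    tibble::tibble(variable = f$variable, term = terms,
                   ss = unname(f$factor_ss[terms]))
  })
}

# restricted log-likelihood of one response at a fixed variance ratio
# (used by optimality diagnostics and tests)
reml_objective <- function(design, y, lambda) {
  reml_loglik_cpp(design$X, y, design$group, design$n_groups, lambda)
}
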