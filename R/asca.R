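#' Assemble the effect matrix of a factor
#'
#' Collects the reconstructed level effects of one factor across all fitted
#' variables into a levels-by-variables matrix and centers every column
#' (with sum-to-zero coding the column sums are already zero up to
#' estimation error on balanced data, so centering is a numerical no-op
#' there). This matrix is the multivariate summary of the factor that the
#' simultaneous component analysis decomposes.
#'
#' @param fits An `lmm_fits` object covering all six variables.
#' @param factor A model term (main factor, or a two-way interaction — the
#'   rows are then level pairs).
#' @param center Center the columns (default `TRUE`).
#' @return A numeric matrix (levels x variables) of class `effect_matrix`
#'   with attributes `factor` and `centered`.
#' @export
effect_matrix <- function(fits, factor, center = TRUE) {
  eff <- level_effects(fits, factor)
  wide <- tidyr::pivot_wider(eff, names_from = "variable",
                             values_from = "effect")
  X <- as.matrix(wide[, -1, drop = FALSE])
  rownames(X) <- wide$level
  missing <- setdiff(variable_names(), colnames(X))
  if (length(missing) > 0) {
    abort(paste0("missing fitted variable(s): ",
                 paste(missing, collapse = ", ")),
          class = "lmmasca_value_error")
  }
  X <- X[, intersect(variable_names(), colnames(X)), drop = FALSE]
  if (center) X <- scale(X, center = TRUE, scale = FALSE)
  attr(X, "scaled:center") <- NULL
  structure(X, factor = factor, centered = center,
            class = c("effect_matrix", "matrix", "array"))
}

#' @method tidy effect_matrix
#' @export
tidy.effect_matrix <- function(x, ...) {
  tibble::tibble(
    factor = attr(x, "factor"),
    level = rep(rownames(x), times = ncol(x)),
    variable = rep(colnames(x), each = nrow(x)),
    effect = as.vector(x)
  )
}

#' Simultaneous component analysis of a factor's effect matrix
#'
#' Thin singular value decomposition `X = U S V'` of the centered effect
#' matrix: scores are `U S` (one point per factor level), loadings are `V`
#' (one arrow per variable), and the explained-variance fraction of
#' component c is `S_c^2 / sum(S^2)`. Because the decomposed matrix holds
#' model effects rather than raw data, these fractions quantify exactly how
#' much of the factor's effect variance each component carries. Signs are
#' fixed deterministically: the largest-magnitude loading entry of each
#' component is made positive.
#'
#' @param x An `lmm_fits` object or an `effect_matrix`.
#' @param factor Model term to decompose (required for `lmm_fits` input).
#' @param threshold Cumulative explained-variance threshold used by
#'   [n_components()] (default 0.85).
#' @return An object of class `asca_model`: scores, loadings, singular
#'   values, explained-variance fractions, the retained-component count at
#'   `threshold` and the centered effect matrix. A zero effect matrix is
#'   flagged `degenerate` (explained variance undefined).
#' @export
asca <- function(x, factor = NULL, threshold = 0.85) {
  if (inherits(x, "lmm_fits")) {
    if (is.null(factor)) {
      abort("factor is required when decomposing an lmm_fits object",
            class = "lmmasca_config_error")
    }
    X <- effect_matrix(x, factor)
  } else if (inherits(x, "effect_matrix")) {
    X <- x
    factor <- factor %||% attr(x, "factor")
  } else {
    abort("x must be an lmm_fits or effect_matrix object",
          class = "lmmasca_config_error")
  }
  if (nrow(X) < 2) {
    abort("at least 2 levels are required", class = "lmmasca_value_error")
  }
  sv <- svd(X)
  d <- sv$d
  degenerate <- max(d) <= 1e-12 * max(1, nrow(X))
  U <- sv$u
  V <- sv$v
  # deterministic sign: largest |loading| per component positive
  for (c in seq_along(d)) {
    i <- which.max(abs(V[, c]))
    if (V[i, c] < 0) {
      V[, c] <- -V[, c]
      U[, c] <- -U[, c]
    }
  }
  scores <- U %*% diag(d, nrow = length(d))
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_along(d)))
  dimnames(V) <- list(colnames(X), paste0("PC", seq_along(d)))
  ev <- if (degenerate) rep(NA_real_, length(d)) else d^2 / sum(d^2)
  model <- structure(
    list(factor = factor, levels = rownames(X), scores = scores,
         loadings = V, singular_values = d, explained_variance = ev,
         threshold = threshold, degenerate = degenerate,
         effect_matrix = X),
    class = "asca_model"
  )
  model$n_components <- if (degenerate) NA_integer_ else
    n_components(model, threshold)
  model
}

#' @export
print.asca_model <- function(x, ...) {
  cat("<asca_model>", x$factor, ":", length(x$levels), "levels x",
      nrow(x$loadings), "variables\n")
  if (x$degenerate) {
    cat("  degenerate: all singular values are zero\n")
    return(invisible(x))
  }
  ev <- round(100 * x$explained_variance, 1)
  cat("  explained variance (%):", paste(ev, collapse = ", "), "\n")
  cat("  components for >=", 100 * x$threshold, "%:", x$n_components, "\n")
  invisible(x)
}

#' Number of components reaching an explained-variance threshold
#'
#' @param model An `asca_model`.
#' @param threshold Cumulative explained-variance target (default 0.85).
#' @return The smallest component count whose cumulative explained variance
#'   reaches the threshold.
#' @export
n_components <- function(model, threshold = 0.85) {
  stopifnot(inherits(model, "asca_model"))
  if (model$degenerate) {
    abort("explained variance is undefined for a degenerate (all-zero) model",
          class = "lmmasca_value_error")
  }
  which(cumsum(model$explained_variance) >= threshold - 1e-12)[1]
}

#' Variable contributions to the decomposition
#'
#' The contribution of variable j to component c is
#' `100 * loading[j, c]^2 / sum_j loading[j, c]^2`; aggregated over the
#' first `dims` components it is the explained-variance-weighted mean of the
#' per-component contributions. Contributions sum to 100 over variables.
#'
#' @param model An `asca_model`.
#' @param dims Number of leading components to aggregate over (default: the
#'   retained count at the model's threshold).
#' @param by_component Return the per-component contributions instead of
#'   the aggregate.
#' @return A tibble `variable`, `contribution` (and `component` when
#'   `by_component = TRUE`).
#' @export
asca_contributions <- function(model, dims = model$n_components,
                               by_component = FALSE) {
  stopifnot(inherits(model, "asca_model"))
  if (model$degenerate) {
    abort("contributions are undefined for a degenerate model",
          class = "lmmasca_value_error")
  }
  if (is.null(dims) || is.na(dims) || dims < 1 ||
      dims > length(model$singular_values)) {
    abort("dims must be between 1 and the number of components",
          class = "lmmasca_config_error")
  }
  L2 <- model$loadings^2
  contrib <- sweep(L2, 2, colSums(L2), "/") * 100
  if (by_component) {
    return(tibble::tibble(
      component = rep(seq_len(ncol(contrib)), each = nrow(contrib)),
      variable = rep(rownames(contrib), times = ncol(contrib)),
      contribution = as.vector(contrib)
    ))
  }
  ev <- model$explained_variance[seq_len(dims)]
  agg <- drop(contrib[, seq_len(dims), drop = FALSE] %*% ev) / sum(ev)
  tibble::tibble(variable = rownames(contrib), contribution = unname(agg))
}

#' Scores and scaled loading arrows for a biplot
#'
#' @param model An `asca_model`.
#' @param dims Pair of component indices (default `c(1, 2)`).
#' @return A tibble with `type` (`"score"` or `"loading"`), `label`, `x`,
#'   `y`; loading arrows are multiplied by a common scale factor (attribute
#'   `"arrow_scale"`, chosen so the longest arrow matches the score spread)
#'   and can be unscaled exactly by dividing it out.
#' @export
biplot_data <- function(model, dims = c(1, 2)) {
  stopifnot(inherits(model, "asca_model"))
  k <- length(model$singular_values)
  if (length(dims) != 2 || any(dims < 1) || any(dims > k)) {
    abort(paste0("dims must be two component indices in 1..", k),
          class = "lmmasca_config_error")
  }
  sc <- model$scores[, dims, drop = FALSE]
  ld <- model$loadings[, dims, drop = FALSE]
  s <- max(abs(sc))
  l <- max(abs(ld))
  arrow_scale <- if (l > 0) s / l else 1
  out <- dplyr::bind_rows(
    tibble::tibble(type = "score", label = rownames(sc),
                   x = sc[, 1], y = sc[, 2]),
    tibble::tibble(type = "loading", label = rownames(ld),
                   x = ld[, 1] * arrow_scale, y = ld[, 2] * arrow_scale)
  )
  attr(out, "arrow_scale") <- arrow_scale
  attr(out, "dims") <- dims
  out
}

#' @export
#' @rdname asca
#' @param matrix Which component to tidy: `"scores"`, `"loadings"` or
#'   `"variance"`.
#' @param ... Unused.
tidy.asca_model <- function(x, matrix = c("scores", "loadings", "variance"),
                            ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") {
    tibble::tibble(level = rep(rownames(x$scores), times = ncol(x$scores)),
                   component = rep(seq_len(ncol(x$scores)),
                                   each = nrow(x$scores)),
                   score = as.vector(x$scores))
  } else if (matrix == "loadings") {
    tibble::tibble(variable = rep(rownames(x$loadings),
                                  times = ncol(x$loadings)),
                   component = rep(seq_len(ncol(x$loadings)),
                                   each = nrow(x$loadings)),
                   loading = as.vector(x$loadings))
  } else {
    tibble::tibble(component = seq_along(x$singular_values),
                   singular_value = x$singular_values,
                   explained_variance = x$explained_variance,
                   cumulative = cumsum(x$explained_variance))
  }
}

#' @export
#' @rdname asca
glance.asca_model <- function(x, ...) {
  tibble::tibble(factor = x$factor, n_levels = length(x$levels),
                 n_components = x$n_components, threshold = x$threshold,
                 cumulative_at_n = if (x$degenerate) NA_real_ else
                   cumsum(x$explained_variance)[x$n_components],
                 degenerate = x$degenerate)
}

#' Levels within a score band around the overall mean
#'
#' Descriptive helper for reading biplots: returns, for one component, the
#' levels whose scores fall inside `[-band, band]` — "not notably different
#' from the overall mean" in the report sense. The band is a plain
#' reporting threshold with no inferential meaning; choose it per
#' application.
#'
#' @param model An `asca_model`.
#' @param component Component index (default 1).
#' @param band Half-width of the band on the score scale (default 0.55).
#' @return A tibble `level`, `score`, `within_band` for the chosen
#'   component.
#' @export
score_band_levels <- function(model, component = 1, band = 0.55) {
  stopifnot(inherits(model, "asca_model"))
  k <- length(model$singular_values)
  if (component < 1 || component > k) {
    abort(paste0("component must be in 1..", k),
          class = "lmmasca_config_error")
  }
  s <- model$scores[, component]
  tibble::tibble(level = model$levels, score = unname(s),
                 within_band = abs(s) <= band)
}
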