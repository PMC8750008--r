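#' Standardize the response variables
#'
#' Centers every response column and scales it to unit variance (the
#' (n-1) sample standard deviation), computed once over the whole table so
#' every downstream model sees comparable variables. The scaling parameters
#' are attached to the result and permit an exact inverse transform.
#'
#' @param blocks A validated block tibble.
#' @return The standardized tibble, with a `"scaling"` attribute (a tibble
#'   `variable`, `mean`, `sd`) retrievable via [scaling_params()].
#' @seealso [unstandardize_blocks()]
#' @export
standardize_blocks <- function(blocks) {
  blocks <- validate_blocks(blocks)
  vars <- variable_names()
  mu <- vapply(blocks[vars], mean, numeric(1))
  s <- vapply(blocks[vars], sd, numeric(1))
  if (any(!is.finite(s) | s <= 0)) {
    bad <- vars[!is.finite(s) | s <= 0]
    abort(paste0("constant (or too short) variable(s) cannot be standardized: ",
                 paste(bad, collapse = ", ")),
          class = "lmmasca_degenerate_scale_error")
  }
  out <- blocks
  for (v in vars) out[[v]] <- (blocks[[v]] - mu[v]) / s[v]
  attr(out, "scaling") <- tibble::tibble(variable = vars, mean = unname(mu),
                                         sd = unname(s))
  out
}

#' @rdname standardize_blocks
#' @param x A tibble returned by `standardize_blocks()`.
#' @export
scaling_params <- function(x) {
  sc <- attr(x, "scaling")
  if (is.null(sc)) {
    abort("no scaling attribute: was this table standardized?",
          class = "lmmasca_config_error")
  }
  sc
}

#' Invert a standardization
#'
#' @param blocks A standardized block tibble.
#' @param scaling A scaling tibble (`variable`, `mean`, `sd`); defaults to the
#'   one attached to `blocks`.
#' @return The tibble on the original scale.
#' @export
unstandardize_blocks <- function(blocks, scaling = scaling_params(blocks)) {
  out <- blocks
  for (i in seq_len(nrow(scaling))) {
    v <- scaling$variable[i]
    out[[v]] <- blocks[[v]] * scaling$sd[i] + scaling$mean[i]
  }
  attr(out, "scaling") <- NULL
  out
}

#' Normal quantile-quantile diagnostic
#'
#' Compares a sample with the standard normal distribution: sorted values are
#' paired with normal quantiles at plotting positions `(i - 0.5) / n` and
#' summarised by their Pearson correlation (1 for perfectly normal-shaped
#' data; heavy skew or tails pull it down). Used as a pre-modelling check of
#' the residual-normality assumption; nothing is excluded automatically.
#'
#' @param x Numeric vector, at least 3 finite values, not all equal.
#' @param variable Optional variable name carried into the output.
#' @return An object of class `qq_diag`: list with `correlation` and
#'   `points` (tibble `theoretical`, `sample`). `tidy()` returns the points,
#'   `glance()` the correlation.
#' @export
qq_diagnostic <- function(x, variable = NA_character_) {
  x <- x[is.finite(x)]
  if (length(x) < 3) {
    abort("qq_diagnostic needs at least 3 finite values",
          class = "lmmasca_value_error")
  }
  if (max(x) == min(x)) {
    abort("qq_diagnostic is undefined for a constant vector",
          class = "lmmasca_degenerate_scale_error")
  }
  n <- length(x)
  q <- qnorm((seq_len(n) - 0.5) / n)
  s <- sort(x)
  structure(
    list(
      variable = variable,
      correlation = stats::cor(q, s),
      points = tibble::tibble(theoretical = q, sample = s)
    ),
    class = "qq_diag"
  )
}

#' @export
print.qq_diag <- function(x, ...) {
  cat("<qq_diag>", if (!is.na(x$variable)) x$variable else "",
      " n =", nrow(x$points),
      " correlation =", format(x$correlation, digits = 6), "\n")
  invisible(x)
}

#' @method tidy qq_diag
#' @export
tidy.qq_diag <- function(x, ...) {
  dplyr::mutate(x$points, variable = x$variable, .before = 1)
}

#' @method glance qq_diag
#' @export
glance.qq_diag <- function(x, ...) {
  tibble::tibble(variable = x$variable, n = nrow(x$points),
                 correlation = x$correlation)
}

#' QQ diagnostics for every response variable
#'
#' @param blocks A block tibble.
#' @return A tibble `variable`, `n`, `correlation`, one row per response.
#' @export
qq_summary <- function(blocks) {
  purrr::map_dfr(variable_names(),
                 function(v) glance(qq_diagnostic(blocks[[v]], v)))
}
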