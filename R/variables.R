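#' The measured cheese-block variables
#'
#' Every block is characterised by six physical responses: the CIELAB colour
#' coordinates (`L` lightness, `a` green-red, `b` blue-yellow, all
#' dimensionless) and three texture parameters from uniaxial compression
#' (`Fmax`, maximum force, N; `Ac`, area under the force/strain curve, N.mm;
#' `El`, elastic modulus, the slope of the linear part of the stress-strain
#' curve, N/mm). The order is fixed and every table in the package carries the
#' six value columns in this order.
#'
#' @return A tibble with columns `variable`, `unit` and `type`
#'   (`"colour"` or `"texture"`), one row per variable, in canonical order.
#' @export
#' @examples
#' block_variables()
block_variables <- function() {
  tibble::tibble(
    variable = c("L", "a", "b", "Fmax", "Ac", "El"),
    unit     = c("dimensionless", "dimensionless", "dimensionless",
                 "N", "N.mm", "N/mm"),
    type     = c("colour", "colour", "colour", "texture", "texture", "texture")
  )
}

#' @rdname block_variables
#' @export
variable_names <- function() block_variables()$variable

#' Sampling-position codes
#'
#' The six annular sampling zones of a wheel cross-section, ordered by
#' decreasing distance from the wheel centre: round (`RND`), round central
#' (`RNDs`), external plate (`RNDp1`), intermediate zone (`Int`), internal
#' plate (`RNDp2`) and centre (`CNT`). The integer encoding 1..6 follows this
#' order.
#'
#' @return Character vector of the six codes in canonical order.
#' @export
position_levels <- function() c("RND", "RNDs", "RNDp1", "Int", "RNDp2", "CNT")

#' Time-period labels
#'
#' The twelve bi-monthly sampling sessions of a two-year campaign collapse to
#' six couple-of-months periods: `time = ((session - 1) mod 6) + 1`. Labels
#' name the month pairs.
#'
#' @return Character vector of the six period labels in calendar order.
#' @export
time_levels <- function() {
  c("JanFeb", "MarApr", "MayJun", "JulAug", "SepOct", "NovDec")
}

#' @rdname time_levels
#' @param session Integer vector of session numbers (1..12).
#' @return `session_to_time()`: integer vector of time levels in 1..6.
#' @export
session_to_time <- function(session) ((as.integer(session) - 1L) %% 6L) + 1L

# factor columns every block table must carry, in canonical order
factor_columns <- function() {
  c("dairy", "session", "time", "wheel_id", "position", "replicate")
}

# the six model terms tested, in reporting order, with the short codes used
# in the significance tile plot
model_terms <- function() {
  c("position", "time", "dairy", "position:time", "position:dairy",
    "time:dairy")
}

term_codes <- function() {
  c(position = "S", time = "T", dairy = "D",
    `position:time` = "S:T", `position:dairy` = "D:S", `time:dairy` = "D:T")
}
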