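#' Read and write block-measurement tables
#'
#' The canonical on-disk layout is a UTF-8 comma-separated file with header
#' `dairy,session,time,wheel_id,position,replicate,L,a,b,Fmax,Ac,El` — one row
#' per measured cheese block, the six responses in wide form (all six are
#' measured on every block). `read_blocks()` coerces the factor columns to
#' factors with canonical level order and validates the table;
#' `write_blocks()` is its inverse up to floating-point formatting.
#'
#' @param path Path to a CSV file.
#' @return `read_blocks()`: a validated block tibble (see [validate_blocks()]).
#' @seealso [validate_blocks()], [simulate_blocks()]
#' @export
read_blocks <- function(path) {
  spec <- readr::cols(
    dairy = readr::col_character(),
    session = readr::col_integer(),
    time = readr::col_integer(),
    wheel_id = readr::col_character(),
    position = readr::col_character(),
    replicate = readr::col_integer(),
    .default = readr::col_double()
  )
  raw <- suppressWarnings(readr::read_csv(path, col_types = spec,
                                          progress = FALSE))
  missing <- setdiff(c(factor_columns(), variable_names()), names(raw))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "lmmasca_schema_error")
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("could not parse ", nrow(probs), " cell(s); first problem: ",
                 "row ", probs$row[1], ", expected ", probs$expected[1]),
          class = "lmmasca_parse_error")
  }
  validate_blocks(as_block_table(raw))
}

#' @rdname read_blocks
#' @param blocks A validated block tibble.
#' @return `write_blocks()`: `blocks`, invisibly.
#' @export
write_blocks <- function(blocks, path) {
  blocks <- validate_blocks(blocks)
  out <- dplyr::mutate(
    blocks,
    dairy = as.character(.data$dairy),
    session = as.integer(as.character(.data$session)),
    time = as.integer(.data$time),
    wheel_id = as.character(.data$wheel_id),
    position = as.character(.data$position),
    replicate = as.integer(.data$replicate)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(blocks)
}

# coerce raw columns to the canonical factor representation; time is stored
# on disk as 1..6 and represented in memory as a labelled factor
as_block_table <- function(x) {
  x <- tibble::as_tibble(x)
  sess <- as.integer(if (is.factor(x$session)) as.character(x$session) else x$session)
  tim <- if (is.factor(x$time) || is.character(x$time)) {
    match(as.character(x$time), time_levels())
  } else {
    as.integer(x$time)
  }
  if (length(tim) > 0 && any(is.na(tim) | tim < 1L | tim > 6L)) {
    abort("time must be coded 1..6 (or the matching period labels)",
          class = "lmmasca_schema_error")
  }
  dplyr::mutate(
    x,
    dairy = factor(.data$dairy),
    session = factor(sess, levels = sort(unique(sess))),
    time = factor(time_levels()[tim], levels = time_levels()[sort(unique(tim))]),
    wheel_id = factor(.data$wheel_id),
    position = factor(.data$position, levels = position_levels()),
    replicate = as.integer(.data$replicate)
  ) |>
    dplyr::select(dplyr::all_of(c(factor_columns(), variable_names())))
}

#' Validate a block-measurement table
#'
#' Checks the structural invariants of the sampling design: required columns
#' present; `time` a deterministic function of `session`
#' (`((session - 1) mod 6) + 1`); every `wheel_id` nested in exactly one
#' `(dairy, session)` cell; every wheel carrying the same set of sampling
#' positions; all six responses finite (missing values are rejected, not
#' imputed).
#'
#' @param blocks A data frame of block measurements.
#' @return The validated table as a tibble (factor columns coerced), invisibly
#'   classed as before; errors of class `lmmasca_schema_error`,
#'   `lmmasca_nesting_error` or `lmmasca_value_error` otherwise.
#' @export
validate_blocks <- function(blocks) {
  missing <- setdiff(c(factor_columns(), variable_names()), names(blocks))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "lmmasca_schema_error")
  }
  if (!all(vapply(blocks[variable_names()], is.numeric, logical(1)))) {
    abort("response columns must be numeric", class = "lmmasca_parse_error")
  }
  if (!is.factor(blocks$time)) blocks <- as_block_table(blocks)
  if (nrow(blocks) == 0) return(blocks)

  bad_pos <- is.na(blocks$position)
  if (any(bad_pos)) {
    abort(paste0("unknown sampling-position code(s); allowed: ",
                 paste(position_levels(), collapse = ", ")),
          class = "lmmasca_schema_error")
  }
  sess <- as.integer(as.character(blocks$session))
  tim <- match(as.character(blocks$time), time_levels())
  if (any(tim != session_to_time(sess))) {
    abort("time must equal ((session - 1) mod 6) + 1",
          class = "lmmasca_schema_error")
  }
  vals <- as.matrix(blocks[variable_names()])
  if (any(!is.finite(vals))) {
    abort("non-finite or missing response values are not allowed",
          class = "lmmasca_value_error")
  }
  cells <- unique(blocks[, c("wheel_id", "dairy", "session")])
  dup <- duplicated(cells$wheel_id)
  if (any(dup)) {
    abort(paste0("wheel(s) appearing under more than one dairy/session cell: ",
                 paste(unique(as.character(cells$wheel_id[dup])), collapse = ", ")),
          class = "lmmasca_nesting_error")
  }
  pos_sets <- tapply(as.character(blocks$position), blocks$wheel_id,
                     function(p) paste(sort(unique(p)), collapse = "|"))
  pos_sets <- pos_sets[!is.na(pos_sets)]
  if (length(unique(pos_sets)) > 1) {
    abort("every wheel must carry the same set of sampling positions",
          class = "lmmasca_nesting_error")
  }
  blocks
}
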