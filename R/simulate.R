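#' Default wheel allocation for the two-year sampling campaign
#'
#' The campaign samples 1 to 3 wheels per dairy per bi-monthly session,
#' proportional to each dairy's production volume, for a grand total of 317
#' wheels over 15 dairies and 12 sessions. Production volumes per dairy are
#' not public, so the default is a fixed, documented table reproducing every
#' printed design count: dairies `C-1`..`C-6` deliver one wheel per session,
#' `C-7`..`C-12` two, and `C-13`..`C-15` three — except that `C-15` delivers
#' two wheels in sessions 1–7, bringing the total from 324 down to 317. 317
#' is not divisible by 12, so no strictly constant-per-dairy table can reach
#' it; a single dairy with a volume dip is the smallest deviation.
#'
#' @return A tibble with columns `dairy` (factor, 15 levels), `session`
#'   (integer 1..12) and `n_wheels` (integer in 1..3); 180 rows summing to
#'   317 wheels.
#' @export
#' @examples
#' sum(default_allocation()$n_wheels)
default_allocation <- function() {
  dairies <- paste0("C-", 1:15)
  base <- rep(c(1L, 2L, 3L), times = c(6, 6, 3))
  alloc <- tidyr::expand_grid(
    dairy = factor(dairies, levels = dairies),
    session = 1:12
  )
  alloc$n_wheels <- base[match(as.character(alloc$dairy), dairies)]
  dip <- alloc$dairy == "C-15" & alloc$session <= 7
  alloc$n_wheels[dip] <- 2L
  alloc
}

#' Generate the sampling-design skeleton
#'
#' Expands a wheel-allocation table into one row per cheese block: each
#' allocated wheel contributes the six sampling positions times
#' `replicates` blocks, with `time = ((session - 1) mod 6) + 1` derived from
#' the session. Responses are not set; pass the result to
#' [simulate_blocks()].
#'
#' @param alloc Allocation tibble with columns `dairy`, `session`,
#'   `n_wheels` (see [default_allocation()]).
#' @param replicates Blocks per sampling position per wheel (default 4, the
#'   equal split of 24 blocks over 6 positions).
#' @return A tibble with the canonical factor columns `dairy`, `session`,
#'   `time`, `wheel_id`, `position`, `replicate` and no response columns.
#' @export
#' @examples
#' nrow(generate_design(default_allocation()))  # 7608
generate_design <- function(alloc, replicates = 4L) {
  stopifnot(is.data.frame(alloc),
            all(c("dairy", "session", "n_wheels") %in% names(alloc)))
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    abort("replicates must be a positive integer", class = "lmmasca_config_error")
  }
  if (any(alloc$n_wheels < 1L)) {
    abort("every allocation cell needs at least one wheel",
          class = "lmmasca_config_error")
  }
  dairy_lev <- if (is.factor(alloc$dairy)) levels(alloc$dairy) else unique(as.character(alloc$dairy))
  dairy_lev <- intersect(dairy_lev, unique(as.character(alloc$dairy)))
  wheels <- tidyr::uncount(alloc, weights = .data$n_wheels, .id = "wheel_no")
  wheels$wheel_id <- sprintf("%s_s%02d_w%d", wheels$dairy, wheels$session,
                             wheels$wheel_no)
  design <- tidyr::expand_grid(
    wheels[, c("dairy", "session", "wheel_id")],
    position = factor(position_levels(), levels = position_levels()),
    replicate = seq_len(replicates)
  )
  sess <- sort(unique(as.integer(design$session)))
  tim <- session_to_time(design$session)
  tibble::tibble(
    dairy = factor(as.character(design$dairy), levels = dairy_lev),
    session = factor(as.integer(design$session), levels = sess),
    time = factor(time_levels()[tim],
                  levels = time_levels()[sort(unique(tim))]),
    wheel_id = factor(design$wheel_id, levels = unique(design$wheel_id)),
    position = design$position,
    replicate = as.integer(design$replicate)
  )
}

# sum-to-zero level pattern for a planted effect: orthogonal-polynomial
# column of the requested degree, rescaled to unit root-mean-square so an
# amplitude of 1 means level effects of typical size 1
effect_pattern <- function(n_levels, degree) {
  if (n_levels < 2L) return(rep(0, n_levels))
  cp <- contr.poly(n_levels)
  # cycle over at most cubic patterns so variables share level structure
  # (colour and texture responses co-vary in real data)
  degree <- ((degree - 1L) %% min(3L, ncol(cp))) + 1L
  cp[, degree] * sqrt(n_levels)
}

#' Simulation configuration for the block-response generative model
#'
#' Describes the additive generative model for one block's response on
#' variable j:
#' `value = mu_j + alpha[position, j] + beta[time, j] + gamma[dairy, j] +
#'  ab[position, time, j] + ag[position, dairy, j] + bg[time, dairy, j] +
#'  delta[wheel, j] + eps`,
#' with `delta ~ N(0, sigma_wheel_j^2)` drawn once per wheel per variable and
#' `eps ~ N(0, sigma_eps_j^2)` per block (jointly across variables when
#' `residual_corr` is given). All effect arrays are in sum-to-zero form over
#' every factor margin.
#'
#' By default the effect arrays are built from fixed orthogonal-polynomial
#' level patterns scaled by per-variable amplitudes (in units of the residual
#' standard deviation). The default amplitudes plant the significance pattern
#' the campaign is designed to detect: position and dairy effects on all six
#' variables, a time effect on `L`, `b`, `Fmax`, `El` only, a
#' position-by-time interaction on the colour variables only, a
#' position-by-dairy interaction on all but `El`, and no time-by-dairy
#' interaction.
#'
#' @param n_dairies,n_times Number of dairy and time levels the effect arrays
#'   are built for (must match the design simulated from).
#' @param mu Grand mean per variable (length 6, raw units).
#' @param sigma_eps Residual standard deviation per variable (length 6, > 0).
#' @param sigma_wheel Wheel random-intercept standard deviation per variable
#'   (length 6, >= 0).
#' @param amplitude Named list of per-variable effect amplitudes (each length
#'   6 or scalar, residual-SD units) with elements `position`, `time`,
#'   `dairy`, `position_time`, `position_dairy`, `time_dairy`.
#' @param alpha,beta,gamma Optional explicit main-effect matrices
#'   (levels x 6 variables, sum-to-zero columns); override the
#'   amplitude-built defaults.
#' @param ab,ag,bg Optional explicit interaction arrays
#'   (levels_1 x levels_2 x 6, sum-to-zero over both factor margins).
#' @param residual_corr Optional 6x6 cross-variable residual correlation
#'   matrix (symmetric PSD, unit diagonal).
#' @param replicates Blocks per position per wheel (default 4).
#' @param seed Optional integer seed stored with the configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_dairies = 15L, n_times = 6L,
                       mu = c(L = 80, a = -2.5, b = 22, Fmax = 260,
                              Ac = 1100, El = 42),
                       sigma_eps = c(2, 0.4, 1.5, 35, 160, 7),
                       sigma_wheel = sigma_eps / 2,
                       amplitude = list(),
                       alpha = NULL, beta = NULL, gamma = NULL,
                       ab = NULL, ag = NULL, bg = NULL,
                       residual_corr = NULL,
                       replicates = 4L, seed = NULL) {
  nv <- 6L
  vars <- variable_names()
  amp_default <- list(
    position       = rep(0.8, nv),
    time           = c(0.4, 0, 0.4, 0.4, 0, 0.4),
    dairy          = rep(0.6, nv),
    position_time  = c(0.15, 0.15, 0.15, 0, 0, 0),
    position_dairy = c(0.15, 0.15, 0.15, 0.15, 0.15, 0),
    time_dairy     = rep(0, nv)
  )
  unknown <- setdiff(names(amplitude), names(amp_default))
  if (length(unknown) > 0) {
    abort(paste0("unknown amplitude component(s): ",
                 paste(unknown, collapse = ", ")),
          class = "lmmasca_config_error")
  }
  amp <- utils::modifyList(amp_default, amplitude)
  amp <- lapply(amp, function(a) {
    a <- rep_len(as.numeric(a), nv)
    names(a) <- vars
    a
  })
  stopifnot(length(mu) == nv, length(sigma_eps) == nv,
            length(sigma_wheel) == nv)
  if (any(sigma_eps <= 0)) {
    abort("sigma_eps must be strictly positive", class = "lmmasca_config_error")
  }
  if (any(sigma_wheel < 0)) {
    abort("sigma_wheel must be non-negative", class = "lmmasca_config_error")
  }

  main_effect <- function(K, amps) {
    m <- matrix(vapply(seq_len(nv),
                       function(j) amps[j] * sigma_eps[j] * effect_pattern(K, j),
                       numeric(K)),
                nrow = K, ncol = nv)
    colnames(m) <- vars
    m
  }
  inter_effect <- function(K1, K2, amps) {
    arr <- array(0, dim = c(K1, K2, nv), dimnames = list(NULL, NULL, vars))
    for (j in seq_len(nv)) {
      arr[, , j] <- amps[j] * sigma_eps[j] *
        outer(effect_pattern(K1, j), effect_pattern(K2, j + 1L))
    }
    arr
  }
  cfg <- list(
    n_dairies = as.integer(n_dairies), n_times = as.integer(n_times),
    mu = setNames(as.numeric(mu), vars),
    sigma_eps = setNames(as.numeric(sigma_eps), vars),
    sigma_wheel = setNames(as.numeric(sigma_wheel), vars),
    amplitude = amp,
    alpha = alpha %||% main_effect(6L, amp$position),
    beta = beta %||% main_effect(n_times, amp$time),
    gamma = gamma %||% main_effect(n_dairies, amp$dairy),
    ab = ab %||% inter_effect(6L, n_times, amp$position_time),
    ag = ag %||% inter_effect(6L, n_dairies, amp$position_dairy),
    bg = bg %||% inter_effect(n_times, n_dairies, amp$time_dairy),
    residual_corr = residual_corr,
    replicates = as.integer(replicates),
    seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  tol <- 1e-8
  check_zero <- function(x, what) {
    if (max(abs(x)) > tol) {
      abort(paste0(what, " must sum to zero over every factor margin"),
            class = "lmmasca_config_error")
    }
  }
  check_zero(colSums(cfg$alpha), "position effects")
  check_zero(colSums(cfg$beta), "time effects")
  check_zero(colSums(cfg$gamma), "dairy effects")
  check_zero(apply(cfg$ab, c(2, 3), sum), "position:time effects")
  check_zero(apply(cfg$ab, c(1, 3), sum), "position:time effects")
  check_zero(apply(cfg$ag, c(2, 3), sum), "position:dairy effects")
  check_zero(apply(cfg$ag, c(1, 3), sum), "position:dairy effects")
  check_zero(apply(cfg$bg, c(2, 3), sum), "time:dairy effects")
  check_zero(apply(cfg$bg, c(1, 3), sum), "time:dairy effects")
  if (!is.null(cfg$residual_corr)) {
    R <- cfg$residual_corr
    if (!isTRUE(all.equal(R, t(R))) || max(abs(diag(R) - 1)) > tol) {
      abort("residual_corr must be symmetric with unit diagonal",
            class = "lmmasca_config_error")
    }
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -tol) {
      abort("residual_corr must be positive semi-definite",
            class = "lmmasca_config_error")
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_dairies, "dairies,", x$n_times, "time levels,",
      x$replicates, "replicates/position\n")
  cat("  amplitudes (residual-SD units):\n")
  for (nm in names(x$amplitude)) {
    cat("   ", format(nm, width = 15), paste(format(x$amplitude[[nm]],
        digits = 2), collapse = " "), "\n")
  }
  invisible(x)
}

#' Simulate block responses from the generative model
#'
#' Fills a design skeleton (see [generate_design()]) with responses drawn
#' from the additive model described in [sim_config()]. The wheel random
#' intercept is drawn once per wheel per variable; residuals are drawn per
#' block, jointly across variables when the configuration carries a residual
#' correlation matrix. Two calls with the same seed produce identical tables.
#'
#' @param design A design skeleton tibble.
#' @param config A [sim_config()] object whose effect arrays conform to the
#'   design's level counts.
#' @param seed Integer seed; overrides `config$seed`. One of the two must be
#'   supplied.
#' @return A validated block tibble with the six response columns filled.
#' @export
#' @examples
#' d <- generate_design(default_allocation()[1:12, ], replicates = 2)
#' head(simulate_blocks(d, sim_config(n_dairies = 1), seed = 1))
simulate_blocks <- function(design, config = sim_config(), seed = NULL) {
  seed <- seed %||% config$seed
  if (is.null(seed)) {
    abort("a seed is required (argument or config$seed)",
          class = "lmmasca_config_error")
  }
  ki <- as.integer(design$position)
  li <- as.integer(design$time)
  gi <- as.integer(design$dairy)
  wi <- as.integer(design$wheel_id)
  nlv <- c(position = max(ki), time = nlevels(design$time),
           dairy = nlevels(design$dairy))
  if (nrow(config$beta) != nlv[["time"]] || nrow(config$gamma) != nlv[["dairy"]] ||
      dim(config$ag)[2] != nlv[["dairy"]] || dim(config$ab)[2] != nlv[["time"]] ||
      dim(config$bg)[1] != nlv[["time"]] || dim(config$bg)[2] != nlv[["dairy"]]) {
    abort("config effect arrays do not conform to the design's level counts",
          class = "lmmasca_config_error")
  }
  n <- nrow(design); nv <- 6L; W <- nlevels(design$wheel_id)
  withr::with_seed(as.integer(seed), {
    delta <- matrix(rnorm(W * nv), W, nv) %*% diag(config$sigma_wheel)
    if (is.null(config$residual_corr)) {
      eps <- matrix(rnorm(n * nv), n, nv) %*% diag(config$sigma_eps)
    } else {
      L <- chol_psd(config$residual_corr)
      eps <- (matrix(rnorm(n * nv), n, nv) %*% L) %*% diag(config$sigma_eps)
    }
    vals <- matrix(0, n, nv, dimnames = list(NULL, variable_names()))
    for (j in seq_len(nv)) {
      vals[, j] <- config$mu[j] + config$alpha[ki, j] + config$beta[li, j] +
        config$gamma[gi, j] +
        config$ab[cbind(ki, li, j)] + config$ag[cbind(ki, gi, j)] +
        config$bg[cbind(li, gi, j)] +
        delta[wi, j] + eps[, j]
    }
    validate_blocks(dplyr::bind_cols(design, tibble::as_tibble(vals)))
  })
}

# upper-triangular square root tolerant of semi-definite matrices
chol_psd <- function(R) {
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  ei <- eigen(R, symmetric = TRUE)
  ev <- pmax(ei$values, 0)
  t(ei$vectors %*% diag(sqrt(ev)) %*% t(ei$vectors))
}
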