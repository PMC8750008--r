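# independent GLS oracle at a fixed variance ratio: whiten each wheel by
# shrinking its group mean, then ordinary least squares
gls_oracle <- function(design, y, lambda) {
  g <- design$group
  m <- as.vector(table(g))
  theta <- 1 - 1 / sqrt(1 + lambda * m)
  Xb <- rowsum(design$X, g) / m
  yb <- rowsum(y, g)[, 1] / m
  Xw <- design$X - theta[g] * Xb[g, , drop = FALSE]
  yw <- y - theta[g] * yb[g]
  stats::lm.fit(Xw, yw)$coefficients
}

test_that("the default design expands to the expected model matrix", {
  d <- generate_design(default_allocation(), 4)
  blocks <- simulate_blocks(d, sim_config(), seed = 1)
  design <- build_design(blocks)
  expect_equal(dim(design$X), c(7608L, 190L))
  expect_equal(lengths(design$term_cols)[design$terms],
               c(position = 5L, time = 5L, dairy = 14L,
                 `position:time` = 25L, `position:dairy` = 70L,
                 `time:dairy` = 70L))
  # positions are balanced within every wheel, so their columns sum to zero
  expect_lt(max(abs(colSums(design$X[, design$term_cols$position]))), 1e-8)
  # on a fully balanced sub-design every non-intercept column sums to zero
  bal <- build_design(small_blocks(n_dairies = 3, n_sessions = 6, seed = 2))
  expect_lt(max(abs(colSums(bal$X[, -1]))), 1e-8)
})

test_that("degenerate one-cell designs reduce to a position-only model", {
  alloc <- tibble::tibble(dairy = "D", session = 1L, n_wheels = 3L)
  b <- simulate_blocks(generate_design(alloc, 3),
                       sim_config(n_dairies = 1, n_times = 1), seed = 2)
  design <- build_design(b)
  expect_equal(design$terms, "position")
  expect_equal(ncol(design$X), 6L)
})

test_that("sigma_wheel = 0 data reduce to the OLS solution", {
  b <- small_blocks(n_dairies = 3, n_sessions = 6, n_wheels = 2,
                    replicates = 2, seed = 4,
                    sigma_wheel = rep(0, 6))
  std <- standardize_blocks(b)
  fits <- fit_lmm(std, "L")
  design <- fits$design
  ols <- stats::lm.fit(design$X, design$blocks$L)$coefficients
  expect_lt(fits$fits$L$sigma2_wheel, 0.05)
  expect_equal(unname(fits$fits$L$beta), unname(ols), tolerance = 1e-6)
})

test_that("noiseless balanced simulations are interpolated exactly", {
  cfg <- sim_config(n_dairies = 3, n_times = 6,
                    sigma_eps = rep(1e-10, 6), sigma_wheel = rep(0, 6))
  d <- generate_design(small_alloc(3, 6), 2)
  b <- simulate_blocks(d, cfg, seed = 6)
  fits <- fit_lmm(b)
  for (j in seq_along(variable_names())) {
    v <- variable_names()[j]
    expect_equal(unname(fits$fits[[v]]$level_effects$position),
                 unname(cfg$alpha[, j]), tolerance = 1e-8)
    expect_equal(unname(fits$fits[[v]]$level_effects$time),
                 unname(cfg$beta[, j]), tolerance = 1e-8)
    expect_equal(unname(fits$fits[[v]]$level_effects$dairy),
                 unname(cfg$gamma[, j]), tolerance = 1e-8)
    # interaction effect matrices are recovered too
    expect_equal(unname(fits$fits[[v]]$level_effects[["position:time"]]),
                 unname(cfg$ab[, , j]), tolerance = 1e-8)
  }
})

test_that("variance components and likelihood agree with lme4", {
  skip_if_not_installed("lme4")
  b <- small_blocks(n_dairies = 4, n_sessions = 3, n_wheels = 3,
                    replicates = 2, seed = 5)
  std <- standardize_blocks(b)
  fits <- fit_lmm(std, c("L", "Fmax"))
  ctr <- list(position = "contr.sum", time = "contr.sum",
              dairy = "contr.sum")
  for (v in c("L", "Fmax")) {
    fml <- stats::as.formula(paste(v, "~ position + time + dairy +",
                                   "position:time + position:dairy +",
                                   "time:dairy + (1 | wheel_id)"))
    lf <- lme4::lmer(fml, data = fits$design$blocks, contrasts = ctr,
                     REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(lf))
    expect_equal(fits$fits[[v]]$sigma2_wheel, vc$vcov[1], tolerance = 1e-5)
    expect_equal(fits$fits[[v]]$sigma2_eps, vc$vcov[2], tolerance = 1e-6)
    expect_equal(-2 * fits$fits[[v]]$loglik_reml, lme4::REMLcrit(lf),
                 tolerance = 1e-8)
    expect_equal(unname(fits$fits[[v]]$beta), unname(lme4::fixef(lf)),
                 tolerance = 1e-6)
  }
})

test_that("on balanced designs level effects are invariant to the ratio", {
  b <- small_blocks(n_dairies = 3, n_sessions = 6, replicates = 2, seed = 7)
  std <- standardize_blocks(b)
  fits <- fit_lmm(std, "b")
  design <- fits$design
  y <- design$blocks$b
  ref <- gls_oracle(design, y, 0)
  for (lambda in c(1, 10)) {
    expect_equal(unname(gls_oracle(design, y, lambda)), unname(ref),
                 tolerance = 1e-8)
  }
  expect_equal(unname(fits$fits$b$beta), unname(ref), tolerance = 1e-8)
})

test_that("unbalanced level effects match a constrained least-squares oracle", {
  # 3 dairies with unequal wheel counts, essentially no noise
  a <- small_alloc(3, 2)
  a$n_wheels <- rep(c(1L, 2L, 3L), each = 2)
  cfg <- sim_config(n_dairies = 3, n_times = 2,
                    sigma_eps = rep(1e-8, 6), sigma_wheel = rep(0, 6))
  b <- simulate_blocks(generate_design(a, 2), cfg, seed = 8)
  fits <- fit_lmm(b, "El")
  # independent oracle: with vanishing noise every cell mean equals the
  # additive model value, so the sum-to-zero dairy effect is the centered
  # equal-weight average of cell means over the other factors
  d <- fits$design$blocks
  full_means <- tapply(d$El, list(d$position, d$time, d$dairy), mean)
  # with vanishing noise, cell means equal the additive model; recover the
  # dairy effects by averaging over the other factors and centering
  dairy_eff <- apply(full_means, 3, mean) - mean(full_means)
  expect_equal(unname(fits$fits$El$level_effects$dairy),
               unname(dairy_eff), tolerance = 1e-6)
})

test_that("factor sums of squares match closed form and brute force", {
  cfg <- sim_config(n_dairies = 3, n_times = 6,
                    sigma_eps = rep(1e-10, 6), sigma_wheel = rep(0, 6))
  d <- generate_design(small_alloc(3, 6), 2)
  b <- simulate_blocks(d, cfg, seed = 9)
  fits <- fit_lmm(b, "L")
  # balanced closed form: m observations per level
  m <- nrow(b) / 6
  expect_equal(fits$fits$L$factor_ss[["position"]],
               m * sum(cfg$alpha[, "L"]^2), tolerance = 1e-6)
  # a factor simulated with zero effect has (numerically) zero SS
  cfg0 <- sim_config(n_dairies = 3, n_times = 6,
                     amplitude = list(time = 0),
                     sigma_eps = rep(1e-10, 6), sigma_wheel = rep(0, 6))
  b0 <- simulate_blocks(d, cfg0, seed = 9)
  f0 <- fit_lmm(b0, "L")
  expect_lt(f0$fits$L$factor_ss[["time"]], 1e-12)
  # brute force on noisy data: look up each row's effect and re-sum
  bn <- small_blocks(n_dairies = 3, n_sessions = 6, replicates = 2,
                     seed = 10)
  fn <- fit_lmm(standardize_blocks(bn), "Ac")
  f <- fn$fits$Ac
  rows <- fn$design$blocks
  for (tm in c("position", "dairy", "position:dairy")) {
    eff <- f$level_effects[[tm]]
    per_row <- if (is.matrix(eff)) {
      fs <- strsplit(tm, ":")[[1]]
      eff[cbind(as.character(rows[[fs[1]]]), as.character(rows[[fs[2]]]))]
    } else {
      eff[as.character(rows[[tm]])]
    }
    expect_equal(f$factor_ss[[tm]], sum(per_row^2), tolerance = 1e-10)
  }
})

test_that("the REML optimum beats random ratio probes", {
  b <- small_blocks(n_dairies = 3, n_sessions = 4, n_wheels = 2,
                    replicates = 2, seed = 11)
  std <- standardize_blocks(b)
  fits <- fit_lmm(std, "a")
  design <- fits$design
  y <- design$blocks$a
  opt <- lmmasca:::reml_objective(design, y, fits$fits$a$variance_ratio)
  probes <- withr::with_seed(12, exp(stats::runif(25, log(1e-6), log(1e6))))
  for (lam in probes) {
    expect_gte(opt + 1e-7, lmmasca:::reml_objective(design, y, lam))
  }
})

test_that("fits are invariant to input row order", {
  b <- small_blocks(n_dairies = 2, n_sessions = 3, seed = 13)
  std <- standardize_blocks(b)
  f1 <- fit_lmm(std, "L")
  shuffled <- std[withr::with_seed(1, sample(nrow(std))), ]
  f2 <- fit_lmm(shuffled, "L")
  expect_equal(f1$fits$L$beta, f2$fits$L$beta, tolerance = 1e-10)
  expect_equal(f1$fits$L$sigma2_wheel, f2$fits$L$sigma2_wheel,
               tolerance = 1e-10)
})

test_that("level effects always sum to zero over levels", {
  b <- small_blocks(n_dairies = 4, n_sessions = 6, replicates = 2,
                    seed = 14)
  fits <- fit_lmm(standardize_blocks(b))
  for (f in fits$fits) {
    for (e in f$level_effects) {
      if (is.matrix(e)) {
        expect_lt(max(abs(rowSums(e))), 1e-8)
        expect_lt(max(abs(colSums(e))), 1e-8)
      } else {
        expect_lt(abs(sum(e)), 1e-8)
      }
    }
  }
})

test_that("tidy and glance expose the fitted quantities", {
  b <- small_blocks(n_dairies = 2, n_sessions = 2, seed = 15)
  fits <- fit_lmm(standardize_blocks(b))
  td <- tidy(fits)
  expect_true(all(c("variable", "factor", "level", "effect") %in% names(td)))
  gl <- glance(fits)
  expect_equal(nrow(gl), 6)
  expect_true(all(gl$converged))
  expect_true(all(gl$sigma2_eps > 0))
  expect_true(all(gl$sigma2_wheel >= 0))
})
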