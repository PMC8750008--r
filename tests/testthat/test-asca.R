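# brute-force oracle: explained variance and contributions from the
# eigendecomposition of X'X
eigen_oracle <- function(X) {
  ei <- eigen(crossprod(X), symmetric = TRUE)
  ev <- pmax(ei$values, 0)
  contrib <- sweep(ei$vectors^2, 2, colSums(ei$vectors^2), "/") * 100
  list(explained = ev / sum(ev), vectors = ei$vectors, contrib = contrib)
}

as_effect_matrix <- function(X, factor = "dairy") {
  colnames(X) <- variable_names()[seq_len(ncol(X))]
  rownames(X) <- paste0("l", seq_len(nrow(X)))
  X <- scale(X, center = TRUE, scale = FALSE)
  attr(X, "scaled:center") <- NULL
  structure(X, factor = factor, centered = TRUE,
            class = c("effect_matrix", "matrix", "array"))
}

test_that("the dairy effect matrix is levels x variables and centered", {
  b <- small_blocks(n_dairies = 5, n_sessions = 6, replicates = 2, seed = 1)
  fits <- fit_lmm(standardize_blocks(b))
  X <- effect_matrix(fits, "dairy")
  expect_equal(dim(X), c(5L, 6L))
  expect_lt(max(abs(colSums(X))), 1e-10)
  expect_equal(colnames(X), variable_names())
  td <- tidy(X)
  expect_equal(nrow(td), 30)
})

test_that("a full-strength default design yields a 15 x 6 dairy matrix", {
  b <- simulate_blocks(generate_design(default_allocation(), 1),
                       sim_config(replicates = 1), seed = 2)
  fits <- fit_lmm(standardize_blocks(b))
  expect_equal(dim(effect_matrix(fits, "dairy")), c(15L, 6L))
  expect_equal(dim(effect_matrix(fits, "time")), c(6L, 6L))
  expect_equal(dim(effect_matrix(fits, "position")), c(6L, 6L))
})

test_that("null simulations give near-zero effect matrices", {
  b <- small_blocks(n_dairies = 5, n_sessions = 6, replicates = 4, seed = 3,
                    amplitude = list(position = 0, time = 0, dairy = 0,
                                     position_time = 0, position_dairy = 0,
                                     time_dairy = 0),
                    sigma_eps = rep(0.05, 6), sigma_wheel = rep(0, 6))
  fits <- fit_lmm(b)  # raw scale: noise stays at sigma_eps
  X <- effect_matrix(fits, "dairy")
  # effects are pure estimation noise at sigma/sqrt(n) scale
  expect_lt(max(abs(X)), 5 / sqrt(nrow(b)))
})

test_that("svd explained variance matches the eigen oracle on random toys", {
  for (s in 1:30) {
    X <- as_effect_matrix(withr::with_seed(s,
      matrix(rnorm(sample(4:12, 1) * 6), ncol = 6)))
    m <- asca(X)
    or <- eigen_oracle(X)
    k <- length(m$explained_variance)
    expect_equal(m$explained_variance, or$explained[seq_len(k)],
                 tolerance = 1e-10)
    # reconstruction from all components
    expect_lt(norm(X - m$scores %*% t(m$loadings), "F") /
                max(norm(X, "F"), 1e-12), 1e-8)
  }
})

test_that("rank-1 matrices put all variance on one component", {
  u <- c(2, -1, 0.5, 1) - 0.625
  v <- c(1, 0.3, -0.4, 0.2, 0, 0.1)
  m <- asca(as_effect_matrix(outer(u, v)))
  expect_equal(m$explained_variance[1], 1, tolerance = 1e-12)
  expect_lt(max(m$singular_values[-1]), 1e-10)
})

test_that("row rotations leave singular values unchanged", {
  X <- as_effect_matrix(withr::with_seed(4, matrix(rnorm(8 * 6), 8, 6)))
  Q <- qr.Q(qr(withr::with_seed(5, matrix(rnorm(64), 8, 8))))
  XR <- Q %*% X
  # rotation breaks column centering, so compare raw svd spectra
  expect_equal(svd(XR)$d, asca(X)$singular_values, tolerance = 1e-10)
})

test_that("the sign convention makes the largest loading positive", {
  X <- as_effect_matrix(withr::with_seed(6, matrix(rnorm(10 * 6), 10, 6)))
  m <- asca(X)
  for (c in seq_along(m$singular_values)) {
    i <- which.max(abs(m$loadings[, c]))
    expect_gt(m$loadings[i, c], 0)
  }
})

test_that("component counts follow the cumulative-variance rule", {
  make_model <- function(ev) {
    # build a matrix with prescribed explained-variance fractions
    k <- length(ev)
    U <- qr.Q(qr(withr::with_seed(7, matrix(rnorm((k + 1) * k), k + 1, k))))
    V <- qr.Q(qr(withr::with_seed(8, matrix(rnorm(6 * k), 6, k))))
    X <- U %*% diag(sqrt(ev), k) %*% t(V)
    asca(structure(X, factor = "toy", centered = TRUE,
                   class = c("effect_matrix", "matrix", "array"),
                   dimnames = list(paste0("l", 1:(k + 1)),
                                   variable_names()[1:6])))
  }
  m <- make_model(c(0.5, 0.3, 0.15, 0.05))
  expect_equal(n_components(m, 0.85), 3L)
  m1 <- make_model(1)
  expect_equal(n_components(m1, 0.85), 1L)
  mu <- make_model(rep(0.2, 5))
  expect_equal(n_components(mu, 0.85), 5L)
})

test_that("contributions are normalized and match the oracle", {
  # single component with loadings on two variables only -> 50/50
  u <- c(1, -1, 2, -2); u <- u - mean(u)
  v <- c(1, 1, 0, 0, 0, 0) / sqrt(2)
  m <- asca(as_effect_matrix(outer(u, v)))
  expect_equal(asca_contributions(m, dims = 1)$contribution,
               c(50, 50, 0, 0, 0, 0), tolerance = 1e-8)
  # generic: sums to 100, matches eigen oracle
  X <- as_effect_matrix(withr::with_seed(9, matrix(rnorm(5 * 6), 5, 6)))
  m <- asca(X)
  or <- eigen_oracle(X)
  for (dims in 1:3) {
    got <- asca_contributions(m, dims = dims)$contribution
    expect_equal(sum(got), 100, tolerance = 1e-8)
    w <- or$explained[seq_len(dims)]
    expect_equal(got,
                 drop(or$contrib[, seq_len(dims), drop = FALSE] %*% w) /
                   sum(w),
                 tolerance = 1e-8)
  }
})

test_that("biplot data exports the right points, arrows and bounds", {
  b <- simulate_blocks(generate_design(default_allocation(), 1),
                       sim_config(replicates = 1), seed = 10)
  m <- asca(fit_lmm(standardize_blocks(b)), "dairy")
  bd <- biplot_data(m, c(1, 2))
  expect_equal(sum(bd$type == "score"), 15)
  expect_equal(sum(bd$type == "loading"), 6)
  bd34 <- biplot_data(m, c(3, 4))
  expect_equal(sum(bd34$type == "score"), 15)
  # arrow scaling is invertible
  sc <- attr(bd, "arrow_scale")
  arrows <- bd[bd$type == "loading", ]
  expect_equal(arrows$x / sc, m$loadings[, 1], ignore_attr = TRUE)
  expect_error(biplot_data(m, c(1, 9)), class = "lmmasca_config_error")
})

test_that("a degenerate all-zero matrix is flagged", {
  X <- as_effect_matrix(matrix(0, 5, 6))
  m <- asca(X)
  expect_true(m$degenerate)
  expect_error(n_components(m), class = "lmmasca_value_error")
  expect_error(asca_contributions(m, 1), class = "lmmasca_value_error")
})

test_that("planted two-group dairy structure separates in score space", {
  gam <- two_group_gamma(10, gap = 3)
  b <- small_blocks(n_dairies = 10, n_sessions = 6, replicates = 2,
                    seed = 11, gamma = gam, sigma_wheel = rep(0.1, 6),
                    sigma_eps = rep(0.5, 6))
  # fit on the raw scale so the planted gap is preserved exactly
  m <- asca(fit_lmm(b), "dairy")
  pc1 <- m$scores[, 1]
  grp <- rep(c(1, 2), length.out = 10)
  gap <- abs(mean(pc1[grp == 1]) - mean(pc1[grp == 2]))
  spread <- max(stats::sd(pc1[grp == 1]), stats::sd(pc1[grp == 2]))
  expect_gt(gap, 5 * spread)
})

test_that("the score band report flags levels near the overall mean", {
  X <- as_effect_matrix(withr::with_seed(21, matrix(rnorm(8 * 6), 8, 6)))
  m <- asca(X)
  sb <- score_band_levels(m, component = 1, band = 0.55)
  expect_equal(nrow(sb), 8)
  expect_equal(sb$within_band, abs(m$scores[, 1]) <= 0.55,
               ignore_attr = TRUE)
  expect_error(score_band_levels(m, component = 99),
               class = "lmmasca_config_error")
})
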