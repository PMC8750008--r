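# shared fixtures, all generated in code

# subset of the default allocation with a fixed number of wheels per cell
small_alloc <- function(n_dairies, n_sessions, n_wheels = 1L) {
  a <- default_allocation()
  a <- a[a$dairy %in% paste0("C-", seq_len(n_dairies)) &
           a$session <= n_sessions, ]
  a$dairy <- droplevels(a$dairy)
  a$n_wheels <- as.integer(n_wheels)
  a
}

# a small simulated table: n_dairies x n_sessions, one wheel per cell
small_blocks <- function(n_dairies = 3, n_sessions = 6, n_wheels = 1,
                         replicates = 2, seed = 1, ...) {
  cfg <- sim_config(n_dairies = n_dairies,
                    n_times = length(unique(session_to_time(seq_len(n_sessions)))),
                    replicates = replicates, ...)
  simulate_blocks(generate_design(small_alloc(n_dairies, n_sessions, n_wheels),
                                  replicates), cfg, seed = seed)
}

# hand-made minimal valid table: one wheel, chosen positions/values
tiny_blocks <- function(positions = position_levels(), L = NULL,
                        replicates = 1) {
  n <- length(positions) * replicates
  tibble::tibble(
    dairy = "C-1", session = 1L, time = 1L, wheel_id = "w1",
    position = rep(positions, each = replicates),
    replicate = rep(seq_len(replicates), times = length(positions)),
    L = L %||% seq_len(n), a = seq_len(n) * 0.1, b = seq_len(n) + 2,
    Fmax = seq_len(n) * 3, Ac = seq_len(n) * 10, El = seq_len(n) + 0.5
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# a sum-to-zero dairy effect matrix with two well-separated groups
two_group_gamma <- function(n_dairies = 15, gap = 4) {
  grp <- rep(c(-1, 1), length.out = n_dairies)
  grp <- grp - mean(grp)
  m <- sapply(1:6, function(j) gap * grp * c(1, 1, 1, -1, -1, -1)[j])
  colnames(m) <- variable_names()
  m
}
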