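# average silhouette width and per-point widths for a Euclidean k-means
# partition; singleton clusters get width 0 by convention
silhouette_widths <- function(x, cluster) {
  x <- as.matrix(x)
  n <- nrow(x)
  D <- as.matrix(dist(x))
  ks <- sort(unique(cluster))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster == cluster[i]
    if (sum(own) == 1L) {
      s[i] <- 0
      next
    }
    a <- sum(D[i, own]) / (sum(own) - 1L)
    b <- min(vapply(setdiff(ks, cluster[i]),
                    function(k) mean(D[i, cluster == k]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# k-means (Hartigan-Wong, best of n_restarts by total within-cluster SS)
# with clusters relabelled canonically by first member
kmeans_best <- function(x, k, n_restarts) {
  fit <- tryCatch(
    kmeans(x, centers = k, nstart = n_restarts,
           algorithm = "Hartigan-Wong", iter.max = 100),
    error = function(e) {
      abort(paste0("k-means infeasible for k = ", k, ": ",
                   conditionMessage(e)),
            class = "lmmasca_value_error")
    }
  )
  old <- unique(fit$cluster)  # order of first appearance over rows
  fit$cluster <- match(fit$cluster, old)
  fit$centers <- fit$centers[old, , drop = FALSE]
  rownames(fit$centers) <- seq_along(old)
  fit$withinss <- fit$withinss[old]
  fit$size <- fit$size[old]
  fit
}

#' Cluster factor levels on their ASCA scores
#'
#' Runs Hartigan-Wong k-means on the score matrix of an ASCA decomposition
#' (by default the components retained at the explained-variance threshold),
#' choosing k by the average silhouette width over `k_range` (or by the
#' elbow of the within-cluster SS curve). Both diagnostic curves are always
#' computed and exported. Clusters are labelled canonically: cluster 1
#' contains the first level, etc., so output is invariant to row order up
#' to relabeling.
#'
#' @param x An `asca_model`, or a numeric matrix / data frame of scores
#'   (rows = levels).
#' @param k `"auto"` (choose from `k_range`) or a fixed integer
#'   `2 <= k <= levels - 1`.
#' @param k_range Candidate k values scanned when `k = "auto"` (default
#'   2..8).
#' @param method k-selection rule: `"silhouette"` (maximum average
#'   silhouette width, the default) or `"elbow"` (largest second difference
#'   of the total within-cluster SS).
#' @param dims Number of leading score components used (default: the
#'   model's retained components; ignored for matrix input).
#' @param n_restarts Random restarts per k (default 25; the best solution
#'   by total within-cluster SS is kept).
#' @param seed Integer seed.
#' @return An object of class `level_clusters`: chosen `k`, assignments,
#'   centroids, within-cluster SS, average silhouette width, per-level
#'   silhouette widths and the per-k `diagnostics` tibble
#'   (`k`, `tot_wss`, `avg_silhouette`). `tidy()` returns the assignments.
#' @export
cluster_levels <- function(x, k = "auto", k_range = 2:8,
                           method = c("silhouette", "elbow"),
                           dims = NULL, n_restarts = 25, seed) {
  method <- match.arg(method)
  if (inherits(x, "asca_model")) {
    dims <- dims %||% x$n_components
    scores <- x$scores[, seq_len(dims), drop = FALSE]
    factor <- x$factor
  } else {
    scores <- as.matrix(x)
    if (!is.null(dims)) scores <- scores[, seq_len(dims), drop = FALSE]
    factor <- NA_character_
  }
  n <- nrow(scores)
  if (is.null(rownames(scores))) rownames(scores) <- seq_len(n)
  feasible <- 2:(n - 1)
  if (identical(k, "auto")) {
    if (any(k_range < 2)) {
      abort("k_range must start at 2: silhouette is undefined for k = 1",
            class = "lmmasca_config_error")
    }
    k_range <- intersect(k_range, feasible)
    if (length(k_range) == 0) {
      abort("no feasible k in k_range", class = "lmmasca_config_error")
    }
  } else {
    k <- as.integer(k)
    if (!(k %in% feasible)) {
      abort(paste0("k must be between 2 and ", n - 1),
            class = "lmmasca_config_error")
    }
  }
  withr::with_seed(as.integer(seed), {
    scan_ks <- if (identical(k, "auto")) k_range else unique(c(k, k_range))
    scan_ks <- intersect(sort(scan_ks), feasible)
    fits <- lapply(setNames(scan_ks, scan_ks),
                   function(kk) kmeans_best(scores, kk, n_restarts))
    diagnostics <- tibble::tibble(
      k = scan_ks,
      tot_wss = vapply(fits, function(f) f$tot.withinss, numeric(1)),
      avg_silhouette = vapply(fits, function(f)
        mean(silhouette_widths(scores, f$cluster)), numeric(1))
    )
    k_star <- if (identical(k, "auto")) {
      if (method == "silhouette") {
        diagnostics$k[which.max(diagnostics$avg_silhouette)]
      } else {
        elbow_k(diagnostics$k, diagnostics$tot_wss)
      }
    } else k
    fit <- fits[[as.character(k_star)]]
    sil <- silhouette_widths(scores, fit$cluster)
    structure(
      list(factor = factor, k = k_star, method = method,
           assignments = tibble::tibble(level = rownames(scores),
                                        cluster = fit$cluster,
                                        silhouette = sil),
           centroids = fit$centers,
           withinss = fit$withinss, tot_withinss = fit$tot.withinss,
           avg_silhouette = mean(sil), diagnostics = diagnostics,
           seed = seed, scores = scores),
      class = "level_clusters"
    )
  })
}

# elbow suggestion: k with the largest second difference of the WSS curve;
# falls back to the first scanned k when the curve is too short
elbow_k <- function(ks, wss) {
  if (length(ks) < 3) return(ks[1])
  d2 <- diff(diff(wss))
  ks[which.max(d2) + 1L]
}

#' @export
print.level_clusters <- function(x, ...) {
  cat("<level_clusters>", if (!is.na(x$factor)) x$factor else "",
      " k =", x$k, "(", x$method, "), average silhouette =",
      format(x$avg_silhouette, digits = 4), "\n")
  print(cluster_report(x), n = Inf)
  invisible(x)
}

#' @export
#' @rdname cluster_levels
#' @param ... Unused.
tidy.level_clusters <- function(x, ...) x$assignments

#' @export
#' @rdname cluster_levels
glance.level_clusters <- function(x, ...) {
  tibble::tibble(factor = x$factor, k = x$k, method = x$method,
                 tot_withinss = x$tot_withinss,
                 avg_silhouette = x$avg_silhouette)
}

#' Labeled cluster table
#'
#' @param x A `level_clusters` object.
#' @return A tibble `level`, `cluster`, `cluster_size`, deterministically
#'   ordered (clusters labelled by first member).
#' @export
cluster_report <- function(x) {
  stopifnot(inherits(x, "level_clusters"))
  sizes <- table(x$assignments$cluster)
  dplyr::mutate(x$assignments,
                cluster_size = as.integer(sizes[as.character(.data$cluster)])) |>
    dplyr::select(dplyr::all_of(c("level", "cluster", "cluster_size")))
}

#' Scan k and report the selection diagnostics
#'
#' @inheritParams cluster_levels
#' @param scores A numeric score matrix or `asca_model`.
#' @return A list with the chosen `k` and the `diagnostics` tibble (total
#'   within-cluster SS and average silhouette per candidate k).
#' @export
choose_k <- function(scores, k_range = 2:8,
                     method = c("silhouette", "elbow"), dims = NULL,
                     n_restarts = 25, seed) {
  res <- cluster_levels(scores, k = "auto", k_range = k_range,
                        method = method, dims = dims,
                        n_restarts = n_restarts, seed = seed)
  list(k = res$k, diagnostics = res$diagnostics)
}
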