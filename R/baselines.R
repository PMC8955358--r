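#' @name baselines
#' @title Built-in reference clusterers
#' @description
#' Two deterministic in-package clusterers exercise the benchmark end-to-end
#' without third-party software: a k-means (k-means++ seeding, Lloyd
#' iterations, restart selection by within-cluster sum of squares) standing in
#' for the k-means family of cytometry tools, and a full-covariance Gaussian
#' mixture model fitted by EM standing in for model-based tools.  They are
#' stand-ins, not re-implementations of any published cytometry tool.
NULL

clustering_result <- function(labels, source, extra = list()) {
  labels <- as.integer(labels)
  structure(c(list(labels = labels, k_out = length(unique(labels)),
                   source = source), extra),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result[%s]: %d events, %d clusters\n",
              x$source, length(x$labels), x$k_out))
  invisible(x)
}

kmeanspp_init <- function(points, k) {
  n <- nrow(points)
  centers <- matrix(NA_real_, k, ncol(points))
  centers[1L, ] <- points[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(points, 2L, centers[1L, ])^2)
  if (k > 1L) for (j in 2:k) {
    pick <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2) else sample.int(n, 1L)
    centers[j, ] <- points[pick, ]
    d2 <- pmin(d2, rowSums(sweep(points, 2L, centers[j, ])^2))
  }
  centers
}

assign_nearest <- function(points, centers) {
  d2 <- outer(rowSums(points^2), rowSums(centers^2), "+") -
    2 * points %*% t(centers)
  max.col(-d2, ties.method = "first")
}

#' k-means baseline clusterer
#'
#' k-means++ seeding followed by Lloyd iterations until the largest center
#' move falls below `tol`; the best of `n_restarts` runs by within-cluster
#' sum of squares is returned.  A cluster emptied during iteration is
#' re-seeded from the point farthest from its assigned center.  Fully
#' deterministic given `seed`.
#'
#' @param points event matrix.
#' @param k number of clusters.
#' @param max_iter Lloyd iteration cap per restart.
#' @param tol convergence threshold on center movement.
#' @param n_restarts independent restarts.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a `clustering_result` with fields `centers` and `tot_withinss`.
#' @export
baseline_kmeans <- function(points, k, max_iter = 300L, tol = 1e-6,
                            n_restarts = 5L, seed = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < k)
    cb_stop("invalid_argument", "need at least k points")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      centers <- kmeanspp_init(points, k)
      lab <- assign_nearest(points, centers)
      for (it in seq_len(max_iter)) {
        newc <- centers
        for (j in seq_len(k)) {
          idx <- lab == j
          if (!any(idx)) {
            dmin <- rowSums((points - centers[lab, , drop = FALSE])^2)
            newc[j, ] <- points[which.max(dmin), ]
          } else newc[j, ] <- colMeans(points[idx, , drop = FALSE])
        }
        move <- max(abs(newc - centers))
        centers <- newc
        lab <- assign_nearest(points, centers)
        if (move < tol) break
      }
      wss <- sum((points - centers[lab, , drop = FALSE])^2)
      if (is.null(best) || wss < best$wss)
        best <- list(centers = centers, lab = lab, wss = wss)
    }
    clustering_result(best$lab, "kmeans",
                      list(centers = best$centers,
                           tot_withinss = best$wss))
  })
}

log_dmvnorm <- function(points, mean, cov) {
  R <- chol(cov)
  z <- forwardsolve(t(R), t(points) - mean)
  -0.5 * colSums(z^2) - sum(log(diag(R))) -
    0.5 * ncol(points) * log(2 * pi)
}

#' Gaussian mixture model baseline clusterer (EM)
#'
#' Fits a `k`-component full-covariance Gaussian mixture by
#' expectation-maximisation, initialised from [baseline_kmeans()].  Each
#' covariance update is regularised by `+1e-6 I`; EM stops when the
#' log-likelihood gain drops below `tol`.  The best of `n_restarts` fits by
#' final log-likelihood is returned, with hard labels by maximum posterior
#' (the benchmark statistic needs integer counts).
#'
#' @inheritParams baseline_kmeans
#' @return a `clustering_result` with fields `means`, `covariances`,
#'   `weights`, `loglik` and the per-iteration `loglik_trace`.
#' @export
baseline_gmm_em <- function(points, k, max_iter = 300L, tol = 1e-6,
                            n_restarts = 5L, seed = NULL) {
  points <- as.matrix(points)
  n <- nrow(points); d <- ncol(points)
  if (n < k * (d + 1L))
    cb_stop("invalid_argument", "need at least k*(dim+1) points")
  reg <- diag(1e-6, d)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- tryCatch({
        km <- baseline_kmeans(points, k, n_restarts = 1L)
        means <- km$centers
        covs <- lapply(seq_len(k), function(j) {
          idx <- km$labels == j
          if (sum(idx) > d) stats::cov(points[idx, , drop = FALSE]) + reg
          else stats::cov(points) + reg
        })
        w <- tabulate(km$labels, k) / n
        w[w == 0] <- 1e-10; w <- w / sum(w)
        ll_prev <- -Inf; trace <- numeric(0); resp <- NULL
        for (it in seq_len(max_iter)) {
          logd <- vapply(seq_len(k), function(j)
            log(w[j]) + log_dmvnorm(points, means[j, ], covs[[j]]),
            numeric(n))
          m <- apply(logd, 1L, max)
          lse <- m + log(rowSums(exp(logd - m)))
          ll <- sum(lse)
          trace <- c(trace, ll)
          resp <- exp(logd - lse)
          if (is.finite(ll_prev) && ll - ll_prev < tol) break
          ll_prev <- ll
          nk <- colSums(resp)
          w <- nk / n
          for (j in seq_len(k)) {
            means[j, ] <- colSums(points * resp[, j]) / nk[j]
            ctr <- sweep(points, 2L, means[j, ])
            covs[[j]] <- crossprod(ctr * resp[, j], ctr) / nk[j] + reg
          }
        }
        list(ll = ll, trace = trace, means = means, covs = covs, w = w,
             labels = max.col(resp, ties.method = "first"))
      }, error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$ll > best$ll)) best <- fit
    }
    if (is.null(best))
      cb_stop("degenerate_fit", "all EM restarts failed")
    clustering_result(best$labels, "gmm_em",
                      list(means = best$means, covariances = best$covs,
                           weights = best$w, loglik = best$ll,
                           loglik_trace = best$trace))
  })
}

#' Load an external tool's cluster assignments
#'
#' Reads an `event_index,label` CSV produced by any external clustering tool
#' for one dataset.  Every event must be covered exactly once; labels are
#' normalised to `1..k` preserving their sorted order.  The `source` of the
#' result is the file stem.
#'
#' @param path assignment CSV path.
#' @param expected_total event count of the paired dataset.
#' @return a `clustering_result`.
#' @export
load_external_assignments <- function(path, expected_total) {
  df <- utils::read.csv(path)
  if (!identical(names(df), c("event_index", "label")))
    cb_stop("format_error", "assignment file must have columns event_index,label")
  if (nrow(df) != expected_total)
    cb_stop("consistency_error", "%d rows for %d events", nrow(df),
            expected_total)
  idx <- as.integer(df$event_index)
  if (!setequal(idx, 0:(expected_total - 1L)) || anyDuplicated(idx))
    cb_stop("consistency_error", "event_index must cover 0..%d exactly once",
            expected_total - 1L)
  lab <- df$label[order(idx)]
  lab <- as.integer(factor(lab, levels = sort(unique(lab))))
  clustering_result(lab, tools::file_path_sans_ext(basename(path)))
}

#' Run a built-in baseline by name
#'
#' @param method `"kmeans"` or `"gmm_em"`.
#' @param points event matrix.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param ... passed through to the baseline.
#' @return a `clustering_result`.
#' @export
run_baseline <- function(method = c("kmeans", "gmm_em"), points, k,
                         seed = NULL, ...) {
  method <- match.arg(method)
  switch(method,
         kmeans = baseline_kmeans(points, k, seed = seed, ...),
         gmm_em = baseline_gmm_em(points, k, seed = seed, ...))
}
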