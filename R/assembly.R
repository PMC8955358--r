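#' Configuration of a synthetic dataset library
#'
#' Captures the study conditions of the benchmark: cluster count, events per
#' cluster, the separation-index grid for the normally distributed family,
#' the skew grid and orientations for the skew family, the covariance
#' eigenvalue range, replicate count, the empirical-SI acceptance band for
#' skew pairs, and the base seed from which every per-dataset seed is
#' derived.
#'
#' @param k number of clusters in the separation family, 2 or 3.
#' @param cluster_size events per cluster (default 1000).
#' @param si_targets separation-index grid (default -0.3 to +0.3 by 0.1).
#' @param replicates replicates per condition (default 9).
#' @param eig_range covariance eigenvalue bounds (default `c(1, 5)`).
#' @param alpha_grid skew-normal shape grid (default 2.5 to 10 by 2.5).
#' @param orientations skew pairings to generate.
#' @param si_band empirical-SI acceptance interval for skew pairs
#'   (default `c(-0.25, -0.15)`).
#' @param base_seed integer seed of the whole library.
#' @return object of class `assembly_spec`.
#' @export
assembly_spec <- function(k = 2L, cluster_size = 1000L,
                          si_targets = seq(-0.3, 0.3, by = 0.1),
                          replicates = 9L, eig_range = c(1, 5),
                          alpha_grid = c(2.5, 5, 7.5, 10),
                          orientations = c("tail_tail", "head_tail", "head_head"),
                          si_band = c(-0.25, -0.15), base_seed = 1L) {
  k <- as.integer(k)
  if (!k %in% c(2L, 3L)) cb_stop("invalid_argument", "k must be 2 or 3")
  if (length(si_targets) && any(si_targets <= -1 | si_targets >= 1))
    cb_stop("invalid_argument", "si_targets must lie in (-1, 1)")
  if (!(si_band[1] < si_band[2]))
    cb_stop("invalid_argument", "si_band lower bound must be below the upper")
  bad <- setdiff(orientations, c("tail_tail", "head_tail", "head_head"))
  if (length(bad))
    cb_stop("invalid_argument", "unknown orientation(s): %s",
            paste(bad, collapse = ", "))
  stopifnot(cluster_size >= 1, replicates >= 1,
            eig_range[1] > 0, eig_range[1] <= eig_range[2])
  structure(list(k = k, cluster_size = as.integer(cluster_size),
                 si_targets = as.numeric(si_targets),
                 replicates = as.integer(replicates),
                 eig_range = as.numeric(eig_range),
                 alpha_grid = as.numeric(alpha_grid),
                 orientations = orientations,
                 si_band = as.numeric(si_band),
                 base_seed = as.integer(base_seed)),
            class = "assembly_spec")
}

new_labeled_dataset <- function(events, labels, meta) {
  structure(list(events = events, labels = as.integer(labels), meta = meta),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  m <- x$meta
  cat(sprintf("labeled_dataset: %d events x %d channels, k = %d [%s]\n",
              nrow(x$events), ncol(x$events), length(unique(x$labels)),
              m$family))
  if (identical(m$family, "separation"))
    cat(sprintf("  target SI %.2f, measured SI %.3f, replicate %d\n",
                m$target_si, m$measured_si, m$replicate))
  else
    cat(sprintf("  alpha %.1f, %s, measured SI %.3f, replicate %d\n",
                m$shape_alpha, m$orientation, m$measured_si, m$replicate))
  invisible(x)
}

# place 3 centers so that every pairwise optimal-direction SI hits the target:
# alternate between (edge directions -> required center distances) and
# rebuilding the triangle from those edge lengths
solve_triangle_centers <- function(covs, si_target, tol = 0.005) {
  centers <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (iter in 1:30) {
    d <- numeric(3)
    for (e in 1:3) {
      i <- pairs[e, 1]; j <- pairs[e, 2]
      u <- unit(centers[j, ] - centers[i, ])
      d[e] <- solve_center_distance(covs[[i]], covs[[j]], u, si_target,
                                    tol = tol / 2)
    }
    # rebuild: c1 at origin, c2 on the x axis at d12, c3 from the two radii
    x3 <- (d[2]^2 - d[3]^2 + d[1]^2) / (2 * d[1])
    h2 <- d[2]^2 - x3^2
    if (h2 <= 0)
      cb_stop("generation_failure",
              "triangle with the required center distances does not exist")
    newc <- rbind(c(0, 0), c(d[1], 0), c(x3, sqrt(h2)))
    if (max(abs(newc - centers)) < 1e-6 * max(d)) { centers <- newc; break }
    centers <- newc
  }
  achieved <- vapply(1:3, function(e) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    a <- optimal_direction(centers[i, ], covs[[i]], centers[j, ], covs[[j]])
    projected_index_theoretical(centers[i, ], covs[[i]], centers[j, ],
                                covs[[j]], a)
  }, numeric(1))
  if (max(abs(achieved - si_target)) > tol * 2)
    cb_stop("generation_failure",
            "three-cluster placement missed the target index (max dev %.4f)",
            max(abs(achieved - si_target)))
  centers
}

#' Build one normally distributed separation dataset
#'
#' Draws `k` random covariances with eigenvalues in `spec$eig_range`, places
#' centers so the optimal-direction theoretical separation index between each
#' cluster and its nearest neighbour equals `si_target` (for `k = 3` all
#' three pairwise indices are solved simultaneously), samples
#' `spec$cluster_size` normal events per cluster, and records both the target
#' and the measured (empirical) index in the metadata.
#'
#' @param spec an [assembly_spec()].
#' @param si_target target separation index in (-1, 1).
#' @param replicate_index replicate number (enters the derived seed).
#' @return a `labeled_dataset`.
#' @export
build_separation_dataset <- function(spec, si_target, replicate_index = 1L) {
  stopifnot(inherits(spec, "assembly_spec"))
  if (!(si_target > -1 && si_target < 1))
    cb_stop("invalid_argument", "si_target must lie in (-1, 1)")
  seed <- derive_seed(spec$base_seed, "separation",
                      sprintf("k%d", spec$k), sprintf("si%+.3f", si_target),
                      sprintf("rep%d", replicate_index))
  with_seed(seed, {
    k <- spec$k
    covs <- lapply(seq_len(k), function(i)
      random_covariance(2L, spec$eig_range[1], spec$eig_range[2]))
    if (k == 2L) {
      u <- unit(stats::rnorm(2))
      delta <- solve_center_distance(covs[[1]], covs[[2]], u, si_target)
      centers <- rbind(c(0, 0), delta * u)
    } else {
      centers <- solve_triangle_centers(covs, si_target)
      # random orientation; rotating centers and covariances together leaves
      # every pairwise index unchanged
      th <- stats::runif(1, 0, 2 * pi)
      R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
      centers <- centers %*% t(R)
      covs <- lapply(covs, function(S) R %*% S %*% t(R))
    }
    clouds <- lapply(seq_len(k), function(i) {
      sample_normal_cluster(cluster_model(centers[i, ], covs[[i]],
                                          size = spec$cluster_size))
    })
    events <- do.call(rbind, clouds)
    labels <- rep(seq_len(k), each = spec$cluster_size)
    pairs <- utils::combn(k, 2)
    measured <- min(vapply(seq_len(ncol(pairs)), function(e) {
      separation_index_empirical(clouds[[pairs[1, e]]],
                                 clouds[[pairs[2, e]]])$value
    }, numeric(1)))
    new_labeled_dataset(events, labels,
                        list(family = "separation", k = k,
                             target_si = si_target, measured_si = measured,
                             shape_alpha = 0, orientation = "none",
                             replicate = as.integer(replicate_index),
                             seed = seed, centers = centers,
                             covariances = covs))
  })
}

orientation_sides <- function(orientation) {
  # cluster A sits at lower x, B at higher x; the "head" is the dense mode
  # side, the "tail" the long sparse side of a skewed cluster
  switch(orientation,
         tail_tail = c(A = "left",  B = "right"),
         head_head = c(A = "right", B = "left"),
         head_tail = c(A = "right", B = "right"),
         cb_stop("invalid_argument", "unknown orientation '%s'", orientation))
}

#' Build one oriented skew-pair dataset
#'
#' Generates two clusters with the same shape parameter (skew pairs never mix
#' shape values), restores their pre-skew width, orients them (cluster A at
#' lower x, B at higher x: tail-to-tail = A left-skewed / B right-skewed,
#' head-to-head the reverse, head-to-tail both skewed the same way), then
#' bisects the x shift of B until the empirical separation index of the
#' sampled events falls inside `spec$si_band`.  `shape_alpha = 0` produces
#' the unskewed control pair via the same shift procedure.
#'
#' @param spec an [assembly_spec()].
#' @param shape_alpha shape parameter, one of `spec$alpha_grid` or 0.
#' @param orientation `"tail_tail"`, `"head_tail"` or `"head_head"`.
#' @param replicate_index replicate number (enters the derived seed).
#' @return a `labeled_dataset` with `measured_si` inside the band.
#' @export
build_skew_pair <- function(spec, shape_alpha, orientation,
                            replicate_index = 1L) {
  stopifnot(inherits(spec, "assembly_spec"))
  if (!(shape_alpha %in% c(spec$alpha_grid, 0)))
    cb_stop("invalid_argument", "shape_alpha %g not on the configured grid",
            shape_alpha)
  sides <- orientation_sides(orientation)
  seed <- derive_seed(spec$base_seed, "skew", sprintf("a%g", shape_alpha),
                      orientation, sprintf("rep%d", replicate_index))
  with_seed(seed, {
    draw <- function(side) {
      S <- random_covariance(2L, spec$eig_range[1], spec$eig_range[2])
      if (shape_alpha > 0) {
        m <- cluster_model(c(0, 0), S, shape_alpha, side, spec$cluster_size)
        rescale_to_preskew_width(sample_skew_normal_cluster(m), shape_alpha)
      } else {
        sample_normal_cluster(cluster_model(c(0, 0), S,
                                            size = spec$cluster_size))
      }
    }
    A <- draw(sides[["A"]])
    B0 <- draw(sides[["B"]])
    si_at <- function(s) {
      B <- B0; B[, 1L] <- B[, 1L] + s
      separation_index_empirical(A, B)$value
    }
    lo <- 0; hi <- 1
    while (si_at(hi) < spec$si_band[2]) {
      hi <- hi * 2
      if (hi > 1e6)
        cb_stop("generation_failure", "no shift reaches the SI band")
    }
    mid_target <- mean(spec$si_band)
    s <- NA_real_; measured <- NA_real_
    for (step in seq_len(60L)) {
      s <- (lo + hi) / 2
      j <- si_at(s)
      if (j >= spec$si_band[1] && j <= spec$si_band[2]) { measured <- j; break }
      if (j < mid_target) lo <- s else hi <- s
    }
    if (is.na(measured))
      cb_stop("generation_failure",
              "bisection did not land in the SI band within 60 steps")
    B <- B0; B[, 1L] <- B[, 1L] + s
    events <- rbind(A, B)
    labels <- rep(1:2, each = spec$cluster_size)
    new_labeled_dataset(events, labels,
                        list(family = "skew", k = 2L, target_si = mid_target,
                             measured_si = measured, shape_alpha = shape_alpha,
                             orientation = orientation,
                             replicate = as.integer(replicate_index),
                             seed = seed, shift = s))
  })
}

#' Materialise a dataset library on disk
#'
#' Generates every (condition x replicate) dataset of the requested families,
#' writes each as an FCS 3.1 file plus a ground-truth label sidecar, and
#' writes a `manifest.csv` with one row per dataset (file names, family,
#' k, target and measured SI, shape, orientation, replicate, seed, status).
#' Generation failures are recorded in the manifest and do not stop the run.
#'
#' @param spec an [assembly_spec()].
#' @param out_dir output directory (created if missing).
#' @param families subset of `c("separation", "skew")`.
#' @return the manifest as a data frame, invisibly.
#' @export
generate_library <- function(spec, out_dir,
                             families = c("separation", "skew")) {
  stopifnot(inherits(spec, "assembly_spec"))
  families <- match.arg(families, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  emit <- function(ds, stem, family, target_si, shape_alpha, orientation,
                   replicate, seed, error = NA_character_) {
    row <- data.frame(file = NA_character_, labels_file = NA_character_,
                      family = family, k = if (is.null(ds)) spec$k else ds$meta$k,
                      target_si = target_si,
                      measured_si = if (is.null(ds)) NA_real_ else ds$meta$measured_si,
                      shape_alpha = shape_alpha, orientation = orientation,
                      replicate = replicate,
                      seed = if (is.null(ds)) NA_integer_ else ds$meta$seed,
                      status = if (is.null(ds)) paste0("failed: ", error) else "ok",
                      stringsAsFactors = FALSE)
    if (!is.null(ds)) {
      fcs <- paste0(stem, ".fcs"); lab <- paste0(stem, "_labels.csv")
      write_fcs(ds, file.path(out_dir, fcs))
      write_labels(ds$labels, file.path(out_dir, lab))
      row$file <- fcs; row$labels_file <- lab
    }
    rows[[length(rows) + 1L]] <<- row
  }
  if ("separation" %in% families) {
    for (si in spec$si_targets) for (r in seq_len(spec$replicates)) {
      stem <- sprintf("sep_k%d_si%s_rep%02d", spec$k,
                      gsub("-", "m", sprintf("%.1f", si)), r)
      ds <- tryCatch(build_separation_dataset(spec, si, r),
                     cytobench_error = function(e) e)
      if (inherits(ds, "condition"))
        emit(NULL, stem, "separation", si, 0, "none", r, NA,
             conditionMessage(ds))
      else emit(ds, stem, "separation", si, 0, "none", r, ds$meta$seed)
    }
  }
  if ("skew" %in% families) {
    for (al in spec$alpha_grid) for (orient in spec$orientations)
      for (r in seq_len(spec$replicates)) {
        stem <- sprintf("skew_a%s_%s_rep%02d", gsub("[.]", "p", format(al)),
                        orient, r)
        ds <- tryCatch(build_skew_pair(spec, al, orient, r),
                       cytobench_error = function(e) e)
        if (inherits(ds, "condition"))
          emit(NULL, stem, "skew", mean(spec$si_band), al, orient, r, NA,
               conditionMessage(ds))
        else emit(ds, stem, "skew", mean(spec$si_band), al, orient, r,
                  ds$meta$seed)
      }
  }
  manifest <- do.call(rbind, rows)
  if (is.null(manifest)) {
    manifest <- data.frame(file = character(0), labels_file = character(0),
                           family = character(0), k = integer(0),
                           target_si = numeric(0), measured_si = numeric(0),
                           shape_alpha = numeric(0), orientation = character(0),
                           replicate = integer(0), seed = integer(0),
                           status = character(0), stringsAsFactors = FALSE)
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
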