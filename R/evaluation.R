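#' @name evaluation
#' @title Scoring clustering outputs against ground truth
#' @description
#' The benchmark statistic is the difference to reference: with A the event
#' count of ground-truth cluster 1 and B the count of the output cluster
#' matched to it, the difference is |A - B| / total events x 100.  Before the
#' statistic can be computed, output labels must be aligned to ground truth
#' (optimal one-to-one assignment on the contingency table) and, for tools
#' that over-cluster, sub-clusters merged down to the designed number of
#' populations by majority overlap.
NULL

# Hungarian algorithm (shortest augmenting path, O(n^3)) for square
# minimum-cost assignment; returns the column assigned to each row.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)          # p[j+1]: row assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    way <- integer(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- INF; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j + 1L] <- minv[j + 1L] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

#' Align output cluster labels with ground truth
#'
#' Finds the one-to-one mapping between predicted and reference labels that
#' maximises total overlap on the contingency table (optimal assignment).
#' Ties are broken deterministically toward the smallest reference label.
#'
#' @param reference ground-truth integer labels.
#' @param predicted output labels, same length, same number of distinct
#'   values as the reference (use [merge_to_k()] first when a tool
#'   over-clusters).
#' @return named integer vector mapping each predicted label (names) to a
#'   reference label (values), with attribute `overlap` = events agreeing
#'   under the mapping.
#' @export
match_labels <- function(reference, predicted) {
  stopifnot(length(reference) == length(predicted))
  rl <- sort(unique(reference)); pl <- sort(unique(predicted))
  if (length(pl) != length(rl))
    cb_stop("k_mismatch",
            "%d predicted vs %d reference labels; apply merge_to_k first",
            length(pl), length(rl))
  tab <- table(factor(predicted, levels = pl), factor(reference, levels = rl))
  k <- length(rl)
  # minimise (max - overlap); epsilon prefers smaller reference labels on ties
  cost <- max(tab) - unclass(tab) +
    matrix(rep(seq_len(k) * 1e-9, each = k), k, k)
  assign <- solve_assignment(cost)
  map <- rl[assign]
  names(map) <- as.character(pl)
  attr(map, "overlap") <- sum(tab[cbind(seq_len(k), assign)])
  map
}

#' Merge over-clustered output down to k populations
#'
#' Automates the manual sub-cluster merging step over-clustering tools
#' require: each predicted sub-cluster is reassigned to the reference cluster
#' holding the majority of its events (many-to-one), yielding at most `k`
#' distinct labels.  The merge map is attached for audit.
#'
#' @param reference ground-truth integer labels.
#' @param predicted output labels with at least `k` distinct values.
#' @param k designed number of populations.
#' @return merged label vector (values are reference labels) with attribute
#'   `merge_map` recording predicted -> reference assignments.
#' @export
merge_to_k <- function(reference, predicted, k) {
  stopifnot(length(reference) == length(predicted))
  pl <- sort(unique(predicted))
  if (length(pl) < k)
    cb_stop("cannot_split",
            "output has %d clusters but %d are required; merging cannot split",
            length(pl), k)
  rl <- sort(unique(reference))
  tab <- table(factor(predicted, levels = pl), factor(reference, levels = rl))
  map <- rl[apply(tab, 1L, which.max)]   # which.max: first max = smallest label
  names(map) <- as.character(pl)
  merged <- map[as.character(predicted)]
  names(merged) <- NULL
  attr(merged, "merge_map") <- map
  merged
}

#' Difference to reference, in percent of total events
#'
#' `|A - B| / total x 100`, where A is the reference cluster-1 event count
#' and B the matched output cluster count.
#'
#' @param a,b event counts in `[0, total]`.
#' @param total total event count, positive.
#' @return percent difference in `[0, 100]`.
#' @export
difference_to_reference <- function(a, b, total) {
  if (!(total > 0)) cb_stop("invalid_argument", "total must be positive")
  if (a < 0 || b < 0 || a > total || b > total)
    cb_stop("invalid_argument", "counts must lie in [0, total]")
  abs(a - b) / total * 100
}

#' Score one clustering output on one dataset
#'
#' Applies [merge_to_k()] when the output has more clusters than the ground
#' truth, aligns labels with [match_labels()], and computes the difference to
#' reference for ground-truth cluster 1.  Outputs with fewer clusters than
#' designed are not an error (tools failing to return the requested k is a
#' reported outcome): reference cluster 1 is matched to the output cluster
#' with maximal overlap and the record is flagged `k_deficit`.
#'
#' @param dataset a `labeled_dataset`.
#' @param result a `clustering_result` (see [baseline_kmeans()],
#'   [load_external_assignments()]) or a bare label vector.
#' @return one-row data frame: dataset id, source, reference and predicted
#'   counts, total events, `difference_pct`, k requested/returned, flags.
#' @export
evaluate_dataset <- function(dataset, result) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (!inherits(result, "clustering_result"))
    result <- clustering_result(result, source = "labels")
  ref <- dataset$labels
  pred <- result$labels
  if (length(pred) != length(ref))
    cb_stop("consistency_error", "result has %d labels for %d events",
            length(pred), length(ref))
  k <- length(unique(ref))
  total <- length(ref)
  a <- sum(ref == 1L)
  k_out <- length(unique(pred))
  merged_flag <- FALSE
  if (k_out > k) {
    pred <- merge_to_k(ref, pred, k)
    merged_flag <- TRUE
    k_out <- length(unique(pred))
  }
  if (k_out == k) {
    map <- match_labels(ref, pred)
    pm <- names(map)[map == 1L]
    b <- sum(pred == as.integer(pm))
    deficit <- FALSE
  } else {
    # k-deficient output: match reference cluster 1 by maximal overlap
    pl <- sort(unique(pred))
    ov <- vapply(pl, function(l) sum(pred == l & ref == 1L), numeric(1))
    b <- sum(pred == pl[which.max(ov)])
    deficit <- TRUE
  }
  id <- dataset$meta$id %||%
    sprintf("%s_k%d_rep%d", dataset$meta$family, dataset$meta$k,
            dataset$meta$replicate)
  data.frame(dataset_id = id, source = result$source,
             family = dataset$meta$family,
             target_si = dataset$meta$target_si,
             measured_si = dataset$meta$measured_si,
             shape_alpha = dataset$meta$shape_alpha,
             orientation = dataset$meta$orientation,
             replicate = dataset$meta$replicate,
             reference_count = a, predicted_count = b,
             total_events = total,
             difference_pct = difference_to_reference(a, b, total),
             k_requested = k, k_returned = length(unique(result$labels)),
             merged = merged_flag, k_deficit = deficit,
             stringsAsFactors = FALSE)
}

#' Summarise evaluation records per condition
#'
#' Per group: mean, sample standard deviation (n - 1 denominator; `NA` for a
#' single record, never reported as 0) and coefficient of variation
#' CV = 100 x SD / mean (undefined when the mean is 0).
#'
#' @param records data frame of rows from [evaluate_dataset()].
#' @param by grouping column names present in `records`.
#' @return data frame with one row per condition, ordered by the grouping
#'   columns.
#' @export
summarize_records <- function(records,
                              by = c("family", "target_si", "shape_alpha",
                                     "orientation", "source")) {
  stopifnot(nrow(records) >= 1L)
  by <- intersect(by, names(records))
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  groups <- split(records, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    x <- g$difference_pct
    m <- mean(x)
    s <- if (length(x) >= 2L) stats::sd(x) else NA_real_
    cv <- if (!is.na(s) && m > 0) 100 * s / m else NA_real_
    cbind(g[1L, by, drop = FALSE],
          data.frame(n_replicates = length(x), mean_difference_pct = m,
                     sd_difference_pct = s, cv_pct = cv))
  }))
  out <- out[do.call(order, out[by]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
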