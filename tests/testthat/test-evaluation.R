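test_that("difference to reference follows the worked arithmetic", {
  expect_equal(difference_to_reference(1000, 950, 2000), 2.5)
  expect_equal(difference_to_reference(1000, 1000, 2000), 0)
  expect_equal(difference_to_reference(1000, 1200, 2000), 10)
  # symmetric, bounded
  expect_equal(difference_to_reference(950, 1000, 2000),
               difference_to_reference(1000, 950, 2000))
  expect_equal(difference_to_reference(0, 2000, 2000), 100)
  expect_error(difference_to_reference(1, 1, 0), class = "invalid_argument")
  expect_error(difference_to_reference(-1, 1, 10), class = "invalid_argument")
})

test_that("label matching recovers permutations and dominant diagonals", {
  ref <- rep(1:2, c(1000, 1000))
  pred <- ref; pred[c(1:100, 1001:1050)] <- 3L - pred[c(1:100, 1001:1050)]
  map <- match_labels(ref, pred)
  expect_identical(as.integer(map), c(1L, 2L))   # dominant diagonal
  # permuted perfect clustering: mapping recovers the permutation
  perm <- c(3L, 1L, 2L)
  ref3 <- rep(1:3, each = 50)
  pred3 <- perm[ref3]
  map3 <- match_labels(ref3, pred3)
  expect_identical(unname(map3[as.character(perm)]), 1:3)
  expect_identical(attr(map3, "overlap"), 150L)
  # symmetric 50/50 contingency: smallest-reference-label tie-break
  refT <- rep(1:2, each = 100)
  predT <- rep(rep(1:2, each = 50), 2)
  mapT <- match_labels(refT, predT)
  expect_identical(unname(mapT["1"]), 1L)
  expect_error(match_labels(ref, rep(1:4, 500)), class = "k_mismatch")
})

test_that("matching is optimal against the exhaustive permutation oracle", {
  set.seed(17)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    n <- 300L
    ref <- sample.int(k, n, replace = TRUE)
    pred <- ref
    flip <- runif(n) < runif(1, 0.1, 0.6)
    pred[flip] <- sample.int(k, sum(flip), replace = TRUE)
    pred <- sample.int(k)[pred]   # relabel randomly
    map <- match_labels(ref, pred)
    expect_identical(as.integer(attr(map, "overlap")),
                     as.integer(perm_best_overlap(ref, pred)))
  }
})

test_that("majority-overlap merging reduces pure sub-clusters to k labels", {
  set.seed(19)
  ref <- rep(1:2, each = 1000)
  # 8 sub-clusters, each >= 90% pure for one reference cluster
  sub <- integer(2000)
  for (j in 1:8) {
    host <- if (j <= 4) 1L else 2L
    idx <- which(ref == host)[(250 * ((j - 1) %% 4)) + 1:250]
    sub[idx] <- j
  }
  impure <- sample(2000, 150)
  sub[impure] <- sample.int(8, 150, replace = TRUE)
  merged <- merge_to_k(ref, sub, 2L)
  expect_lte(length(unique(merged)), 2L)
  expect_gte(mean(merged == ref), 0.9)
  mm <- attr(merged, "merge_map")
  expect_identical(sort(names(mm)), as.character(1:8))
  # identity merge when already at k
  same <- merge_to_k(ref, ref, 2L)
  expect_identical(as.integer(same), ref)
  # 50/50 sub-cluster goes to the smallest reference label
  refT <- rep(1:2, each = 50)
  predT <- c(rep(1L, 25), rep(2L, 25), rep(2L, 25), rep(1L, 25))
  mm2 <- attr(merge_to_k(refT, predT, 2L), "merge_map")
  expect_identical(unname(mm2["1"]), 1L)
  expect_error(merge_to_k(ref, rep(1L, 2000), 2L), class = "cannot_split")
})

test_that("merging never hurts the best-bijection overlap", {
  # best injective assignment of k raw sub-clusters to the k reference
  # clusters, by enumeration (other sub-clusters stay unmatched)
  best_k_subset_overlap <- function(ref, pred, k) {
    pl <- sort(unique(pred)); rl <- sort(unique(ref))
    tab <- table(factor(pred, levels = pl), factor(ref, levels = rl))
    perms <- function(v) {
      if (length(v) <= 1L) return(list(v))
      out <- list()
      for (i in seq_along(v)) for (p in perms(v[-i]))
        out[[length(out) + 1L]] <- c(v[i], p)
      out
    }
    subsets <- utils::combn(length(pl), k, simplify = FALSE)
    max(vapply(subsets, function(s)
      max(vapply(perms(seq_len(k)), function(p)
        sum(tab[cbind(s, p)]), numeric(1))), numeric(1)))
  }
  set.seed(29)
  for (i in 1:100) {
    k <- sample(2:3, 1)
    n <- 400L
    ref <- sample.int(k, n, replace = TRUE)
    ksub <- k + sample(1:4, 1)
    host <- rep(seq_len(k), length.out = ksub)
    pred <- vapply(seq_len(n), function(t) {
      if (runif(1) < 0.7) {
        idx <- which(host == ref[t])
        idx[sample.int(length(idx), 1L)]
      } else sample.int(ksub, 1L)
    }, integer(1))
    merged <- merge_to_k(ref, pred, k)
    if (length(unique(merged)) == k) {
      best_merged <- attr(match_labels(ref, merged), "overlap")
      expect_gte(best_merged, best_k_subset_overlap(ref, pred, k))
    }
  }
})

test_that("dataset evaluation composes merging, matching and the statistic", {
  sp <- assembly_spec(cluster_size = 500L, base_seed = 83L)
  ds <- build_separation_dataset(sp, 0.3, 1)
  # perfect clustering (relabelled)
  perfect <- evaluate_dataset(ds, 3L - ds$labels)
  expect_equal(perfect$difference_pct, 0)
  expect_false(perfect$k_deficit)
  # 30 events swapped out of cluster 1 -> |500 - 530| / 1000 * 100 = 3
  pred <- ds$labels
  pred[which(ds$labels == 2L)[1:30]] <- 1L
  expect_equal(evaluate_dataset(ds, pred)$difference_pct, 3)
  # single-cluster output for k = 2: matched count is everything -> 50%
  rec <- evaluate_dataset(ds, rep(1L, 1000L))
  expect_equal(rec$difference_pct, 50)
  expect_true(rec$k_deficit)
  # over-clustered output is merged before matching
  over <- ds$labels * 2L
  over[seq(1, 1000, by = 2)] <- over[seq(1, 1000, by = 2)] - 1L
  rec2 <- evaluate_dataset(ds, over)
  expect_equal(rec2$difference_pct, 0)
  expect_true(rec2$merged)
  expect_error(evaluate_dataset(ds, rep(1L, 5L)), class = "consistency_error")
})

test_that("per-condition summaries use the sample SD and flag n = 1", {
  rec <- function(d, si, rep) data.frame(
    dataset_id = sprintf("d%d", rep), source = "toy", family = "separation",
    target_si = si, measured_si = si, shape_alpha = 0, orientation = "none",
    replicate = rep, reference_count = 0, predicted_count = 0,
    total_events = 100, difference_pct = d, k_requested = 2, k_returned = 2,
    merged = FALSE, k_deficit = FALSE)
  two <- rbind(rec(2, 0.1, 1), rec(4, 0.1, 2))
  s <- summarize_records(two)
  expect_equal(s$mean_difference_pct, 3)
  expect_equal(s$sd_difference_pct, sqrt(2), tolerance = 1e-9)
  expect_equal(s$cv_pct, 100 * sqrt(2) / 3, tolerance = 1e-6)
  # single record: SD reported as missing, never 0
  s1 <- summarize_records(rec(5, 0.2, 1))
  expect_true(is.na(s1$sd_difference_pct))
  expect_true(is.na(s1$cv_pct))
  # nine identical records: SD and CV exactly 0
  nine <- do.call(rbind, lapply(1:9, function(r) rec(3, 0, r)))
  s9 <- summarize_records(nine)
  expect_equal(s9$n_replicates, 9L)
  expect_equal(s9$sd_difference_pct, 0)
  expect_equal(s9$cv_pct, 0)
})
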