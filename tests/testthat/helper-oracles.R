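# Independent oracles and shared fixtures for the test suite.
# These deliberately avoid the package's own code paths.

# closed-form separation index over a dense angle grid (2-D), vectorised;
# independent of optimal_direction / projected_index_theoretical
oracle_grid_max_j <- function(mean1, cov1, mean2, cov2, n_angles = 3600L,
                              coverage_alpha = 0.05) {
  th <- seq(0, pi, length.out = n_angles)
  ax <- cos(th); ay <- sin(th)
  d <- mean2 - mean1
  delta <- abs(ax * d[1] + ay * d[2])
  s1 <- sqrt(cov1[1, 1] * ax^2 + 2 * cov1[1, 2] * ax * ay + cov1[2, 2] * ay^2)
  s2 <- sqrt(cov2[1, 1] * ax^2 + 2 * cov2[1, 2] * ax * ay + cov2[2, 2] * ay^2)
  z <- qnorm(1 - coverage_alpha / 2)
  max((delta - z * (s1 + s2)) / (delta + z * (s1 + s2)))
}

# random SPD matrix built independently of random_covariance
rand_spd <- function(dim = 2L, scale = 2) {
  A <- matrix(rnorm(dim * dim, sd = scale), dim, dim)
  crossprod(A) + diag(0.5, dim)
}

# exhaustive-permutation oracle for optimal one-to-one label matching
perm_best_overlap <- function(reference, predicted) {
  rl <- sort(unique(reference)); pl <- sort(unique(predicted))
  stopifnot(length(rl) == length(pl), length(rl) <= 4L)
  tab <- table(factor(predicted, levels = pl), factor(reference, levels = rl))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  max(vapply(perms(seq_along(rl)),
             function(p) sum(tab[cbind(seq_along(rl), p)]), numeric(1)))
}

# byte-level structural verifier for FCS 3.1 files, written directly from the
# published layout with its own offset parsing and float decoding (separate
# code path from read_fcs)
fcs_struct_check <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  stopifnot(rawToChar(bytes[1:6]) == "FCS3.1",
            rawToChar(bytes[7:10]) == "    ")
  off <- vapply(0:5, function(i)
    as.integer(trimws(rawToChar(bytes[(11 + 8 * i):(18 + 8 * i)]))),
    integer(1))
  txt <- rawToChar(bytes[(off[1] + 1):(off[2] + 1)])
  delim <- substr(txt, 1, 1)
  stopifnot(delim == "/")
  fields <- strsplit(substr(txt, 2, nchar(txt) - 1), delim, fixed = TRUE)[[1]]
  kw <- fields[seq(2, length(fields), 2)]
  names(kw) <- fields[seq(1, length(fields), 2)]
  n <- as.integer(kw[["$TOT"]]); p <- as.integer(kw[["$PAR"]])
  db <- as.integer(kw[["$BEGINDATA"]]); de <- as.integer(kw[["$ENDDATA"]])
  stopifnot(db == off[3], de == off[4], de - db + 1 == 4 * n * p,
            kw[["$DATATYPE"]] == "F", kw[["$MODE"]] == "L",
            kw[["$BYTEORD"]] == "1,2,3,4", kw[["$NEXTDATA"]] == "0")
  vals <- readBin(bytes[(db + 1):(de + 1)], "double", n = n * p, size = 4,
                  endian = "little")
  list(n = n, p = p, data = matrix(vals, n, p, byrow = TRUE), keywords = kw)
}

# cached per-(method, SI) difference-to-reference vectors over 9 replicates
# at the study conditions (1000 events/cluster, eigenvalues 1-5)
bench_cache <- new.env(parent = emptyenv())

eval_separation_grid <- function(method, si, replicates = 9L,
                                 base_seed = 20260101L) {
  key <- sprintf("%s_%+0.1f_%d_%d", method, si, replicates, base_seed)
  if (!is.null(bench_cache[[key]])) return(bench_cache[[key]])
  sp <- assembly_spec(base_seed = base_seed)
  diffs <- vapply(seq_len(replicates), function(r) {
    ds <- build_separation_dataset(sp, si, r)
    res <- run_baseline(method, ds$events, 2L,
                        seed = ds$meta$seed + 1000L)
    evaluate_dataset(ds, res)$difference_pct
  }, numeric(1))
  bench_cache[[key]] <- diffs
  diffs
}
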