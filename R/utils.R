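# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

cb_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "cytobench_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

check_spd <- function(m, name = "covariance") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    cb_stop("invalid_model", "%s must be a square matrix", name)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    cb_stop("invalid_model", "%s must be symmetric", name)
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    cb_stop("invalid_model", "%s must be positive definite (min eigenvalue %g)",
            name, min(ev))
  invisible(TRUE)
}

unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) cb_stop("invalid_argument", "direction must be nonzero")
  v / nv
}

# Deterministic 32-bit seed from a base seed plus a string tag, so any single
# dataset in a library is reproducible in isolation.
derive_seed <- function(base_seed, ...) {
  tag <- paste(..., sep = "|")
  h <- as.double(base_seed %% 2147483647L)
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% 2147483647
  as.integer(h) + 1L
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
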