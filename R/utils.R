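# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed tables in the clinical
#' literature use half-away-from-zero, so report formatting goes through this.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Column-wise Pearson correlation of a matrix with a vector.
# Columns with (numerically) zero variance score 0 by convention.
col_cor <- function(X, y) {
  n <- length(y)
  stopifnot(nrow(X) == n)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  cm <- .colMeans(X, n, ncol(X))
  num <- as.vector(crossprod(X, yc))
  ss <- .colSums(X * X, n, ncol(X)) - n * cm^2
  # a column of identical values leaves only rounding residue in ss
  const <- ss <= n * pmax(cm^2, .Machine$double.eps) * 1e-9
  r <- numeric(ncol(X))
  ok <- !const & sy > 0
  r[ok] <- num[ok] / (sqrt(ss[ok]) * sy)
  pmin(1, pmax(-1, r))
}

# Pearson correlation of one summed feature vector with labels (fast path).
vec_cor <- function(s, yc, sy) {
  n <- length(s)
  ms <- sum(s) / n
  ss <- sum(s * s) - n * ms^2
  if (ss <= n * pmax(ms^2, .Machine$double.eps) * 1e-9) return(0)
  sum(yc * s) / (sqrt(ss) * sy)
}

# 26-neighbourhood linear-index offsets for a given array shape (with the
# coordinate deltas kept so callers can reject out-of-bounds wraps).
neighbour_offsets <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d[rowSums(d != 0) > 0, , drop = FALSE]
}

# Neighbours of linear indices `idx` inside an array of dimension `dm`.
neighbours26 <- function(idx, dm) {
  co <- arrayInd(idx, dm)
  off <- neighbour_offsets()
  out <- integer(0)
  for (k in seq_len(nrow(off))) {
    nb <- co + matrix(off[k, ], nrow(co), 3, byrow = TRUE)
    keep <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
      nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (any(keep)) {
      nbk <- nb[keep, , drop = FALSE]
      out <- c(out, nbk[, 1] + (nbk[, 2] - 1L) * dm[1] +
                 (nbk[, 3] - 1L) * dm[1] * dm[2])
    }
  }
  unique(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
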