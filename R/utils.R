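# internal helpers shared across modules

# evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls never perturb user randomness
with_seed <- function(seed, expr) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("seed is required: all randomness must be seeded")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# column-wise z-score with a zero-variance guard: constant columns map to 0
zscore_cols <- function(x, warn = FALSE) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  bad <- !is.finite(sdv) | sdv == 0
  if (any(bad) && warn)
    warning(sum(bad), " zero-variance column(s) z-scored to 0")
  sdv[bad] <- 1
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
  z[, bad] <- 0
  z
}

# Pearson correlation between matching columns of two matrices
colwise_cor <- function(a, b) {
  a <- sweep(a, 2L, colMeans(a), "-")
  b <- sweep(b, 2L, colMeans(b), "-")
  num <- colSums(a * b)
  den <- sqrt(colSums(a^2) * colSums(b^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# lower-triangle (excluding diagonal) of a square matrix as a vector
lower_tri_vec <- function(m) m[lower.tri(m)]

#' Spearman-Brown corrected split-half correlation
#'
#' Projects the Pearson correlation between two half-splits to the
#' reliability of the full-length measurement: `SB = 2 * rho / (1 + rho)`.
#' Fixes 0 and 1, is strictly increasing on (-1, 1], and passes negative
#' correlations through unmodified.
#'
#' @param rho Pearson correlation(s) between two split-half averages.
#' @return Corrected reliability, same length as `rho`.
#' @export
#' @examples
#' spearman_brown(1/3) # 0.5
spearman_brown <- function(rho) 2 * rho / (1 + rho)
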