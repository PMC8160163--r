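## Nonparametric association statistics backing the network edges and the
## scenario comparisons: tie-corrected Spearman correlation with exact
## permutation, t-approximation or Monte-Carlo p-values, and the Friedman
## test with Bonferroni-corrected Wilcoxon signed-rank post-hoc.

#' Spearman rank correlation coefficient
#'
#' Tie-safe form: average ranks are assigned to ties and rho is the
#' product-moment correlation of the two rank vectors (not the 6*sum(d^2)
#' shortcut, which is biased under ties). Missing values are removed
#' pairwise.
#'
#' @param x,y Numeric vectors of equal length; at least 3 complete pairs.
#' @return rho in [-1, 1], or \code{NA} if either vector is constant after
#'   pairwise deletion.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Two-sided p-value for a Spearman correlation
#'
#' Three methods:
#' \describe{
#'   \item{t_approx}{Student-t approximation, \code{t = rho * sqrt((n-2) /
#'     (1-rho^2))} on \code{n - 2} degrees of freedom; \code{|rho| = 1}
#'     yields p = 0 by continuity.}
#'   \item{exact_perm}{full enumeration of all \code{n!} permutations of one
#'     rank vector (permitted for \code{n <= 8}); exact and valid under
#'     ties, conditional on the observed ranks.}
#'   \item{mc_perm}{Monte-Carlo permutation with \code{B} replicates and the
#'     add-one estimator \code{(1 + #{|rho*| >= |rho|}) / (B + 1)}.}
#' }
#'
#' @param x,y Numeric vectors (needed by the permutation methods; the
#'   t-approximation uses them only for rho and n).
#' @param method One of \code{"auto"}, \code{"t_approx"}, \code{"exact_perm"},
#'   \code{"mc_perm"}. \code{"auto"} picks exact enumeration for n <= 8 and
#'   the t approximation otherwise.
#' @param B Monte-Carlo replicates for \code{mc_perm}.
#' @param mc_seed Seed for \code{mc_perm} draws (local RNG scope).
#' @return A list with \code{rho}, \code{p_value}, \code{n}, \code{method}.
#' @export
spearman_test <- function(x, y, method = c("auto", "t_approx", "exact_perm",
                                           "mc_perm"),
                          B = 10000L, mc_seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs for a p-value")
  rho <- tryCatch(spearman_rho(x, y), error = function(e) NA_real_)
  if (method == "auto") method <- if (n <= 8) "exact_perm" else "t_approx"
  if (is.na(rho)) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, method = method))
  }
  rx <- rank(x); ry <- rank(y)
  p <- switch(method,
    t_approx = {
      if (abs(rho) >= 1) 0 else {
        tstat <- rho * sqrt((n - 2) / (1 - rho^2))
        2 * stats::pt(-abs(tstat), df = n - 2)
      }
    },
    exact_perm = {
      if (n > 8) stop("exact enumeration limited to n <= 8 (n! permutations)")
      perm <- all_permutations(n)
      rho_perm <- perm_rho(rx, ry, perm)
      mean(abs(rho_perm) >= abs(rho) - 1e-12)
    },
    mc_perm = {
      stats_local <- withr_seed(mc_seed, {
        replicate(B, {
          ryp <- ry[sample.int(n)]
          a <- rx - mean(rx); b <- ryp - mean(ryp)
          sum(a * b) / sqrt(sum(a^2) * sum(b^2))
        })
      })
      (1 + sum(abs(stats_local) >= abs(rho) - 1e-12)) / (B + 1)
    })
  list(rho = rho, p_value = p, n = n, method = method)
}

#' @rdname spearman_test
#' @export
spearman_pvalue <- function(x, y, method = "auto", B = 10000L, mc_seed = 1L) {
  spearman_test(x, y, method, B = B, mc_seed = mc_seed)$p_value
}

## All n! permutations of 1..n as a matrix (rows = permutations).
## Memory: n = 8 gives 40320 x 8 integers (~1.3 MB).
all_permutations <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1, n <= 9)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  f <- nrow(sub)
  out <- matrix(0L, nrow = n * f, ncol = n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * f + 1L):(i * f)
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow = f)
  }
  out
}

## rho of rx against every row-permutation of ry, vectorised.
perm_rho <- function(rx, ry, perm) {
  a <- rx - mean(rx)
  b <- ry - mean(ry)
  num <- matrix(b[perm], nrow = nrow(perm)) %*% a
  as.numeric(num) / sqrt(sum(a^2) * sum(b^2))
}

## Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Friedman test with Bonferroni-corrected pairwise post-hoc
#'
#' Rank-based repeated-measures test across k treatments observed on n
#' blocks (here: athletes across the three pre-activation scenarios).
#' Values are ranked within each block with average ranks for ties; the
#' tie-corrected statistic
#' \deqn{Q = (k-1) \sum_j (R_j - n(k+1)/2)^2 / (A - C)}
#' with \eqn{A = \sum r_{ij}^2} and \eqn{C = n k (k+1)^2 / 4} reduces to the
#' classical \eqn{12/(nk(k+1)) \sum R_j^2 - 3n(k+1)} without ties, and is
#' referred to a chi-square distribution on k - 1 degrees of freedom. When
#' every block is entirely tied (A = C) the statistic is 0. The post-hoc is
#' a Wilcoxon signed-rank test per treatment pair with Bonferroni adjustment
#' over the m = k(k-1)/2 pairs.
#'
#' @param values Numeric matrix or data frame, n blocks x k treatments, no
#'   missing cells.
#' @param posthoc Run the pairwise Wilcoxon post-hoc (default TRUE).
#' @return A list with \code{statistic}, \code{df}, \code{p_value}, and (if
#'   requested) \code{pairwise}: a data frame of treatment pairs with raw
#'   and Bonferroni-adjusted Wilcoxon p-values.
#' @export
friedman_rank_test <- function(values, posthoc = TRUE) {
  m <- as.matrix(values)
  if (anyNA(m)) stop("missing cells are not allowed")
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 2, k >= 2)
  r <- t(apply(m, 1L, rank))
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  stat <- if (A - C <= .Machine$double.eps * A) 0 else
    (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A - C)
  df <- k - 1
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  out <- list(statistic = stat, df = df, p_value = p)
  if (posthoc) {
    pairs <- utils::combn(k, 2)
    mtests <- ncol(pairs)
    labs <- colnames(m)
    if (is.null(labs)) labs <- paste0("T", seq_len(k))
    praw <- apply(pairs, 2, function(ij) {
      d <- m[, ij[1]] - m[, ij[2]]
      if (all(d == 0)) return(1)
      suppressWarnings(
        stats::wilcox.test(m[, ij[1]], m[, ij[2]], paired = TRUE)$p.value)
    })
    out$pairwise <- data.frame(
      pair = paste(labs[pairs[1, ]], labs[pairs[2, ]], sep = " vs "),
      p_raw = praw,
      p_bonferroni = bonferroni_adjust(praw, mtests),
      stringsAsFactors = FALSE)
  }
  out
}

#' Bonferroni adjustment
#'
#' \code{min(1, m * p)} for each p-value.
#'
#' @param p_values Numeric vector of raw p-values.
#' @param m Number of comparisons (default: \code{length(p_values)}).
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  stopifnot(m >= 1)
  pmin(1, m * p_values)
}
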