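# Two-group statistics kernel used throughout the screen: Wilcoxon rank-sum
# with an exact small-sample path, Welch's t with explicit degenerate-input
# rules, Benjamini-Hochberg adjustment and the Pearson correlation test.

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Computes the Mann-Whitney U statistic for \code{x} relative to \code{y}.
#' The p-value is exact (null distribution of U over all labelings) when the
#' smaller group has at most 10 observations and the pooled sample is free of
#' ties; otherwise a normal approximation with midranks, tie-corrected
#' variance and continuity correction is used.
#'
#' @param x,y numeric vectors (missing values dropped); both non-empty.
#' @param alternative \code{"two_sided"} (default), \code{"greater"}
#'   (\code{x} stochastically larger) or \code{"less"}.
#' @param exact_max largest size of the smaller group for which the exact
#'   null distribution is used (default 10).
#' @return list with \code{statistic} (U), \code{p_value}, \code{method}
#'   (\code{"exact"} or \code{"normal"}), \code{n_x}, \code{n_y}.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two_sided", "greater", "less"),
                              exact_max = 10L) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L)
    stop("both groups must be non-empty", call. = FALSE)

  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  exact <- !ties && min(nx, ny) <= exact_max

  if (exact) {
    p_le <- stats::pwilcox(U, nx, ny)               # P(U <= u)
    p_ge <- 1 - stats::pwilcox(U - 1, nx, ny)       # P(U >= u)
    p <- switch(alternative,
                two_sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    n <- nx + ny
    tie_tab <- table(r)
    sigma2 <- (nx * ny / 12) *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      # all pooled values identical: perfectly symmetric null
      return(list(statistic = U, p_value = 1, method = "normal",
                  n_x = nx, n_y = ny))
    }
    z <- U - mu
    cc <- switch(alternative,
                 two_sided = sign(z) * 0.5,
                 greater = 0.5,
                 less = -0.5)
    z <- (z - cc) / sqrt(sigma2)
    p <- switch(alternative,
                two_sided = min(1, 2 * min(stats::pnorm(z),
                                           stats::pnorm(z, lower.tail = FALSE))),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    method <- "normal"
  }
  list(statistic = unname(U), p_value = p, method = method,
       n_x = nx, n_y = ny)
}

#' Welch's unequal-variance t test
#'
#' Two-sided t test with the Welch-Satterthwaite degrees of freedom. When
#' both groups have zero variance: equal means give \eqn{t = 0, p = 1};
#' unequal means are a degenerate input and raise an error.
#'
#' @param x,y numeric vectors with at least 2 non-missing values each.
#' @return list with \code{statistic} (t), \code{df}, \code{p_value}.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    stop("both groups need at least 2 observations", call. = FALSE)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, df = nx + ny - 2, p_value = 1))
    stop("degenerate input: both variances zero with unequal means",
         call. = FALSE)
  }
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(statistic = t_stat, df = df, p_value = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin validating wrapper around
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p numeric vector of p-values, all in (0, 1].
#' @return vector of q-values, same order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation test
#'
#' Sample Pearson coefficient with p-value from
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom.
#' \code{sidedness = "one_sided"} halves the two-sided p, testing in the
#' direction of the observed correlation (some published correlations are
#' quoted under this convention).
#'
#' @param x,y numeric vectors of equal length; pairs with missing values are
#'   dropped; at least 3 complete pairs and nonzero variance required.
#' @param sidedness \code{"two_sided"} (default) or \code{"one_sided"}.
#' @return a \code{correlation_result} list with \code{r}, \code{p_value},
#'   \code{n}, \code{sidedness}.
#' @export
pearson_corr_test <- function(x, y, sidedness = c("two_sided", "one_sided")) {
  sidedness <- match.arg(sidedness)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  p <- unname(ct$p.value)
  if (sidedness == "one_sided") p <- p / 2
  structure(list(r = unname(ct$estimate), p_value = p, n = n,
                 sidedness = sidedness),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson R = %.4f, P = %.4g (%s), N = %d\n",
              x$r, x$p_value, sub("_", "-", x$sidedness), x$n))
  invisible(x)
}
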