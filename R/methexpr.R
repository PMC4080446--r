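#' Pair gene-level methylation and expression
#'
#' Intersects the two gene universes and computes, for each shared gene,
#' its mean methylation and mean expression over the chosen group's
#' samples.
#'
#' @param meth methylation \code{\link{gene_profile_matrix}}.
#' @param expr expression \code{\link{gene_profile_matrix}}.
#' @param group which samples to average (\code{"case"}, \code{"control"}
#'   or \code{"all"}).
#' @return data frame with columns \code{gene}, \code{x} (methylation
#'   mean), \code{y} (expression mean).
#' @export
gene_level_pairs <- function(meth, expr, group = c("case", "control", "all")) {
  group <- match.arg(group)
  shared <- intersect(rownames(meth), rownames(expr))
  pick <- function(m) {
    g <- sample_groups(m)
    cols <- if (group == "all") rep(TRUE, length(g)) else g == group
    rowMeans(unclass(m)[shared, cols, drop = FALSE])
  }
  data.frame(gene = shared, x = pick(meth), y = pick(expr),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks are used for ties; the p-value uses the t approximation
#' \code{t = rho sqrt((n - 2) / (1 - rho^2))} with \code{n - 2} degrees of
#' freedom (two-sided).
#'
#' @param pairs data frame with columns \code{x} and \code{y}.
#' @return list with \code{rho} and \code{p}.
#' @export
spearman <- function(pairs) {
  x <- rank(pairs$x); y <- rank(pairs$y)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero rank variance: correlation undefined (ties-only input)")
  rho <- stats::cor(x, y)
  tstat <- abs(rho) * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * stats::pt(tstat, n - 2, lower.tail = FALSE))
}

#' Fit the methylation-expression regression line
#'
#' Ordinary least squares of expression on methylation, with the
#' \code{level} prediction interval at any methylation value x0:
#' \code{yhat(x0) +/- t * s * sqrt(1 + 1/n + (x0 - xbar)^2 / Sxx)}.
#' The Spearman correlation of the pairs is carried along.
#'
#' @param pairs data frame with columns \code{x} and \code{y} (>= 3 rows).
#' @param level prediction-interval level.
#' @return object of class \code{"methexpr_fit"}: list with \code{slope},
#'   \code{intercept}, \code{sigma}, \code{n}, \code{level},
#'   \code{spearman_rho}, \code{spearman_p}, \code{halfwidth} (function of
#'   x0) and the underlying \code{lm} fit.
#' @export
fit_line <- function(pairs, level = 0.95) {
  if (nrow(pairs) < 3) stop("need at least 3 pairs")
  fit <- stats::lm(y ~ x, data = pairs)
  s <- summary(fit)$sigma
  n <- nrow(pairs)
  xbar <- mean(pairs$x)
  sxx <- sum((pairs$x - xbar)^2)
  tq <- stats::qt(1 - (1 - level) / 2, n - 2)
  sp <- spearman(pairs)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    sigma = s, n = n, level = level,
    spearman_rho = sp$rho, spearman_p = sp$p,
    halfwidth = function(x0) tq * s * sqrt(1 + 1 / n + (x0 - xbar)^2 / sxx),
    lm = fit), class = "methexpr_fit")
}

#' @export
print.methexpr_fit <- function(x, ...) {
  cat(sprintf("methexpr_fit: y = %.4gx + %.4g (n = %d, sigma = %.4g)\n",
              x$slope, x$intercept, x$n, x$sigma))
  cat(sprintf("  Spearman rho = %.4f (p = %.3g); %g%% prediction interval\n",
              x$spearman_rho, x$spearman_p, 100 * x$level))
  invisible(x)
}

#' Flag genes inside the prediction interval
#'
#' A gene is flagged when its expression lies inside the fitted line's
#' prediction band at its methylation value — the regime where expression
#' is consistent with control by methylation.
#'
#' @param fit a \code{\link{fit_line}} result.
#' @param pairs data frame with columns \code{gene}, \code{x}, \code{y}.
#' @return list with \code{flags} (data frame gene, x, y, lower, upper,
#'   within) and \code{n_within}.
#' @export
flag_within_interval <- function(fit, pairs) {
  yhat <- fit$intercept + fit$slope * pairs$x
  hw <- fit$halfwidth(pairs$x)
  lower <- yhat - hw
  upper <- yhat + hw
  # floating-point guard so an exact fit (zero-width band) flags its own
  # points as inside
  eps <- sqrt(.Machine$double.eps) * pmax(1, abs(yhat))
  within <- pairs$y >= lower - eps & pairs$y <= upper + eps
  list(flags = data.frame(gene = pairs$gene, x = pairs$x, y = pairs$y,
                          lower = lower, upper = upper, within = within,
                          stringsAsFactors = FALSE),
       n_within = sum(within))
}
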