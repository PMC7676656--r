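new_histology_distribution <- function(x, fx, histology, bandwidth, n_source,
                                       flagged = FALSE) {
  fx[fx < 0] <- 0
  total <- trapz_integral(x, fx)
  if (total <= 0) stop("density has no mass on the grid", call. = FALSE)
  fx <- fx / total
  cdf <- cum_trapz(x, fx)
  cdf <- cdf / cdf[length(cdf)]
  structure(
    list(histology = histology, x = x, fx = fx, cdf = cdf,
         bandwidth = bandwidth, n_source = n_source, flagged = flagged),
    class = "histology_distribution")
}

trapz_integral <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

cum_trapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

#' @export
print.histology_distribution <- function(x, ...) {
  cat("<histology_distribution> ", x$histology,
      "  n_source=", x$n_source,
      "  bandwidth=", signif(x$bandwidth, 4),
      "  grid=[0, ", signif(max(x$x), 4), "] x ", length(x$x), " points",
      if (isTRUE(x$flagged)) "  [minimal-bandwidth fallback]" else "",
      "\n", sep = "")
  invisible(x)
}

#' Fit the true-TMB distribution of one histology
#'
#' Kernel density estimate of the whole-exome TMB distribution for one
#' histology, with Gaussian kernels and reflection at the origin so that all
#' probability mass lies on nonnegative TMB. The density is tabulated on a
#' uniform grid spanning `[0, max(T) * 1.5 + 10 * bandwidth]` and normalized
#' to integrate to 1 on that grid.
#'
#' @param cohort a [tmb_cohort], or a numeric vector of TMB values.
#' @param histology histology code to select from the cohort (ignored for a
#'   numeric vector input).
#' @param bandwidth_rule `"default"` (Silverman's rule-of-thumb,
#'   `stats::bw.nrd0`) or `"fixed"` with `bandwidth` supplied.
#' @param bandwidth fixed kernel bandwidth in mutations/Mb when
#'   `bandwidth_rule = "fixed"`.
#' @param grid_size number of grid points (>= 2048).
#' @return A `histology_distribution`: density values `fx` and CDF on grid
#'   `x`, plus the bandwidth and source sample count. If all samples are
#'   identical and the default rule degenerates, a minimal bandwidth of 0.5
#'   mutations/Mb is used and the result is flagged.
#' @export
fit_histology_distribution <- function(cohort, histology = NULL,
                                       bandwidth_rule = c("default", "fixed"),
                                       bandwidth = NULL, grid_size = 4096) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  stopifnot(grid_size >= 2048)
  if (is.numeric(cohort)) {
    vals <- cohort
    if (is.null(histology)) histology <- "unspecified"
  } else {
    if (is.null(histology)) stop("histology must be given for a cohort input",
                                 call. = FALSE)
    vals <- cohort$tmb_wes[cohort$histology == histology]
  }
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2) {
    stop("insufficient data: need >= 2 finite TMB values for ", histology,
         call. = FALSE)
  }
  if (any(vals < 0)) stop("negative TMB values in input", call. = FALSE)
  flagged <- FALSE
  if (bandwidth_rule == "fixed") {
    if (is.null(bandwidth) || bandwidth <= 0) {
      stop("fixed bandwidth_rule requires a positive bandwidth", call. = FALSE)
    }
    bw <- bandwidth
  } else {
    if (stats::sd(vals) == 0) {        # degenerate sample: all values identical
      bw <- 0.5
      flagged <- TRUE
    } else {
      bw <- stats::bw.nrd0(vals)
    }
  }
  xmax <- max(vals) * 1.5 + 10 * bw
  # KDE on the data augmented with its mirror image, folded onto T >= 0:
  # evaluating the augmented-sample KDE on [0, xmax] and doubling is exactly
  # the reflection estimator (1/n) sum_i [K(t - x_i) + K(t + x_i)].
  g <- stats::density(c(vals, -vals), bw = bw, from = 0, to = xmax,
                      n = grid_size)
  new_histology_distribution(g$x, 2 * g$y, histology, bw, length(vals),
                             flagged)
}

#' Build a distribution from tabulated density values
#'
#' Wraps an analytic or externally computed density, given on a grid of
#' nonnegative TMB values, as a `histology_distribution`. The density is
#' renormalized to integrate to 1 on the grid.
#'
#' @param x increasing grid of TMB values starting at 0 (mutations/Mb).
#' @param fx nonnegative density values on `x`.
#' @param histology label for the distribution.
#' @return A `histology_distribution`.
#' @export
grid_distribution <- function(x, fx, histology = "analytic") {
  stopifnot(length(x) == length(fx), !is.unsorted(x), min(x) >= 0)
  new_histology_distribution(x, fx, histology, bandwidth = NA_real_,
                             n_source = NA_integer_)
}

#' Density, CDF and quantiles of a fitted TMB distribution
#'
#' `dist_density` and `dist_cdf` interpolate the tabulated density/CDF;
#' both are 0 below the support. `dist_quantile` inverts the CDF by
#' monotone interpolation.
#'
#' @param dist a `histology_distribution`.
#' @param t TMB values (mutations/Mb).
#' @param p probabilities in \[0, 1\].
#' @return Numeric vector.
#' @export
dist_density <- function(dist, t) {
  out <- stats::approx(dist$x, dist$fx, xout = t, yleft = 0, yright = 0)$y
  out[t < 0] <- 0
  out
}

#' @rdname dist_density
#' @export
dist_cdf <- function(dist, t) {
  out <- stats::approx(dist$x, dist$cdf, xout = t, yleft = 0, yright = 1)$y
  out[t < 0] <- 0
  out
}

#' @rdname dist_density
#' @export
dist_quantile <- function(dist, p) {
  stopifnot(all(p >= 0), all(p <= 1))
  # restrict to strictly increasing CDF segments so interpolation is monotone
  keep <- c(TRUE, diff(dist$cdf) > 0)
  xs <- dist$x[keep]
  cs <- dist$cdf[keep]
  out <- stats::approx(cs, xs, xout = p, yleft = xs[1], yright = max(dist$x),
                       ties = "ordered")$y
  out
}

#' Top-fraction TMB threshold
#'
#' Returns the threshold tau such that a fraction `top_fraction` of the
#' distribution lies at or above tau, i.e. the (1 - top_fraction) quantile.
#' This is the per-histology "top 20 percent" rule used for
#' histology-adaptive thresholding.
#'
#' @param dist a `histology_distribution`.
#' @param top_fraction fraction in (0, 1] of the population to select.
#' @return Threshold in mutations/Mb; decreasing in `top_fraction`.
#' @export
quantile_threshold <- function(dist, top_fraction) {
  if (length(top_fraction) != 1 || top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must lie in (0, 1]", call. = FALSE)
  }
  dist_quantile(dist, 1 - top_fraction)
}

#' Sample true TMB values from a fitted distribution
#'
#' Inverse-CDF sampling on the tabulated grid; reproducible from `seed`.
#'
#' @param dist a `histology_distribution`.
#' @param n number of draws (>= 0).
#' @param seed integer seed.
#' @return Numeric vector of `n` nonnegative TMB values.
#' @export
sample_tmb <- function(dist, n, seed) {
  stopifnot(n >= 0)
  if (n == 0) return(numeric(0))
  u <- withr::with_seed(seed, stats::runif(n))
  dist_quantile(dist, u)
}

#' Median of a fitted TMB distribution
#' @param dist a `histology_distribution`.
#' @return The 50 percent quantile in mutations/Mb.
#' @export
dist_median <- function(dist) dist_quantile(dist, 0.5)

#' Write / read a tabulated distribution as CSV
#'
#' Serializes the density grid as a two-column CSV (`tmb`, `density`) for
#' inspection or reuse; `read_distribution_csv` reconstructs the object via
#' [grid_distribution].
#'
#' @param dist a `histology_distribution`.
#' @param path CSV file path.
#' @param histology label used on re-read.
#' @return `write_distribution_csv` invisibly returns `path`;
#'   `read_distribution_csv` returns a `histology_distribution`.
#' @export
write_distribution_csv <- function(dist, path) {
  utils::write.csv(data.frame(tmb = dist$x, density = dist$fx), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_distribution_csv
#' @export
read_distribution_csv <- function(path, histology = "from_file") {
  df <- utils::read.csv(path)
  grid_distribution(df$tmb, df$density, histology = histology)
}
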