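#' Ordinary least squares regression of panel TMB on whole-exome TMB
#'
#' The regression analysis typically performed on paired real-world data to
#' map panel TMB onto WES TMB. Both variables are in mutations/Mb, so the
#' noiseless ground-truth map is the identity (slope 1, intercept 0).
#'
#' @param paired a [tmb_cohort] with both `tmb_wes` and `tmb_panel`.
#' @param histology a histology code to subset on, or `"all"`.
#' @return List with `histology`, `slope`, `intercept` (mutations/Mb),
#'   `r_squared` and `n_pairs`.
#' @export
regress_panel_vs_wes <- function(paired, histology = "all") {
  keep <- !is.na(paired$tmb_wes) & !is.na(paired$tmb_panel)
  if (histology != "all") keep <- keep & paired$histology == histology
  wes <- paired$tmb_wes[keep]
  pan <- paired$tmb_panel[keep]
  if (length(wes) < 2) {
    stop("insufficient data: need >= 2 paired records", call. = FALSE)
  }
  if (stats::var(wes) == 0) {
    stop("degenerate data: tmb_wes has zero variance", call. = FALSE)
  }
  fit <- stats::lm(pan ~ wes)
  ss_tot <- sum((pan - mean(pan))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  structure(
    list(histology = histology,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         n_pairs = length(wes)),
    class = "tmb_regression")
}

#' @export
print.tmb_regression <- function(x, ...) {
  cat("<tmb_regression> ", x$histology, ": slope=", signif(x$slope, 4),
      ", intercept=", signif(x$intercept, 4),
      ", R^2=", signif(x$r_squared, 4), " (n=", x$n_pairs, ")\n", sep = "")
  invisible(x)
}

slope_only <- function(wes, pan) {
  stats::cov(wes, pan) / stats::var(wes)
}

#' Histology dependence of panel-vs-WES regression variability
#'
#' For each histology, simulates a paired WES/panel cohort (either through
#' the Gaussian + Poisson measurement model or by binomial thinning of the
#' exome counts), then bootstraps the OLS slope of panel TMB on WES TMB and
#' reports its interquartile range as the dispersion statistic. Although
#' the simulated ground-truth map is identical for every histology (it
#' depends on panel size only), low-TMB histologies produce more variable
#' slopes because small counts make the measurement noise markedly
#' non-normal and asymmetric — negative TMB being impossible.
#'
#' @param dists named list of `histology_distribution` objects (>= 2).
#' @param panel a [panel_model].
#' @param n_per_cohort samples per simulated cohort.
#' @param n_boot bootstrap replicates (>= 50).
#' @param seed integer seed.
#' @param method `"model"` or `"thinning"`; see [add_panel_measurements].
#' @return Tibble (histology, median_tmb, mean_slope, slope_iqr), sorted by
#'   increasing median TMB.
#' @export
regression_variability_scan <- function(dists, panel, n_per_cohort = 200,
                                        n_boot = 200, seed = 1,
                                        method = c("model", "thinning")) {
  method <- match.arg(method)
  if (length(dists) < 2) {
    stop("insufficient data: need >= 2 histologies", call. = FALSE)
  }
  if (n_boot < 50) stop("n_boot must be >= 50", call. = FALSE)
  if (is.null(names(dists))) {
    names(dists) <- vapply(dists, function(d) d$histology, character(1))
  }
  rows <- lapply(seq_along(dists), function(i) {
    d <- dists[[i]]
    s <- seed + 1000L * i
    t_true <- sample_tmb(d, n_per_cohort, seed = s)
    if (method == "model") {
      pan <- simulate_panel_tmb(panel, t_true, n_reps = 1, seed = s + 1)
    } else {
      K <- panel$K
      pan <- withr::with_seed(s + 1, stats::rbinom(
        length(t_true), size = round(t_true * panel$exome_size_L0),
        prob = K)) / panel$panel_size_L
    }
    slopes <- withr::with_seed(s + 2, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n_per_cohort, replace = TRUE)
        slope_only(t_true[idx], pan[idx])
      }, numeric(1))
    })
    tibble::tibble(histology = names(dists)[i],
                   median_tmb = dist_median(d),
                   mean_slope = mean(slopes),
                   slope_iqr = stats::IQR(slopes))
  })
  out <- do.call(rbind, rows)
  out[order(out$median_tmb), ]
}

# -- threshold solvers --------------------------------------------------------
#
# For a noisy panel the selection probability depends on tau only through the
# smallest selected integer count m = floor(tau * L) + 1, so Z(tau) and
# ORR(tau) are step functions of tau. The solvers therefore search over the
# integer count threshold (by bisection, using monotonicity) and return a tau
# in the middle of the count bin that comes closest to the target; the
# achieved value and the residual gap are attached as attributes, since the
# discreteness of small panels bounds the attainable precision by the
# probability mass of a single count. Noiseless devices are continuous and
# solve to the stated tolerance directly.

count_upper_bound <- function(dist, panel) {
  q_hi <- dist_quantile(dist, 0.999)
  kt <- q_hi * panel$panel_size_L
  ceiling(kt + panel$lambda_driver + 6 * (panel$C0 + sqrt(kt))) + 2L
}

treated_fraction_count <- function(dist, panel, m) {
  # Z restricted to integer count threshold m (select iff count >= m)
  tau <- (m - 0.5) / panel$panel_size_L
  treated_fraction(dist, panel, tau)
}

expected_orr_count <- function(dist, psi, panel, m) {
  tau <- (m - 0.5) / panel$panel_size_L
  expected_orr(dist, psi, panel, tau)
}

#' Threshold achieving a target treated fraction
#'
#' Finds the threshold tau such that the panel selects a fraction
#' `target_fraction` of the population ([treated_fraction]). For a noiseless
#' device this is the exact (1 - target) quantile of the TMB distribution.
#' For a noisy panel the treated fraction is a step function of tau (the
#' readout is an integer count), so the returned tau achieves the nearest
#' attainable fraction; the achieved value and residual gap are attached as
#' attributes `achieved` and `gap`.
#'
#' @param dist a `histology_distribution`.
#' @param panel a [panel_model].
#' @param target_fraction target in (0, 1).
#' @return Threshold tau (mutations/Mb) with attributes `achieved`, `gap`.
#' @export
threshold_for_fraction <- function(dist, panel, target_fraction) {
  stopifnot(target_fraction > 0, target_fraction < 1)
  if (panel$noiseless) {
    tau <- dist_quantile(dist, 1 - target_fraction)
    ach <- treated_fraction(dist, panel, tau)
    return(structure(tau, achieved = ach, gap = ach - target_fraction))
  }
  L <- panel$panel_size_L
  hi <- count_upper_bound(dist, panel)
  # bisect for the largest m with Z(m) >= target (Z nonincreasing in m)
  lo <- 1L
  if (treated_fraction_count(dist, panel, hi) >= target_fraction) {
    lo <- hi
  } else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (treated_fraction_count(dist, panel, mid) >= target_fraction) {
        lo <- mid
      } else hi <- mid
    }
  }
  cand <- unique(c(lo, min(lo + 1L, hi)))
  z <- vapply(cand, function(m) treated_fraction_count(dist, panel, m),
              numeric(1))
  best <- cand[which.min(abs(z - target_fraction))]
  ach <- z[match(best, cand)]
  structure((best - 0.5) / L, achieved = ach, gap = ach - target_fraction)
}

#' Threshold achieving a target expected ORR
#'
#' Finds the threshold tau such that the expected ORR of the selected
#' cohort ([expected_orr]) equals `target_orr`. ORR is nondecreasing in tau
#' for a nondecreasing response function; plateau ties are resolved to the
#' smallest satisfying tau. For noisy panels the same count-discreteness
#' caveat as in [threshold_for_fraction] applies and the achieved ORR is
#' attached as an attribute. If the target lies outside the attainable
#' range over the search bracket, an error reports that range.
#'
#' @param dist a `histology_distribution`.
#' @param panel a [panel_model].
#' @param psi a nondecreasing [response_function][response_step].
#' @param target_orr target response rate.
#' @param tol acceptance tolerance used for the plateau/round-trip check.
#' @return Threshold tau (mutations/Mb) with attributes `achieved`, `gap`.
#' @export
threshold_for_orr <- function(dist, panel, psi, target_orr, tol = 1e-3) {
  if (panel$noiseless) {
    # continuous: ORR(tau) for every grid tau via reverse cumulative integrals
    x <- dist$x
    fx <- dist$fx
    psix <- evaluate_response(psi, x)
    seg <- diff(x) * (utils::head(fx, -1) + utils::tail(fx, -1)) / 2
    segn <- diff(x) * (utils::head(fx * psix, -1) + utils::tail(fx * psix, -1)) / 2
    z_tail <- rev(cumsum(rev(c(seg, 0))))      # P(T >= x_i)
    n_tail <- rev(cumsum(rev(c(segn, 0))))
    ok <- z_tail > 1e-12
    orr <- ifelse(ok, n_tail / pmax(z_tail, 1e-300), NA_real_)
    rng <- range(orr, na.rm = TRUE)
    if (target_orr > rng[2] + tol || target_orr < rng[1] - tol) {
      stop(sprintf(
        "solver error: target ORR %.4g outside attainable range [%.4g, %.4g]",
        target_orr, rng[1], rng[2]), call. = FALSE)
    }
    hit <- which(ok & orr >= target_orr - tol)
    if (length(hit) == 0) hit <- which.max(orr)
    tau <- x[hit[1]]                            # smallest satisfying tau
    ach <- orr[hit[1]]
    return(structure(tau, achieved = ach, gap = ach - target_orr))
  }
  hi <- count_upper_bound(dist, panel)
  orr_lo <- expected_orr_count(dist, psi, panel, 1L)
  orr_hi <- expected_orr_count(dist, psi, panel, hi)
  if (target_orr > orr_hi + tol || target_orr < orr_lo - tol) {
    stop(sprintf(
      "solver error: target ORR %.4g outside attainable range [%.4g, %.4g]",
      target_orr, orr_lo, orr_hi), call. = FALSE)
  }
  lo <- 1L
  # bisect for the smallest m with ORR(m) >= target (ORR nondecreasing in m)
  if (orr_lo >= target_orr) {
    hi <- lo
  } else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (expected_orr_count(dist, psi, panel, mid) >= target_orr) {
        hi <- mid
      } else lo <- mid
    }
  }
  cand <- unique(c(max(hi - 1L, 1L), hi))
  o <- vapply(cand, function(m) expected_orr_count(dist, psi, panel, m),
              numeric(1))
  best_i <- which.min(abs(o - target_orr))      # ties -> smaller m
  best <- cand[best_i]
  structure((best - 0.5) / panel$panel_size_L,
            achieved = o[best_i], gap = o[best_i] - target_orr)
}

#' The harmonization trade-off between treated fraction and ORR
#'
#' Quantifies whether a second assay (`panel_b`) can be harmonized to a
#' reference assay (`panel_a`) on both criteria at once. The reference is
#' operated at the threshold that selects `target_fraction` of the
#' population, defining the reference operating point (treated fraction
#' `Z_ref`, response rate `ORR_ref`). For the second assay the report then
#' solves two thresholds: one matching the reference's treated fraction
#' (and records the ORR mismatch there) and one matching the reference's
#' ORR (and records the treated-fraction mismatch there). For assays with
#' different noise no single threshold removes both mismatches:
#' `impossible = TRUE` when both gaps exceed `tol`. The target-based
#' solutions (threshold for `target_fraction`, threshold for `target_orr`)
#' are reported per assay as well, since the two solutions differing is the
#' within-assay face of the same trade-off.
#'
#' @param dist a `histology_distribution`.
#' @param panel_a reference [panel_model] (e.g. [noiseless_wes]).
#' @param panel_b comparison [panel_model].
#' @param psi a nondecreasing [response_function][response_step].
#' @param target_fraction target treated fraction in (0, 1).
#' @param target_orr target ORR for the per-assay solutions.
#' @param tol equality tolerance for the `impossible` flag (default one
#'   percentage point).
#' @return A list of class `harmonization_report`.
#' @export
harmonization_tradeoff <- function(dist, panel_a, panel_b, psi,
                                   target_fraction = 0.2, target_orr = 0.5,
                                   tol = 0.01) {
  per_target <- function(panel) {
    tau_f <- threshold_for_fraction(dist, panel, target_fraction)
    tau_o <- threshold_for_orr(dist, panel, psi, target_orr)
    list(tau_fraction = as.numeric(tau_f),
         fraction_achieved = attr(tau_f, "achieved"),
         tau_orr = as.numeric(tau_o),
         orr_achieved = attr(tau_o, "achieved"))
  }
  a <- per_target(panel_a)
  b <- per_target(panel_b)
  z_ref <- a$fraction_achieved
  orr_ref <- expected_orr(dist, psi, panel_a, a$tau_fraction)

  tau_b_frac <- threshold_for_fraction(dist, panel_b, z_ref)
  orr_gap <- expected_orr(dist, psi, panel_b, as.numeric(tau_b_frac)) - orr_ref
  tau_b_orr <- threshold_for_orr(dist, panel_b, psi, orr_ref)
  frac_gap <- treated_fraction(dist, panel_b, as.numeric(tau_b_orr)) - z_ref

  structure(
    list(target_fraction = target_fraction, target_orr = target_orr,
         tol = tol, panel_a = a, panel_b = b,
         reference_fraction = z_ref, reference_orr = orr_ref,
         tau_b_fraction_matched = as.numeric(tau_b_frac),
         tau_b_orr_matched = as.numeric(tau_b_orr),
         orr_gap_at_matched_fraction = orr_gap,
         fraction_gap_at_matched_orr = frac_gap,
         impossible = abs(orr_gap) > tol && abs(frac_gap) > tol),
    class = "harmonization_report")
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat("<harmonization_report> targets: fraction=", x$target_fraction,
      ", ORR=", x$target_orr, "\n", sep = "")
  for (nm in c("panel_a", "panel_b")) {
    p <- x[[nm]]
    cat(sprintf(
      "  %s: tau(fraction)=%.3f (Z=%.3f); tau(ORR)=%.3f (ORR=%.3f)\n",
      nm, p$tau_fraction, p$fraction_achieved, p$tau_orr, p$orr_achieved))
  }
  cat(sprintf(
    "  reference operating point: Z=%.3f, ORR=%.3f\n",
    x$reference_fraction, x$reference_orr))
  cat(sprintf(
    "  panel_b gaps: ORR %+.3f at matched fraction; fraction %+.3f at matched ORR\n",
    x$orr_gap_at_matched_fraction, x$fraction_gap_at_matched_orr))
  cat("  joint harmonization possible: ",
      if (x$impossible) "NO" else "yes", "\n", sep = "")
  invisible(x)
}

# -- Cramer / energy two-sample concordance ----------------------------------

sum_abs_diff_within <- function(x) {
  # sum_{i<j} |x_i - x_j| for sorted input, O(n log n) overall
  x <- sort(x)
  n <- length(x)
  sum(x * (2 * seq_len(n) - n - 1))
}

sum_abs_diff_cross <- function(x, y) {
  # sum_{i,j} |x_i - y_j| via prefix sums of sorted x
  x <- sort(x)
  m <- length(x)
  S <- cumsum(x)
  k <- findInterval(y, x)
  Sk <- c(0, S)[k + 1]
  sum(y * k - Sk + (S[m] - Sk) - y * (m - k))
}

#' Two-sample energy statistic
#'
#' The Baringhaus-Franz (Cramer-type) statistic
#' T = mn/(m+n) * ( mean|X - Y| - mean|X - X'|/2 - mean|Y - Y'|/2 ),
#' computed in O(N log N) via sorted prefix sums. Zero iff the two samples
#' are identical; large under distributional difference.
#'
#' @param x,y numeric samples.
#' @return The statistic (nonnegative scalar).
#' @export
energy_statistic <- function(x, y) {
  m <- length(x)
  n <- length(y)
  if (m == 0 || n == 0) stop("insufficient data: empty sample", call. = FALSE)
  cross <- sum_abs_diff_cross(x, y) / (m * n)
  wx <- 2 * sum_abs_diff_within(x) / (m * m)
  wy <- 2 * sum_abs_diff_within(y) / (n * n)
  (m * n / (m + n)) * (cross - wx / 2 - wy / 2)
}

#' Cramer two-sample concordance test
#'
#' Permutation test of the hypothesis that two TMB samples come from the
#' same distribution, based on the [energy_statistic]. The p-value is
#' `(1 + #{permuted >= observed}) / (n_perm + 1)`, hence always in (0, 1].
#'
#' @param sample_a,sample_b numeric TMB samples (non-empty).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return List with `statistic` and `p_value`.
#' @export
cramer_concordance <- function(sample_a, sample_b, n_perm = 999, seed = 1) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("insufficient data: empty sample", call. = FALSE)
  }
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  obs <- energy_statistic(sample_a, sample_b)
  pooled <- c(sample_a, sample_b)
  m <- length(sample_a)
  N <- length(pooled)
  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(N, m)
      energy_statistic(pooled[idx], pooled[-idx]) >= obs
    }, logical(1)))
  })
  list(statistic = obs, p_value = (1 + exceed) / (n_perm + 1))
}
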