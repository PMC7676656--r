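#' Fraction of the population selected for treatment
#'
#' The treated fraction ("market size") Z(tau, sigma) = integral of
#' Pi(T) Theta(T, tau, sigma) dT: the probability that a patient drawn from
#' the histology's TMB distribution is classified TMB-high by the panel.
#' Evaluated by trapezoidal quadrature on the distribution's grid, with the
#' selection probability computed analytically.
#'
#' @param dist a `histology_distribution`.
#' @param panel a [panel_model].
#' @param tau classification threshold in mutations/Mb.
#' @return Probability in \[0, 1\]; nonincreasing in `tau`.
#' @export
treated_fraction <- function(dist, panel, tau) {
  theta <- selection_probability(panel, tau, dist$x)
  z <- trapz_integral(dist$x, dist$fx * theta)
  min(max(z, 0), 1)
}

#' Expected overall response rate of the selected cohort
#'
#' P_response(tau, sigma) = (1/Z) * integral of Pi(T) Psi(T) Theta(T) dT:
#' the expected fraction of responders among patients the panel classifies
#' TMB-high. Evaluated by quadrature on the distribution's grid.
#'
#' @param dist a `histology_distribution`.
#' @param psi a [response_function][response_step].
#' @param panel a [panel_model].
#' @param tau classification threshold in mutations/Mb.
#' @return Probability, bounded by the range of `psi`.
#' @export
expected_orr <- function(dist, psi, panel, tau) {
  theta <- selection_probability(panel, tau, dist$x)
  z <- trapz_integral(dist$x, dist$fx * theta)
  if (z <= 0) {
    stop("undefined cohort: treated fraction is zero, nobody is selected",
         call. = FALSE)
  }
  num <- trapz_integral(dist$x, dist$fx * evaluate_response(psi, dist$x) * theta)
  num / z
}

#' Concordance of a panel classification against noiseless truth
#'
#' Monte-Carlo estimate of the 2x2 agreement between the noisy panel call
#' (readout > `tau_panel`) and the noiseless gold-standard call
#' (T >= `tau_truth`) for patients drawn from the histology distribution.
#' Returns positive/negative percent agreement (PPA = TP/(TP+FN),
#' NPA = TN/(TN+FP)), overall percent agreement, and positive/negative
#' predictive values. A metric whose denominator stratum is empty is
#' reported as `NA`, never coerced to 0 or 1.
#'
#' @param dist a `histology_distribution`.
#' @param panel a [panel_model].
#' @param tau_panel threshold applied to the panel readout (mutations/Mb).
#' @param tau_truth threshold defining true TMB-high status; defaults to
#'   `tau_panel`.
#' @param n_mc Monte-Carlo sample size (>= 1000).
#' @param seed integer seed.
#' @return Named list with `ppa`, `npa`, `opa`, `ppv`, `npv` and the counts
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
classification_metrics <- function(dist, panel, tau_panel,
                                   tau_truth = tau_panel,
                                   n_mc = 10000, seed = 1) {
  stopifnot(n_mc >= 1000)
  t_true <- sample_tmb(dist, n_mc, seed = seed)
  truth <- t_true >= tau_truth
  if (panel$noiseless) {
    test <- t_true >= tau_panel
  } else {
    readout <- simulate_panel_tmb(panel, t_true, n_reps = 1, seed = seed + 1)
    test <- readout > tau_panel
  }
  metrics_from_confusion(sum(test & truth), sum(test & !truth),
                         sum(!test & !truth), sum(!test & truth))
}

metrics_from_confusion <- function(tp, fp, tn, fn) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  list(ppa = ratio(tp, tp + fn), npa = ratio(tn, tn + fp),
       opa = ratio(tp + tn, tp + fp + tn + fn),
       ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Outcome summaries over a grid of histologies, panel sizes and thresholds
#'
#' For every combination of histology distribution, panel size and
#' threshold, computes the treated fraction and expected ORR by quadrature
#' and the concordance metrics by Monte Carlo. Thresholds may be fixed
#' values (numeric vector) or a per-histology top-fraction rule
#' (`list(top_fraction = q)`), resolved through [quantile_threshold]. A cell
#' whose computation fails is recorded with `NA` values and the error
#' message rather than aborting the grid.
#'
#' @param dists named list of `histology_distribution` objects.
#' @param psi a [response_function][response_step].
#' @param panel_sizes panel sizes in Mbp.
#' @param thresholds numeric vector of thresholds (mutations/Mb) or
#'   `list(top_fraction = q)`.
#' @param n_mc Monte-Carlo size for the concordance metrics.
#' @param seed integer seed.
#' @param C0,lambda_driver,exome_size_L0 noise constants for the panels.
#' @return A tibble with one row per (histology, panel size, threshold).
#' @export
outcome_grid <- function(dists, psi, panel_sizes, thresholds,
                         n_mc = 10000, seed = 1,
                         C0 = 0.5, lambda_driver = 1, exome_size_L0 = 35.6) {
  stopifnot(length(dists) > 0, length(panel_sizes) > 0)
  if (is.null(names(dists))) {
    names(dists) <- vapply(dists, function(d) d$histology, character(1))
  }
  top_frac <- NULL
  if (is.list(thresholds) && !is.null(thresholds$top_fraction)) {
    top_frac <- thresholds$top_fraction
    thresholds <- NA_real_  # resolved per histology below
  }
  cells <- expand.grid(histology = names(dists), L = panel_sizes,
                       tau = thresholds, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    h <- cells$histology[i]
    d <- dists[[h]]
    tau <- if (is.null(top_frac)) cells$tau[i] else
      quantile_threshold(d, top_frac)
    out <- tryCatch({
      pm <- panel_model(cells$L[i], exome_size_L0, C0 = C0,
                        lambda_driver = lambda_driver)
      m <- classification_metrics(d, pm, tau_panel = tau, tau_truth = tau,
                                  n_mc = n_mc, seed = seed + i)
      tibble::tibble(
        histology = h, panel_size_L = cells$L[i], threshold_tau = tau,
        treated_fraction = treated_fraction(d, pm, tau),
        orr = expected_orr(d, psi, pm, tau),
        ppa = m$ppa, npa = m$npa, opa = m$opa, ppv = m$ppv, npv = m$npv,
        error = NA_character_)
    }, error = function(e) {
      tibble::tibble(
        histology = h, panel_size_L = cells$L[i], threshold_tau = tau,
        treated_fraction = NA_real_, orr = NA_real_,
        ppa = NA_real_, npa = NA_real_, opa = NA_real_,
        ppv = NA_real_, npv = NA_real_, error = conditionMessage(e))
    })
    out
  })
  do.call(rbind, rows)
}
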