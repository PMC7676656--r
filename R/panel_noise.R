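#' Panel measurement model
#'
#' Parameters of the measurement process by which a targeted panel of size
#' `panel_size_L` (Mbp) records the mutations of a tumor whose exome-wide
#' mutation count is t. Writing K = L / L0 for the panel-to-exome size
#' ratio, the recorded count is modelled as
#'
#'   t~ = round( K t + N(0, sigma) + Poisson(lambda) ),  clamped at 0,
#'
#' with sigma = C0 + sqrt(K t). The Gaussian term is the panel's sampling
#' noise (binomial thinning in its normal approximation), `C0` a
#' panel-size-independent noise floor (e.g. germline subtraction errors), and
#' `lambda` the mean number of enriched driver/germline counts a targeted
#' panel picks up regardless of its size. The reported panel TMB is t~ / L.
#'
#' @param panel_size_L panel territory in Mbp, in (0, exome_size_L0].
#' @param exome_size_L0 exome territory in Mbp (default 35.6).
#' @param C0 nonnegative Gaussian noise constant (counts). Default 0.5.
#' @param lambda_driver nonnegative Poisson rate of driver/germline counts.
#'   Default 1.
#' @param noiseless if `TRUE`, the device reports t~ = K t exactly and
#'   classifies with the `>=` convention; used for the idealized
#'   whole-exome gold standard.
#' @return An object of class `panel_model`.
#' @export
panel_model <- function(panel_size_L, exome_size_L0 = 35.6, C0 = 0.5,
                        lambda_driver = 1, noiseless = FALSE) {
  stopifnot(panel_size_L > 0, exome_size_L0 > 0,
            panel_size_L <= exome_size_L0, C0 >= 0, lambda_driver >= 0)
  structure(
    list(panel_size_L = panel_size_L, exome_size_L0 = exome_size_L0,
         C0 = C0, lambda_driver = lambda_driver, noiseless = noiseless,
         K = panel_size_L / exome_size_L0),
    class = "panel_model")
}

#' A zero-noise whole-exome device
#'
#' Convenience constructor for the idealized gold-standard assay: full exome
#' territory, no Gaussian noise, no driver enrichment, `>=` classification.
#'
#' @param exome_size_L0 exome territory in Mbp.
#' @return A `panel_model` with `noiseless = TRUE`.
#' @export
noiseless_wes <- function(exome_size_L0 = 35.6) {
  panel_model(exome_size_L0, exome_size_L0, C0 = 0, lambda_driver = 0,
              noiseless = TRUE)
}

#' @export
print.panel_model <- function(x, ...) {
  cat("<panel_model> L=", x$panel_size_L, " Mbp (K=", signif(x$K, 4),
      "), C0=", x$C0, ", lambda=", x$lambda_driver,
      if (x$noiseless) " [noiseless]" else "", "\n", sep = "")
  invisible(x)
}

#' Gaussian noise scale of a panel readout
#'
#' sigma = C0 + sqrt(expected panel count), in counts. Nondecreasing in the
#' expected count.
#'
#' @param panel a [panel_model].
#' @param expected_panel_count expected number of mutations on the panel,
#'   K t (nonnegative).
#' @return Noise standard deviation in counts.
#' @export
panel_sigma <- function(panel, expected_panel_count) {
  if (any(expected_panel_count < 0)) {
    stop("expected_panel_count must be nonnegative", call. = FALSE)
  }
  panel$C0 + sqrt(expected_panel_count)
}

#' Simulate panel TMB readouts
#'
#' Draws replicate panel TMB measurements for given true TMB values: scale
#' the exome count to the panel (K t), add centered Gaussian noise with
#' scale [panel_sigma], add a Poisson driver count, round to an integer,
#' clamp at zero, and divide by the panel size. All readouts are therefore
#' nonnegative multiples of 1 / `panel_size_L`.
#'
#' @param panel a [panel_model].
#' @param true_tmb vector of true TMB values T (mutations/Mb).
#' @param n_reps replicates per value of `true_tmb`.
#' @param seed integer seed.
#' @return If `n_reps == 1` or `length(true_tmb) == 1`, a numeric vector;
#'   otherwise an `n_reps` x `length(true_tmb)` matrix.
#' @export
simulate_panel_tmb <- function(panel, true_tmb, n_reps = 1, seed) {
  stopifnot(all(true_tmb >= 0), n_reps >= 0)
  nT <- length(true_tmb)
  if (n_reps == 0 || nT == 0) return(numeric(0))
  Kt <- rep(true_tmb * panel$panel_size_L, each = n_reps)  # expected counts
  if (panel$noiseless) {
    out <- Kt / panel$panel_size_L
  } else {
    sigma <- panel_sigma(panel, Kt)
    counts <- withr::with_seed(seed, {
      g <- stats::rnorm(length(Kt), mean = 0, sd = 1) * sigma
      p <- stats::rpois(length(Kt), lambda = panel$lambda_driver)
      pmax(round(Kt + g + p), 0)
    })
    out <- counts / panel$panel_size_L
  }
  if (n_reps == 1 || nT == 1) return(as.numeric(out))
  matrix(out, nrow = n_reps, ncol = nT)
}

# Upper truncation point of the Poisson driver mass, leaving < 1e-12 tail.
poisson_cutoff <- function(lambda) {
  if (lambda == 0) return(0L)
  stats::qpois(1 - 1e-12, lambda)
}

#' Probability that a panel classifies a patient TMB-high
#'
#' The selection probability Theta(T, tau, sigma) = P(t~ / L > tau): the
#' chance that the noisy, discretized panel readout exceeds the threshold
#' `tau`, for a patient with true TMB `T`. The analytic method sums the
#' Poisson driver mass (truncated below 1e-12 tail probability) against the
#' rounded Gaussian: t~ > tau L for integer t~ means t~ >= m =
#' floor(tau L) + 1, and round(x) >= m means x >= m - 1/2. For a noiseless
#' device the step function with the `>=` convention is returned:
#' Theta = 1 if T >= tau, else 0.
#'
#' @param panel a [panel_model].
#' @param tau classification threshold in mutations/Mb (>= 0).
#' @param true_tmb vector of true TMB values (mutations/Mb).
#' @param method `"analytic"` or `"monte_carlo"`.
#' @param n_mc Monte-Carlo replicates (`method = "monte_carlo"` only; > 0).
#' @param seed integer seed for the Monte-Carlo method.
#' @return Selection probabilities in \[0, 1\], same length as `true_tmb`.
#' @export
selection_probability <- function(panel, tau, true_tmb,
                                  method = c("analytic", "monte_carlo"),
                                  n_mc = 1e5, seed = 1) {
  method <- match.arg(method)
  stopifnot(tau >= 0, all(true_tmb >= 0))
  if (panel$noiseless) return(as.numeric(true_tmb >= tau))
  if (method == "monte_carlo") {
    if (n_mc <= 0) stop("n_mc must be positive", call. = FALSE)
    probs <- vapply(seq_along(true_tmb), function(i) {
      r <- simulate_panel_tmb(panel, true_tmb[i], n_reps = n_mc,
                              seed = seed + i - 1)
      mean(r > tau)
    }, numeric(1))
    return(probs)
  }
  L <- panel$panel_size_L
  Kt <- true_tmb * L
  sigma <- panel_sigma(panel, Kt)
  m <- floor(tau * L) + 1            # smallest selected integer count
  jmax <- poisson_cutoff(panel$lambda_driver)
  out <- numeric(length(true_tmb))
  for (j in 0:jmax) {
    wj <- stats::dpois(j, panel$lambda_driver)
    mu <- Kt + j
    term <- ifelse(sigma > 0,
                   stats::pnorm(m - 0.5, mean = mu, sd = sigma,
                                lower.tail = FALSE),
                   as.numeric(mu >= m - 0.5))
    out <- out + wj * term
  }
  pmin(pmax(out, 0), 1)
}

#' Fit the noise constants C0 and lambda by grid search
#'
#' Given a cohort with paired whole-exome and panel TMB measurements,
#' evaluates every `(C0, lambda)` grid point by simulating panel readouts
#' from each sample's `tmb_wes` and scoring the concordance between the
#' simulated and observed noise residuals `tmb_panel - tmb_wes` (the
#' expected panel readout equals the WES TMB, so the residual isolates the
#' measurement noise: comparing residuals rather than pooled readouts
#' removes the spread of the TMB distribution itself from the objective and
#' makes the small effect of `C0` identifiable). `"quantile_rmse"` scores
#' the root-mean-square difference between the 1..99 percentiles of the two
#' residual samples; `"energy_distance"` uses the two-sample energy
#' statistic (see [cramer_concordance]). Common random numbers (one seed
#' for all grid points) make the grid comparison deterministic and
#' low-noise.
#'
#' @param paired a [tmb_cohort] with `tmb_wes` and `tmb_panel` present
#'   (>= 20 pairs).
#' @param panel_size_L panel size in Mbp.
#' @param grid_C0,grid_lambda nonnegative candidate values.
#' @param concordance `"quantile_rmse"` or `"energy_distance"`.
#' @param seed integer seed.
#' @param n_rep simulated readouts per sample per grid point.
#' @param exome_size_L0 exome size in Mbp.
#' @return List with `C0`, `lambda_driver`, and `scores`, a tibble of the
#'   full grid with one score per point (minimized).
#' @export
fit_noise_params <- function(paired, panel_size_L, grid_C0, grid_lambda,
                             concordance = c("quantile_rmse", "energy_distance"),
                             seed = 1, n_rep = 20, exome_size_L0 = 35.6) {
  concordance <- match.arg(concordance)
  ok <- !is.na(paired$tmb_wes) & !is.na(paired$tmb_panel)
  wes <- paired$tmb_wes[ok]
  obs <- paired$tmb_panel[ok]
  if (length(wes) < 20) {
    stop("insufficient data: need >= 20 paired WES/panel records",
         call. = FALSE)
  }
  if (length(grid_C0) == 0 || length(grid_lambda) == 0 ||
      any(grid_C0 < 0) || any(grid_lambda < 0)) {
    stop("grids must be non-empty and nonnegative", call. = FALSE)
  }
  probs <- seq(0.01, 0.99, by = 0.01)
  res_obs <- obs - wes
  qobs <- stats::quantile(res_obs, probs, names = FALSE)
  grid <- expand.grid(C0 = grid_C0, lambda = grid_lambda)
  wes_rep <- rep(wes, each = n_rep)
  score <- vapply(seq_len(nrow(grid)), function(i) {
    pm <- panel_model(panel_size_L, exome_size_L0, C0 = grid$C0[i],
                      lambda_driver = grid$lambda[i])
    sim <- as.numeric(simulate_panel_tmb(pm, wes, n_reps = n_rep, seed = seed))
    res_sim <- sim - wes_rep
    if (concordance == "quantile_rmse") {
      qsim <- stats::quantile(res_sim, probs, names = FALSE)
      sqrt(mean((qsim - qobs)^2))
    } else {
      energy_statistic(res_sim, res_obs)
    }
  }, numeric(1))
  best <- which.min(score)
  list(C0 = grid$C0[best], lambda_driver = grid$lambda[best],
       scores = tibble::tibble(C0 = grid$C0, lambda = grid$lambda,
                               score = score))
}
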