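#' Treatment response functions of true TMB
#'
#' A response function Psi(T) gives the probability that a patient with true
#' TMB T responds to checkpoint-inhibitor treatment. Three families are
#' supported:
#'
#' * `response_step(tau)`: perfect predictor, Psi(T) = 1 if T >= tau else 0.
#' * `response_two_level(tau, p_high, p_low)`: Psi(T) = p_high above the
#'   threshold, p_low below (e.g. 80 percent vs 20 percent ORR).
#' * `response_gamma(shape, rate)`: the CDF of a Gamma(shape, rate)
#'   distribution — the lower incomplete gamma function. Mechanistically,
#'   if neoepitope presentations accrue as a Poisson process in T, the
#'   waiting "time" (TMB) to the shape-th presentation is Gamma distributed,
#'   so the probability that at least `shape` neoepitopes have been
#'   presented by burden T is this CDF. Shape 1 (immunodominance: a single
#'   epitope suffices) reduces to 1 - exp(-rate * T).
#'
#' @param tau threshold in mutations/Mb.
#' @param p_high,p_low response probabilities above/below the threshold,
#'   with 0 <= p_low <= p_high <= 1.
#' @param shape positive integer number of neoepitopes required.
#' @param rate positive rate per (mutations/Mb).
#' @return An object of class `response_function`.
#' @export
response_step <- function(tau) {
  stopifnot(tau >= 0)
  structure(list(kind = "step", tau_resp = tau), class = "response_function")
}

#' @rdname response_step
#' @export
response_two_level <- function(tau, p_high, p_low) {
  stopifnot(tau >= 0, p_low >= 0, p_high <= 1, p_low <= p_high)
  structure(list(kind = "two_level", tau_resp = tau,
                 p_high = p_high, p_low = p_low),
            class = "response_function")
}

#' @rdname response_step
#' @export
response_gamma <- function(shape, rate) {
  stopifnot(shape >= 1, shape == round(shape), rate > 0)
  structure(list(kind = "gamma", shape_n = as.integer(shape), rate_r = rate),
            class = "response_function")
}

#' @export
print.response_function <- function(x, ...) {
  desc <- switch(x$kind,
    step = paste0("step at tau=", x$tau_resp),
    two_level = paste0("two-level at tau=", x$tau_resp, " (",
                       x$p_low, " / ", x$p_high, ")"),
    gamma = paste0("incomplete-gamma, shape=", x$shape_n,
                   ", rate=", signif(x$rate_r, 4)))
  cat("<response_function> ", desc, "\n", sep = "")
  invisible(x)
}

#' Evaluate a response function
#'
#' @param psi a [response_function][response_step].
#' @param t true TMB values (mutations/Mb, nonnegative).
#' @return Response probabilities in \[0, 1\].
#' @export
evaluate_response <- function(psi, t) {
  if (any(t < 0)) stop("TMB must be nonnegative", call. = FALSE)
  switch(psi$kind,
    step = as.numeric(t >= psi$tau_resp),
    two_level = ifelse(t >= psi$tau_resp, psi$p_high, psi$p_low),
    gamma = stats::pgamma(t, shape = psi$shape_n, rate = psi$rate_r))
}

#' Fit an incomplete-gamma response function to binary response data
#'
#' For each candidate integer shape, minimizes the ordinary least squares
#' error sum_i (response_i - Psi(T_i))^2 over the rate by bounded scalar
#' minimization (on log10 rate, tolerance 1e-8), and returns the global
#' minimizer across the shape grid. OLS on the binary outcomes is used
#' deliberately: E[response | T] = Psi(T), so the OLS objective is minimized
#' in expectation at the true parameters.
#'
#' @param data a [tmb_cohort] with `tmb_wes` and binary `response`
#'   (>= 10 complete records, both outcome classes present).
#' @param shape_grid positive integer candidate shapes (default 1:3).
#' @param rate_bounds search interval for the rate, per (mutations/Mb).
#' @return List with `shape_n`, `rate_r`, `ols_error`, and `by_shape`, a
#'   tibble of the per-shape optima.
#' @export
fit_gamma_response <- function(data, shape_grid = 1:3,
                               rate_bounds = c(1e-4, 10)) {
  ok <- !is.na(data$tmb_wes) & !is.na(data$response)
  t <- data$tmb_wes[ok]
  y <- data$response[ok]
  if (length(t) < 10) {
    stop("insufficient data: need >= 10 records with TMB and response",
         call. = FALSE)
  }
  if (all(y == 1) || all(y == 0)) {
    stop("degenerate data: need at least one responder and one non-responder",
         call. = FALSE)
  }
  stopifnot(all(shape_grid >= 1), all(shape_grid == round(shape_grid)),
            rate_bounds[1] > 0, rate_bounds[2] > rate_bounds[1])
  per_shape <- lapply(shape_grid, function(n) {
    obj <- function(log10r) {
      mean((y - stats::pgamma(t, shape = n, rate = 10^log10r))^2)
    }
    opt <- stats::optimize(obj, interval = log10(rate_bounds), tol = 1e-8)
    list(shape = n, rate = 10^opt$minimum, err = opt$objective)
  })
  errs <- vapply(per_shape, `[[`, numeric(1), "err")
  best <- per_shape[[which.min(errs)]]
  list(shape_n = best$shape, rate_r = best$rate,
       ols_error = best$err * length(t),
       by_shape = tibble::tibble(
         shape = vapply(per_shape, `[[`, numeric(1), "shape"),
         rate = vapply(per_shape, `[[`, numeric(1), "rate"),
         ols_error = errs * length(t)))
}

#' Calibrate the gamma response rate to a target ORR at a quantile threshold
#'
#' Solves Psi(tau_q) = `target_orr` for the rate, where tau_q is the
#' top-`top_fraction` threshold of the given TMB distribution — e.g. "50
#' percent response probability at the top-20-percent threshold". Because
#' pgamma(t, shape, rate) = pgamma(rate * t, shape, 1), the solution is the
#' closed form rate = qgamma(target_orr, shape, 1) / tau_q; a round-trip
#' check to 1e-6 is performed. For shape 1 this reduces to
#' -log(1 - target_orr) / tau_q.
#'
#' @param dist a `histology_distribution`.
#' @param shape_n positive integer shape.
#' @param top_fraction fraction in (0, 1) defining the threshold quantile.
#' @param target_orr target response probability in (0, 1) at the threshold.
#' @return Calibrated rate per (mutations/Mb).
#' @export
calibrate_gamma_rate <- function(dist, shape_n, top_fraction, target_orr) {
  stopifnot(top_fraction > 0, top_fraction < 1,
            target_orr > 0, target_orr < 1,
            shape_n >= 1, shape_n == round(shape_n))
  tau_q <- quantile_threshold(dist, top_fraction)
  if (tau_q <= 0) {
    stop("solver error: threshold quantile is not positive; ",
         "target unreachable on (0, Inf)", call. = FALSE)
  }
  rate <- stats::qgamma(target_orr, shape = shape_n, rate = 1) / tau_q
  achieved <- stats::pgamma(tau_q, shape = shape_n, rate = rate)
  if (abs(achieved - target_orr) > 1e-6) {
    stop("solver error: round-trip check failed (achieved ", achieved, ")",
         call. = FALSE)
  }
  rate
}
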