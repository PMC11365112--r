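# Two-step global Stern-Volmer analysis of an acrylamide quench
# titration: (1) empirical tri-exponential reconvolution fit of every
# decay, (2) reconstruction of the deconvoluted decays and a
# one-parameter global fit of the quenching rate constant kq with the
# zero-quencher decay F0(t) held fixed.

#' Global quenching-rate fit of a quench titration
#'
#' Step 1 fits each decay by multi-exponential reconvolution; step 2
#' reconstructs the noise-free decays and fits all quenched curves
#' jointly to F0(t) * exp(-t kq \[Q\]) by unweighted least squares over
#' the window \[0, 5 max(tau)\], adjusting only kq (constrained
#' non-negative; a negative unconstrained optimum warns).
#'
#' @param decays list of [decay_histogram()] with `quencher_M` metadata;
#'   at least 3 concentrations including \[Q\] = 0, no duplicates
#' @param irf shared [instrument_response()]
#' @param n_components components for the step-1 empirical fits
#' @param window optional step-1 fit window
#' @param n_starts multi-start count for the step-1 fits
#' @return an object of class `quench_fit_result` with `kq`, `F0_model`,
#'   `per_Q_sse`, `Q_list`, `fits`
#' @export
fit_quench_series <- function(decays, irf, n_components = 3,
                              window = NULL, n_starts = 3) {
  Q <- vapply(decays, function(d)
    as.numeric(d$meta$quencher_M %||% NA_real_), numeric(1))
  if (anyNA(Q)) stop("every decay needs `quencher_M` metadata")
  if (anyDuplicated(Q)) stop("duplicate quencher concentrations")
  if (!any(Q == 0)) stop("the series must include [Q] = 0")
  if (length(Q) < 3L) stop("at least 3 concentrations are required")

  fits <- lapply(decays, function(d)
    fit_multiexp_reconvolution(d, irf, n_components = n_components,
                               window = window, n_starts = n_starts))
  i0 <- which(Q == 0)
  F0_model <- fits[[i0]]$model
  tau_max <- max(vapply(fits, function(f) max(f$model$lifetimes),
                        numeric(1)))
  dt <- decays[[1]]$grid$dt
  tt <- seq(0, 5 * tau_max, by = dt)
  F0 <- multiexp_intensity(F0_model, tt)
  iq <- which(Q > 0)
  Fq <- lapply(fits[iq], function(f) multiexp_intensity(f$model, tt))

  sse_at <- function(kq) {
    s <- numeric(length(iq))
    for (k in seq_along(iq))
      # exponent capped so unphysical trial values (strongly negative
      # kq) stay finite instead of overflowing
      s[k] <- sum((Fq[[k]] - F0 * exp(pmin(-tt * kq * Q[iq[k]], 30)))^2)
    s
  }
  obj <- function(kq) sum(sse_at(kq))
  kq_hi <- 10 / (min(Q[iq]) * min(F0_model$lifetimes))
  un <- stats::optimize(obj, c(-kq_hi, kq_hi))
  if (un$minimum < -1e-6) {
    warning("unconstrained optimum kq = ", signif(un$minimum, 4),
            " is negative; returning the constrained non-negative fit")
    co <- stats::optimize(obj, c(0, kq_hi))
    kq <- max(co$minimum, 0)
  } else {
    kq <- max(un$minimum, 0)
  }
  structure(list(kq = kq, F0_model = F0_model,
                 per_Q_sse = stats::setNames(sse_at(kq), Q[iq]),
                 Q_list = Q, fits = fits),
            class = "quench_fit_result")
}

#' Exposure-versus-relaxation correlation line
#'
#' Ordinary least-squares line through (nu_inf, kq) points across
#' conditions: the apparent quenching constant as a function of the
#' limiting relaxation level.
#'
#' @param kq apparent quenching rate constants (y)
#' @param nu_inf limiting relaxation levels (x, cm^-1)
#' @return list with `slope`, `intercept`, `r_squared`
#' @export
quench_relaxation_scatter <- function(kq, nu_inf) {
  if (length(kq) != length(nu_inf)) stop("length mismatch")
  if (length(kq) < 3L) stop("at least 3 points are required")
  if (stats::sd(nu_inf) == 0)
    stop("slope undefined: all nu_inf values identical")
  fit <- stats::lm(kq ~ nu_inf)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((kq - mean(kq))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}
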