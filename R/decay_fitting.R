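# Iterative-reconvolution multi-exponential fitting of photon-count
# histograms, noise-free decay reconstruction, and the generic NSSR
# support-plane procedure.
#
# The fit minimizes Neyman-weighted least squares
#   sum_k (counts_k - model_k)^2 / max(counts_k, 1)
# over the fit window.  Lifetimes and the IRF shift are the nonlinear
# parameters; amplitudes and background are solved at each step by
# non-negative weighted linear least squares (variable projection), which
# keeps the optimization low-dimensional and robust.  A Poisson-deviance
# (MLE) objective is available as a switch.

# Non-negative weighted linear LS via normal equations with iterative
# clamping of negative coefficients (columns clamped to zero are dropped
# and the rest re-solved).  k is tiny (<= 4), so this is O(n k^2).
nnls_clamped <- function(X, y, w) {
  w2 <- w * w
  A <- crossprod(X, X * w2)
  b <- crossprod(X, y * w2)
  active <- rep(TRUE, ncol(X))
  beta <- rep(0, ncol(X))
  for (it in seq_len(ncol(X) + 1L)) {
    beta <- rep(0, ncol(X))
    fit <- tryCatch(
      solve(A[active, active, drop = FALSE], b[active, , drop = FALSE]),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- qr.coef(qr(X[, active, drop = FALSE] * w), y * w)
      fit[is.na(fit)] <- 0
    }
    beta[active] <- fit
    neg <- beta < -1e-12 * max(abs(beta), 1e-300)
    if (!any(neg)) return(pmax(beta, 0))
    active <- active & !neg
    if (!any(active)) return(rep(0, ncol(X)))
  }
  pmax(beta, 0)
}

# Precomputed per-fit context so the inner objective stays cheap.
make_reconv_ctx <- function(decay, irf, win) {
  t <- grid_times(decay$grid)
  n <- length(t)
  L <- stats::nextn(2L * n, 2)
  y <- decay$counts[win]
  list(t0 = t - t[1], n = n, L = L, win = win, y = y,
       w = 1 / sqrt(pmax(y, 1)), irf = irf)
}

# Objective pieces shared by the reconvolution fits: build the convolved
# exponential basis for given lifetimes/shift, solve amplitudes and
# background linearly, return SSR and components.  With nonneg = FALSE
# the amplitudes may go negative (rise terms of red-edge relaxation
# decays); the background stays clamped at >= 0.
reconv_eval <- function(log_tau, shift, ctx, mle = FALSE, nonneg = TRUE) {
  taus <- exp(log_tau)
  h <- shift_irf_counts(ctx$irf, shift)
  if (is.null(h))
    return(list(ssr = 1e300, amplitudes = rep(0, length(taus)),
                background = 0, taus = taus,
                fit = numeric(length(ctx$win)),
                resid_w = numeric(length(ctx$win))))
  H <- stats::fft(c(h, numeric(ctx$L - ctx$n)))
  basis <- vapply(taus, function(tau) {
    E <- stats::fft(c(exp(-ctx$t0 / tau), numeric(ctx$L - ctx$n)))
    Re(stats::fft(H * E, inverse = TRUE))[seq_len(ctx$n)] / ctx$L
  }, numeric(ctx$n))
  X <- cbind(basis, 1)[ctx$win, , drop = FALSE]
  solve_lin <- function(X, w2) {
    beta <- if (nonneg) {
      Xc <- X; Xc[Xc < 0] <- 0
      nnls_clamped(Xc, ctx$y, sqrt(w2))
    } else {
      b <- tryCatch(
        as.numeric(solve(crossprod(X, X * w2), crossprod(X, ctx$y * w2))),
        error = function(e) nnls_clamped(X, ctx$y, sqrt(w2)))
      if (b[length(b)] < 0) {               # background stays >= 0
        Xr <- X[, -ncol(X), drop = FALSE]
        b <- c(tryCatch(
          as.numeric(solve(crossprod(Xr, Xr * w2),
                           crossprod(Xr, ctx$y * w2))),
          error = function(e) nnls_clamped(Xr, ctx$y, sqrt(w2))), 0)
      }
      b
    }
    beta
  }
  beta <- solve_lin(X, ctx$w^2)
  if (mle) {
    # Fisher scoring for the identity-link Poisson model: re-solve the
    # linear coefficients with weights 1/mu, which makes the inner
    # solve consistent with the deviance objective (Neyman weights are
    # biased where counts approach zero)
    for (it in 1:4) {
      mu <- pmax(as.numeric(X %*% beta), 0.3)
      beta_new <- solve_lin(X, 1 / mu)
      if (max(abs(beta_new - beta)) < 1e-8 * max(abs(beta), 1)) {
        beta <- beta_new; break
      }
      beta <- beta_new
    }
  }
  fit <- as.numeric(X %*% beta)
  resid_w <- (ctx$y - fit) * ctx$w
  ssr <- if (mle) {
    mu <- pmax(fit, 1e-9)
    2 * sum(mu - ctx$y + ifelse(ctx$y > 0, ctx$y * log(ctx$y / mu), 0))
  } else sum(resid_w^2)
  list(ssr = ssr, amplitudes = beta[seq_along(taus)],
       background = beta[length(beta)], taus = taus,
       fit = fit, resid_w = resid_w)
}

#' Fit a decay histogram by iterative reconvolution
#'
#' Multi-exponential (1-3 components) reconvolution fit with free
#' amplitudes, background, lifetimes, and a bounded IRF temporal shift
#' (+/- 5 bins).  Deterministic multi-start over dispersed log-spaced
#' lifetime sets; the best objective wins.  Components whose fitted
#' lifetimes agree within 5% are merged (amplitudes summed).
#'
#' @param decay a [decay_histogram()]
#' @param irf an [instrument_response()] on the same grid
#' @param n_components 1, 2, or 3
#' @param init optional list with elements `lifetimes` (and optionally
#'   `shift`) used as an additional start
#' @param fixed optional list; `fixed$lifetimes` pins all lifetimes (no
#'   lifetime optimization)
#' @param window optional `c(t_lo, t_hi)` (ns); default starts 0.5 ns
#'   before the IRF peak and runs to the end of the grid
#' @param n_starts number of dispersed multi-start lifetime sets
#' @param fit_shift fit the IRF shift (default TRUE)
#' @param mle use the Poisson-deviance objective instead of
#'   Neyman-weighted least squares
#' @param nonneg constrain amplitudes non-negative (default).  Set FALSE
#'   for wavelength-resolved (TRES) decays, whose red edge rises during
#'   spectral relaxation and needs negative pre-exponentials
#' @param tau_bounds optional `c(lo, hi)` bounds on every lifetime (ns)
#' @return an object of class `decay_fit_result` with elements `model`,
#'   `irf_shift`, `background`, `scale`, `reduced_chi2`, `residuals`,
#'   `converged`, `window`, `meta`
#' @export
fit_multiexp_reconvolution <- function(decay, irf, n_components = 3,
                                       init = NULL, fixed = NULL,
                                       window = NULL, n_starts = 5,
                                       fit_shift = TRUE, mle = FALSE,
                                       nonneg = TRUE, tau_bounds = NULL) {
  stopifnot(inherits(decay, "decay_histogram"),
            inherits(irf, "instrument_response"))
  if (!same_grid(decay$grid, irf$grid))
    stop("decay and IRF must share one time grid")
  if (!n_components %in% 1:3)
    stop("`n_components` must be 1, 2, or 3")
  t <- grid_times(decay$grid)
  dt <- decay$grid$dt
  if (is.null(window)) {
    t_peak <- t[which.max(irf$counts)]
    window <- c(max(t[1], t_peak - 0.5), t[length(t)])
  }
  win <- which(t >= window[1] & t <= window[2])
  if (length(win) < 2 * n_components + 3)
    stop("fit window does not overlap the grid (or is too short)")
  ctx <- make_reconv_ctx(decay, irf, win)

  span <- t[length(t)] - t[1]
  lo_tau <- if (is.null(tau_bounds)) max(dt, 1e-3) else tau_bounds[1]
  hi_tau <- if (is.null(tau_bounds)) span else tau_bounds[2]
  base <- exp(seq(log(max(2 * dt, lo_tau)), log(min(span / 3, hi_tau)),
                  length.out = n_components + 2))[2:(n_components + 1)]
  starts <- lapply(c(1, 0.4, 2.5, 0.16, 6)[seq_len(n_starts)],
                   function(f) pmin(pmax(base * f, lo_tau), hi_tau))
  if (!is.null(init) && !is.null(init$lifetimes))
    starts <- c(list(pmin(pmax(init$lifetimes, lo_tau), hi_tau)), starts)

  shift_max <- 5 * dt
  fixed_tau <- !is.null(fixed) && !is.null(fixed$lifetimes)
  if (fixed_tau) starts <- list(fixed$lifetimes)

  best <- NULL
  for (s in starts) {
    par0 <- c(if (!fixed_tau) log(s), if (fit_shift) 0)
    obj <- function(par) {
      lt <- if (fixed_tau) log(fixed$lifetimes)
            else par[seq_len(n_components)]
      sh <- if (fit_shift) par[length(par)] else 0
      reconv_eval(lt, sh, ctx, mle, nonneg)$ssr
    }
    if (length(par0) == 0) {
      res <- list(par = numeric(0), objective = obj(numeric(0)),
                  convergence = 0)
    } else {
      lower <- c(if (!fixed_tau) rep(log(lo_tau), n_components),
                 if (fit_shift) -shift_max)
      upper <- c(if (!fixed_tau) rep(log(hi_tau), n_components),
                 if (fit_shift) shift_max)
      res <- tryCatch(
        stats::nlminb(par0, obj, lower = lower, upper = upper,
                      control = list(rel.tol = 1e-8, iter.max = 300)),
        error = function(e) NULL)
      if (is.null(res)) next
    }
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) stop("all optimization starts failed")

  lt <- if (fixed_tau) log(fixed$lifetimes)
        else best$par[seq_len(n_components)]
  sh <- if (fit_shift) best$par[length(best$par)] else 0
  ev <- reconv_eval(lt, sh, ctx, mle, nonneg)

  # merge nearly degenerate lifetimes (within 5% relative); never merge
  # components of opposite sign (a rise term next to a decay term is a
  # real feature, not a degeneracy)
  taus <- ev$taus; amps <- ev$amplitudes
  o <- order(taus); taus <- taus[o]; amps <- amps[o]
  keep_t <- c(); keep_a <- c()
  for (i in seq_along(taus)) {
    k <- length(keep_t)
    if (k && taus[i] / keep_t[k] < 1.05 &&
        sign(amps[i]) * sign(keep_a[k]) >= 0) {
      keep_a[k] <- keep_a[k] + amps[i]
    } else {
      keep_t <- c(keep_t, taus[i]); keep_a <- c(keep_a, amps[i])
    }
  }
  pos <- if (nonneg) keep_a > 0 else keep_a != 0
  if (!any(pos)) { pos[which.max(keep_a + 1e-300)] <- TRUE; keep_a[pos] <- 1e-12 }
  if (max(keep_a[pos]) <= 0) keep_a[which.max(keep_a)] <- 1e-12
  model <- multiexp_model(keep_a[pos], keep_t[pos], allow_negative = !nonneg)

  npar <- 2 * sum(pos) + 1 + as.integer(fit_shift)
  converged <- is.finite(best$objective) &&
    (length(best$par) == 0 || best$convergence %in% c(0, 1))
  structure(list(model = model, irf_shift = sh,
                 background = ev$background, scale = sum(model$amplitudes),
                 reduced_chi2 = ev$ssr / max(length(win) - npar, 1),
                 residuals = ev$resid_w, converged = converged,
                 window = window, meta = decay$meta),
            class = "decay_fit_result")
}

#' Reconstruct the noise-free, IRF-free decay of a fit
#'
#' Evaluates the fitted multi-exponential law (no IRF, no background) on a
#' grid: the "deconvoluted" decay used by the TRES and quenching stages.
#'
#' @param result a converged [fit_multiexp_reconvolution()] result
#' @param grid a [time_grid()] (defaults to any grid; times are relative
#'   to the grid start)
#' @return numeric intensity vector on the grid
#' @export
reconstruct_decay <- function(result, grid) {
  stopifnot(inherits(result, "decay_fit_result"))
  if (!isTRUE(result$converged))
    stop("refusing to reconstruct from an unconverged fit; inspect the ",
         "fit (reduced_chi2 = ", signif(result$reduced_chi2, 4), ")")
  t <- grid_times(grid)
  multiexp_intensity(result$model, t - t[1])
}

#' Support-plane (NSSR) confidence profile for one parameter
#'
#' For each trial value of the pinned parameter, `objective` must return
#' the sum of squared residuals after re-optimizing all other parameters.
#' The profile records NSSR = SSR(trial) / SSR(best); the confidence
#' interval collects the region where NSSR <= cutoff, with crossing points
#' located by linear interpolation.  The default cutoff is 1.5.
#'
#' @param objective function(value) -> SSR with other parameters re-fitted
#' @param best_sse SSR of the unconstrained best fit
#' @param grid trial values spanning the best-fit value
#' @param cutoff NSSR cutoff (> 1), default 1.5
#' @param parameter name of the profiled parameter (for reporting)
#' @return an object of class `nssr_profile` with elements `parameter`,
#'   `grid`, `nssr`, `cutoff`, `interval`, `open` (logical lo/hi flags)
#' @export
support_plane_nssr <- function(objective, best_sse, grid, cutoff = 1.5,
                               parameter = "parameter") {
  if (cutoff <= 1) stop("`cutoff` must exceed 1")
  if (best_sse <= 0) stop("`best_sse` must be positive")
  nssr <- vapply(grid, function(v) objective(v) / best_sse, numeric(1))
  i_min <- which.min(nssr)
  open <- c(lo = FALSE, hi = FALSE)
  # walk left from the minimum
  lo <- grid[1]
  below <- nssr <= cutoff
  if (below[1]) {
    open["lo"] <- TRUE
  } else {
    i <- i_min
    while (i > 1 && below[i - 1]) i <- i - 1
    # crossing between i-1 and i
    lo <- grid[i - 1] + (cutoff - nssr[i - 1]) /
      (nssr[i] - nssr[i - 1]) * (grid[i] - grid[i - 1])
  }
  hi <- grid[length(grid)]
  if (below[length(grid)]) {
    open["hi"] <- TRUE
  } else {
    i <- i_min
    while (i < length(grid) && below[i + 1]) i <- i + 1
    hi <- grid[i] + (cutoff - nssr[i]) /
      (nssr[i + 1] - nssr[i]) * (grid[i + 1] - grid[i])
  }
  structure(list(parameter = parameter, grid = grid, nssr = nssr,
                 cutoff = cutoff, interval = c(lo, hi), open = open),
            class = "nssr_profile")
}
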