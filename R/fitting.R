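t2_bounds <- c(0.01, 2000) # ms; the TE grid is sensitive to roughly 5-500 ms

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Inverse-variance echo weights
#'
#' Weights compensate for echo-to-echo differences in noise level:
#' `w_i` is proportional to `1 / sigma_i^2`, normalized to mean 1. Noise
#' SDs are either given directly or estimated as the per-echo standard
#' deviation of background voxels.
#'
#' @param sigmas per-echo noise SDs (all > 0); or `NULL` to estimate from
#'   `background`.
#' @param background numeric matrix of background voxel values, one row per
#'   voxel (>= 20) and one column per echo.
#' @return Numeric weight vector with mean 1.
#' @export
estimate_weights <- function(sigmas = NULL, background = NULL) {
  if (is.null(sigmas)) {
    if (is.null(background)) {
      stop("provide either sigmas or a background region", call. = FALSE)
    }
    background <- as.matrix(background)
    if (nrow(background) < 20L) {
      stop("background region needs >= 20 voxels per echo", call. = FALSE)
    }
    sigmas <- apply(background, 2L, stats::sd)
  }
  if (any(!is.finite(sigmas)) || any(sigmas <= 0)) {
    stop("noise SDs must all be positive (constant background has zero variance)",
         call. = FALSE)
  }
  w <- 1 / sigmas^2
  w / mean(w)
}

#' Uniform echo weights
#'
#' @param n_echoes number of echoes.
#' @return Weight vector of ones.
#' @export
uniform_weights <- function(n_echoes) rep(1, n_echoes)

#' Weighted mean squared error of fit
#'
#' `sum(w_i * (obs_i - pred_i)^2) / n_echoes`.
#'
#' @param observed,predicted signal vectors of equal length.
#' @param w weight vector (same length).
#' @return Non-negative scalar.
#' @export
weighted_mse <- function(observed, predicted, w) {
  if (length(observed) != length(predicted) || length(observed) != length(w)) {
    stop("observed, predicted and weights must have equal length", call. = FALSE)
  }
  sum(w * (observed - predicted)^2) / length(observed)
}

# Objectives are built as lean closures: they run tens of thousands of
# times per volume, so bound handling is scalar clipping, not vector ops.
mono_objective <- function(curve, tes, w) {
  n <- length(curve)
  ntes <- -tes
  function(par) {
    amp <- par[1]
    if (amp < 0) amp <- 0
    t2 <- par[2]
    if (t2 < 0.01) t2 <- 0.01 else if (t2 > 2000) t2 <- 2000
    r <- curve - amp * exp(ntes / t2)
    sum(w * r * r) / n
  }
}

biexp_objective <- function(curve, tes, w) {
  n <- length(curve)
  ntes <- -tes
  function(par) {
    a1 <- par[1]
    if (a1 < 0) a1 <- 0
    a2 <- par[2]
    if (a2 < 0) a2 <- 0
    t1 <- par[3]
    if (t1 < 0.01) t1 <- 0.01 else if (t1 > 2000) t1 <- 2000
    t2 <- par[4]
    if (t2 < 0.01) t2 <- 0.01 else if (t2 > 2000) t2 <- 2000
    r <- curve - a1 * exp(ntes / t1) - a2 * exp(ntes / t2)
    sum(w * r * r) / n
  }
}

# Log-linear regression seed: fit log(S) ~ TE on the given echo subset
# (positive signals only). Returns c(amp, t2) or NULL if underdetermined.
loglin_seed <- function(curve, tes, idx) {
  keep <- idx[curve[idx] > 0]
  if (length(keep) < 2L) return(NULL)
  fit <- stats::lm.fit(cbind(1, tes[keep]), log(curve[keep]))
  slope <- fit$coefficients[2]
  amp <- exp(fit$coefficients[1])
  t2 <- if (is.finite(slope) && slope < -1e-12) -1 / slope else t2_bounds[2]
  c(max(amp, 0), clip(t2, t2_bounds[1], t2_bounds[2]))
}

# Weighted linear least squares for the two amplitudes at fixed T2 pair,
# clipped at zero — used to complete the lattice multi-starts.
amps_given_t2 <- function(curve, tes, w, t2s, t2l) {
  X <- cbind(exp(-tes / t2s), exp(-tes / t2l))
  sw <- sqrt(w)
  fit <- tryCatch(stats::lm.fit(X * sw, curve * sw),
                  error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) return(c(0.5, 0.5) * max(curve, 0))
  pmax(fit$coefficients, 0)
}

#' Weighted monoexponential fit
#'
#' Two-parameter weighted least squares: a log-linear regression on the
#' strictly positive signals seeds `(amp, t2)`, which Powell minimization
#' then refines.
#'
#' @param curve measured decay signal, one value per echo.
#' @param tes echo times (ms).
#' @param w echo weights; default uniform.
#' @return list with `params` ([mono_params()] fields), `mse`, `converged`,
#'   `degenerate` (`TRUE` for an all-zero curve).
#' @export
fit_mono <- function(curve, tes, w = uniform_weights(length(tes))) {
  validate_echo_times(tes)
  if (length(curve) != length(tes)) {
    stop("curve length must match echo count", call. = FALSE)
  }
  if (all(curve <= 0)) {
    return(list(params = list(amp = 0, t2 = NA_real_),
                mse = weighted_mse(curve, 0 * curve, w),
                converged = TRUE, degenerate = TRUE))
  }
  obj <- mono_objective(curve, tes, w)
  seed <- loglin_seed(curve, tes, seq_along(tes))
  if (is.null(seed)) seed <- c(max(curve), tes[ceiling(length(tes) / 2)])
  res <- powell_minimize(obj, seed, ftol = 1e-11, line_tol = 1e-6)
  amp <- max(res$par[1], 0)
  t2 <- clip(res$par[2], t2_bounds[1], t2_bounds[2])
  list(params = list(amp = amp, t2 = t2), mse = res$value,
       converged = res$converged, degenerate = FALSE)
}

biexp_objective_reduced <- function(curve, tes, w, amp_total) {
  n <- length(curve)
  ntes <- -tes
  function(par) {
    f <- par[1]
    if (f < 0) f <- 0 else if (f > 1) f <- 1
    t1 <- par[2]
    if (t1 < 0.01) t1 <- 0.01 else if (t1 > 2000) t1 <- 2000
    t2 <- par[3]
    if (t2 < 0.01) t2 <- 0.01 else if (t2 > 2000) t2 <- 2000
    r <- curve - amp_total * (f * exp(ntes / t1) + (1 - f) * exp(ntes / t2))
    sum(w * r * r) / n
  }
}

biexp_starts <- function(curve, tes, w) {
  starts <- list()
  # primary: two-segment log-linear split -- tail echoes estimate the long
  # component, the residual of the leading echoes estimates the short one
  n <- length(tes)
  long_seed <- loglin_seed(curve, tes, (n - 2):n)
  if (!is.null(long_seed)) {
    resid <- curve - long_seed[1] * exp(-tes / long_seed[2])
    short_seed <- loglin_seed(pmax(resid, 0), tes, 1:3)
    if (is.null(short_seed)) {
      short_seed <- c(max(curve[1] - long_seed[1], 0.1 * max(curve)),
                      long_seed[2] / 5)
    }
    starts[[1]] <- c(short_seed[1], long_seed[1],
                     min(short_seed[2], long_seed[2] * 0.8), long_seed[2])
  } else {
    starts[[1]] <- c(0.5, 0.5, 20, 100) * c(max(curve), max(curve), 1, 1)
  }
  # deterministic coarse lattice over (t2_short, t2_long)
  lattice <- list(c(10, 90), c(10, 200), c(35, 90), c(35, 200))
  for (tt in lattice) {
    a <- amps_given_t2(curve, tes, w, tt[1], tt[2])
    starts[[length(starts) + 1L]] <- c(a[1], a[2], tt[1], tt[2])
  }
  starts
}

#' Weighted biexponential fit
#'
#' Minimizes the weighted MSE over `(amp_short, amp_long, t2_short,
#' t2_long)` with Powell's conjugate-direction method; amplitudes are
#' constrained non-negative and T2 values to (0.01, 2000] ms by clipping.
#' Multi-start: a two-segment log-linear seed plus four deterministic
#' starts on a coarse (t2_short, t2_long) lattice with amplitudes from
#' weighted linear least squares; the best restart wins. Components are
#' order-normalized so `t2_short <= t2_long`.
#'
#' @inheritParams fit_mono
#' @param amp_total optional known amplitude sum. When given, the reduced
#'   3-parameter problem is solved instead: the free parameters are the
#'   short fraction and the two T2 times, with amplitudes
#'   `amp_total * (frac, 1 - frac)`. Useful when the total signal at TE = 0
#'   is known (e.g. normalized synthetic phantoms); the default (`NULL`)
#'   fits all four parameters.
#' @return list with `params` ([biexp_params()] fields), `mse`,
#'   `converged`, `n_restarts_used`.
#' @export
fit_biexp <- function(curve, tes, w = uniform_weights(length(tes)),
                      amp_total = NULL) {
  validate_echo_times(tes)
  if (length(tes) < 5L) {
    stop("biexponential fit needs >= 5 echoes (4 free parameters)",
         call. = FALSE)
  }
  if (length(curve) != length(tes)) {
    stop("curve length must match echo count", call. = FALSE)
  }
  reduced <- !is.null(amp_total)
  obj <- if (reduced) {
    biexp_objective_reduced(curve, tes, w, amp_total)
  } else {
    biexp_objective(curve, tes, w)
  }
  scale2 <- max(max(abs(curve))^2, .Machine$double.eps)
  best <- NULL
  n_used <- 0L
  starts <- biexp_starts(curve, tes, w)
  if (reduced) {
    starts <- lapply(starts, function(s) {
      total <- s[1] + s[2]
      f <- if (total > 0) s[1] / total else 0.5
      c(clip(f, 0.01, 0.99), s[3], s[4])
    })
  }
  for (start in starts) {
    n_used <- n_used + 1L
    res <- powell_minimize(obj, start, ftol = 1e-11, line_tol = 1e-6)
    if (is.null(best) || res$value < best$value) best <- res
    if (best$value < 1e-14 * scale2) break # numerically exact fit
  }
  if (reduced) {
    f <- clip(best$par[1], 0, 1)
    a1 <- amp_total * f
    a2 <- amp_total * (1 - f)
    t1 <- clip(best$par[2], t2_bounds[1], t2_bounds[2])
    t2 <- clip(best$par[3], t2_bounds[1], t2_bounds[2])
  } else {
    a1 <- max(best$par[1], 0)
    a2 <- max(best$par[2], 0)
    t1 <- clip(best$par[3], t2_bounds[1], t2_bounds[2])
    t2 <- clip(best$par[4], t2_bounds[1], t2_bounds[2])
  }
  if (t1 > t2) { # order-normalize, carrying amplitudes along
    tmp <- t1; t1 <- t2; t2 <- tmp
    tmp <- a1; a1 <- a2; a2 <- tmp
  }
  list(params = list(amp_short = a1, amp_long = a2, t2_short = t1, t2_long = t2),
       mse = best$value, converged = best$converged, n_restarts_used = n_used)
}

#' Classify a voxel as biexponential or monoexponential
#'
#' A voxel is monoexponential (degenerate biexponential fit) when ANY rule
#' fires: a relaxation-time component is (numerically) zero; the two time
#' components differ by less than 1 ms; an amplitude is (numerically) zero;
#' or the monoexponential fit has a lower weighted MSE than the
#' biexponential fit. Otherwise it is biexponential. The rules are a
#' logical OR — their order never matters.
#'
#' @param biexp result of [fit_biexp()].
#' @param mono result of [fit_mono()].
#' @param eps_t2 threshold (ms) below which a T2 component counts as zero.
#' @param eps_amp_rel fraction of the amplitude sum below which an
#'   amplitude counts as zero.
#' @return `"monoexponential"` or `"biexponential"`.
#' @export
classify_voxel <- function(biexp, mono, eps_t2 = 0.01, eps_amp_rel = 1e-6) {
  if (is.null(biexp) || is.null(mono) ||
      is.null(biexp$params) || is.null(mono$mse)) {
    stop("both fits are required for classification", call. = FALSE)
  }
  p <- biexp$params
  eps_amp <- eps_amp_rel * (p$amp_short + p$amp_long)
  mono_rules <- c(
    t2_zero = p$t2_short < eps_t2 || p$t2_long < eps_t2,
    t2_close = abs(p$t2_long - p$t2_short) < 1,
    amp_zero = p$amp_short <= eps_amp || p$amp_long <= eps_amp,
    mono_better = mono$mse < biexp$mse
  )
  if (any(mono_rules)) "monoexponential" else "biexponential"
}

#' Dense grid-search reference for the reduced biexponential problem
#'
#' Exhaustive search over a `(t2_short, t2_long, frac_short)` lattice with
#' amplitudes constrained to sum to `amp_total`. Used as an independent
#' optimality reference for the Powell-based fitter; it is deliberately
#' simple and brute-force.
#'
#' @inheritParams fit_mono
#' @param amp_total fixed amplitude sum (default 1).
#' @param t2s_grid,t2l_grid,frac_grid lattice values.
#' @return list with `params` and `mse` of the best lattice point.
#' @export
biexp_grid_search <- function(curve, tes, w = uniform_weights(length(tes)),
                              amp_total = 1,
                              t2s_grid = seq(1, 60, by = 1),
                              t2l_grid = seq(60, 300, by = 5),
                              frac_grid = seq(0.05, 0.95, by = 0.05)) {
  Es <- exp(-outer(tes, 1 / t2s_grid))   # n_echo x n_s
  El <- exp(-outer(tes, 1 / t2l_grid))   # n_echo x n_l
  best <- list(mse = Inf)
  n <- length(curve)
  for (f in frac_grid) {
    # predictions for every (t2s, t2l) pair at this fraction
    for (i in seq_along(t2s_grid)) {
      pred <- amp_total * (f * Es[, i] + (1 - f) * El) # n_echo x n_l
      mses <- colSums(w * (curve - pred)^2) / n
      j <- which.min(mses)
      if (mses[j] < best$mse) {
        best <- list(
          params = list(amp_short = amp_total * f,
                        amp_long = amp_total * (1 - f),
                        t2_short = t2s_grid[i], t2_long = t2l_grid[j]),
          mse = mses[j]
        )
      }
    }
  }
  best
}
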