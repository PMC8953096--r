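#' @keywords internal
#' Bracket a 1-D minimum by golden-ratio downhill expansion.
#' Returns (ax, bx, cx) with bx between ax and cx and f(bx) < f(ax), f(cx).
bracket_minimum <- function(f, ax = 0, bx = 1) {
  gold <- 1.618034
  glimit <- 100
  tiny <- 1e-20
  fa <- f(ax)
  fb <- f(bx)
  if (fb > fa) { # swap so we search downhill from a to b
    tmp <- ax; ax <- bx; bx <- tmp
    tmp <- fa; fa <- fb; fb <- tmp
  }
  cx <- bx + gold * (bx - ax)
  fc <- f(cx)
  while (fb > fc) {
    r <- (bx - ax) * (fb - fc)
    q <- (bx - cx) * (fb - fa)
    u <- bx - ((bx - cx) * q - (bx - ax) * r) /
      (2 * sign(q - r) * max(abs(q - r), tiny))
    ulim <- bx + glimit * (cx - bx)
    if ((bx - u) * (u - cx) > 0) {        # u between b and c: try parabolic u
      fu <- f(u)
      if (fu < fc) {
        return(list(ax = bx, bx = u, cx = cx, fb = fu))
      } else if (fu > fb) {
        return(list(ax = ax, bx = bx, cx = u, fb = fb))
      }
      u <- cx + gold * (cx - bx)
      fu <- f(u)
    } else if ((cx - u) * (u - ulim) > 0) { # u between c and the step limit
      fu <- f(u)
      if (fu < fc) {
        bx <- cx; cx <- u
        u <- cx + gold * (cx - bx)
        fb <- fc; fc <- fu; fu <- f(u)
      }
    } else if ((u - ulim) * (ulim - cx) >= 0) { # clamp to the limit
      u <- ulim
      fu <- f(u)
    } else {                               # reject u, take default golden step
      u <- cx + gold * (cx - bx)
      fu <- f(u)
    }
    ax <- bx; bx <- cx; cx <- u
    fa <- fb; fb <- fc; fc <- fu
  }
  list(ax = ax, bx = bx, cx = cx, fb = fb)
}

#' @keywords internal
#' Brent parabolic-interpolation line search on a bracketed minimum.
brent_minimize <- function(f, ax, bx, cx, tol = 1e-8, itmax = 100L) {
  cgold <- 0.381966
  zeps <- 1e-12
  a <- min(ax, cx)
  b <- max(ax, cx)
  v <- w <- x <- bx
  fv <- fw <- fx <- f(x)
  e <- 0
  d <- 0
  for (iter in seq_len(itmax)) {
    xm <- 0.5 * (a + b)
    tol1 <- tol * abs(x) + zeps
    tol2 <- 2 * tol1
    if (abs(x - xm) <= tol2 - 0.5 * (b - a)) break
    use_golden <- TRUE
    if (abs(e) > tol1) {
      r <- (x - w) * (fx - fv)
      q <- (x - v) * (fx - fw)
      p <- (x - v) * q - (x - w) * r
      q <- 2 * (q - r)
      if (q > 0) p <- -p
      q <- abs(q)
      etemp <- e
      e <- d
      if (abs(p) < abs(0.5 * q * etemp) && p > q * (a - x) && p < q * (b - x)) {
        d <- p / q
        u <- x + d
        if (u - a < tol2 || b - u < tol2) d <- tol1 * sign(xm - x)
        use_golden <- FALSE
      }
    }
    if (use_golden) {
      e <- if (x >= xm) a - x else b - x
      d <- cgold * e
    }
    u <- if (abs(d) >= tol1) x + d else x + tol1 * sign(d)
    fu <- f(u)
    if (fu <= fx) {
      if (u >= x) a <- x else b <- x
      v <- w; fv <- fw
      w <- x; fw <- fx
      x <- u; fx <- fu
    } else {
      if (u < x) a <- u else b <- u
      if (fu <= fw || w == x) {
        v <- w; fv <- fw
        w <- u; fw <- fu
      } else if (fu <= fv || v == x || v == w) {
        v <- u; fv <- fu
      }
    }
  }
  list(xmin = x, fmin = fx)
}

#' @keywords internal
#' Minimize fn along direction d from point p: bracket then Brent.
line_minimize <- function(fn, p, fp, d, tol = 1e-8) {
  g <- function(t) fn(p + t * d)
  br <- bracket_minimum(g, 0, 1)
  res <- brent_minimize(g, br$ax, br$bx, br$cx, tol = tol)
  if (res$fmin >= fp) {
    return(list(p = p, f = fp, t = 0))
  }
  list(p = p + res$xmin * d, f = res$fmin, t = res$xmin)
}

#' Powell's conjugate-direction minimization
#'
#' Derivative-free minimizer: starting from the coordinate axes, each cycle
#' line-minimizes along every direction in the set (golden-section
#' bracketing followed by Brent parabolic interpolation), then applies
#' Powell's update rule — if the extrapolated point along the cycle's net
#' displacement improves on the cycle start, that displacement replaces the
#' direction of largest single decrease. Stops when a cycle's fractional
#' function decrease falls below `ftol`, the parameter change falls below
#' `xtol`, or `max_cycles` is reached.
#'
#' @param fn objective, a function of a numeric vector; must be finite at
#'   `x0`.
#' @param x0 numeric start vector.
#' @param xtol absolute parameter-change tolerance (max-norm per cycle).
#' @param ftol fractional function-decrease tolerance per cycle.
#' @param max_cycles maximum number of direction-set cycles.
#' @param line_tol relative tolerance of each Brent line search.
#' @return list with `par` (argmin), `value` (fmin), `converged` (logical),
#'   `cycles` (cycles used).
#' @export
powell_minimize <- function(fn, x0, xtol = 1e-8, ftol = 1e-12,
                            max_cycles = 200L, line_tol = 1e-8) {
  x0 <- as.numeric(x0)
  n <- length(x0)
  fp <- fn(x0)
  if (!is.finite(fp)) {
    stop("objective is not finite at the starting point", call. = FALSE)
  }
  dirs <- diag(n)
  p <- x0
  tiny <- 1e-25
  converged <- FALSE
  cycles <- 0L
  for (cycle in seq_len(max_cycles)) {
    cycles <- cycle
    f0 <- fp
    p0 <- p
    del <- 0
    ibig <- 1L
    for (i in seq_len(n)) {
      res <- line_minimize(fn, p, fp, dirs[, i], tol = line_tol)
      if (fp - res$f > del) {
        del <- fp - res$f
        ibig <- i
      }
      p <- res$p
      fp <- res$f
    }
    if (2 * (f0 - fp) <= ftol * (abs(f0) + abs(fp)) + tiny ||
        max(abs(p - p0)) <= xtol) {
      converged <- TRUE
      break
    }
    dvec <- p - p0
    pe <- 2 * p - p0
    fe <- fn(pe)
    if (fe < f0) {
      t <- 2 * (f0 - 2 * fp + fe) * (f0 - fp - del)^2 - del * (f0 - fe)^2
      if (t < 0) {
        res <- line_minimize(fn, p, fp, dvec, tol = line_tol)
        p <- res$p
        fp <- res$f
        dirs[, ibig] <- dirs[, n]
        dirs[, n] <- dvec
      }
    }
  }
  list(par = p, value = fp, converged = converged, cycles = cycles)
}
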