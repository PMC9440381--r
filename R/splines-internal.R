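# Cubic B-spline basis with linear extrapolation beyond the boundary knots.
#
# A basis definition is the full knot vector (boundary knots replicated 4
# times) for a cubic (order 4) B-spline. With `df` coefficients the basis
# has df - 3 interior knots placed at quantiles of the training values and
# the leading basis column dropped (its role is absorbed by the node
# intercept), leaving exactly `df` columns.

spline_knots <- function(x, df) {
  lo <- min(x); hi <- max(x)
  if (hi - lo < 1e-12) stop("degenerate (constant) parent values", call. = FALSE)
  n_int <- df - 3L
  interior <- stats::quantile(x, probs = seq_len(n_int) / (n_int + 1),
                              names = FALSE, type = 7)
  # keep interior knots strictly inside the boundary
  eps <- (hi - lo) * 1e-6
  interior <- pmin(pmax(interior, lo + eps), hi - eps)
  interior <- sort(interior)
  c(rep(lo, 4L), interior, rep(hi, 4L))
}

# Evaluate the (dropped-first-column) basis at arbitrary x. Inside the
# boundary the basis is the standard B-spline design; outside it continues
# linearly with the boundary value and first derivative.
spline_basis <- function(knots, x) {
  K <- length(knots) - 4L           # number of raw basis functions
  lo <- knots[4L]; hi <- knots[length(knots) - 3L]
  B <- matrix(0, length(x), K)
  inside <- x >= lo & x <= hi
  if (any(inside)) {
    B[inside, ] <- splines::splineDesign(knots, x[inside], ord = 4L)
  }
  if (any(!inside)) {
    lo_side <- !inside & x < lo
    hi_side <- !inside & x > hi
    if (any(lo_side)) {
      b0 <- splines::splineDesign(knots, lo, ord = 4L)
      b1 <- splines::splineDesign(knots, lo, ord = 4L, derivs = 1L)
      B[lo_side, ] <- rep(1, sum(lo_side)) %o% drop(b0) +
        (x[lo_side] - lo) %o% drop(b1)
    }
    if (any(hi_side)) {
      b0 <- splines::splineDesign(knots, hi, ord = 4L)
      b1 <- splines::splineDesign(knots, hi, ord = 4L, derivs = 1L)
      B[hi_side, ] <- rep(1, sum(hi_side)) %o% drop(b0) +
        (x[hi_side] - hi) %o% drop(b1)
    }
  }
  B[, -1L, drop = FALSE]
}

# Least squares on [1, B1, ..., Bm]; ridge-stabilized if rank deficient.
# Returns intercept, per-block coefficients, fitted values and RSS.
ls_fit_blocks <- function(y, blocks, warn_ridge = FALSE) {
  n <- length(y)
  X <- cbind(rep(1, n), do.call(cbind, blocks))
  p <- ncol(X)
  fit <- stats::.lm.fit(X, y)
  if (fit$rank < p) {
    if (warn_ridge) warning("ill-conditioned basis: ridge-stabilized fit", call. = FALSE)
    XtX <- crossprod(X)
    lam <- 1e-8 * mean(diag(XtX))
    beta <- solve(XtX + diag(lam, p), crossprod(X, y))
    beta <- drop(beta)
  } else {
    beta <- fit$coefficients
  }
  fitted <- drop(X %*% beta)
  sizes <- vapply(blocks, ncol, 0L)
  splits <- split(beta[-1L], rep(seq_along(blocks), sizes))
  list(intercept = beta[1L], coef = splits, fitted = fitted,
       rss = sum((y - fitted)^2))
}
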