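#' Negative binomial log pmf (mean/dispersion parametrization)
#'
#' Log probability mass of the negative binomial with mean `mean` and
#' quadratic-overdispersion coefficient `dispersion`, so that
#' `Var(X) = mean + dispersion * mean^2`. At `dispersion = 0` this is the
#' Poisson log pmf.
#'
#' @param x non-negative integer counts.
#' @param mean positive expected value(s).
#' @param dispersion non-negative dispersion(s).
#' @return numeric vector of log probabilities.
#' @export
nb_log_pmf <- function(x, mean, dispersion) {
  if (any(!is.finite(x)) || any(!is.finite(mean)) || any(!is.finite(dispersion)))
    stop("non-finite inputs to nb_log_pmf")
  if (any(x < 0)) stop("negative counts")
  if (any(mean <= 0)) stop("mean must be positive")
  if (any(dispersion < 0)) stop("dispersion must be >= 0")
  n <- max(length(x), length(mean), length(dispersion))
  x <- rep_len(x, n); mean <- rep_len(mean, n); dispersion <- rep_len(dispersion, n)
  out <- numeric(n)
  pois <- dispersion < 1e-10
  if (any(pois)) out[pois] <- stats::dpois(x[pois], mean[pois], log = TRUE)
  if (any(!pois))
    out[!pois] <- stats::dnbinom(x[!pois], size = 1 / dispersion[!pois],
                                 mu = mean[!pois], log = TRUE)
  out
}

# d/d(log mean) of the NB log pmf at fixed dispersion:
# x - mean * (x + r) / (r + mean), r = 1/dispersion (Poisson limit: x - mean)
nb_dll_dlogmean <- function(x, mean, dispersion) {
  r <- 1 / pmax(dispersion, 1e-12)
  x - mean * (x + r) / (r + mean)
}

#' Expected log proportion under the sinusoidal mean model
#'
#' The gene's expected log transcript proportion at cell phase `theta`:
#' `mesor + cycling * amplitude * cos(theta - acrophase)`. The expected count
#' is the cell library size times the exponential of this value.
#'
#' @param theta cell phase(s), radians.
#' @param mesor mean log proportion over the cycle.
#' @param amplitude maximum log deviation from the mesor (>= 0).
#' @param acrophase phase of peak expression, radians.
#' @param cycling 0/1 indicator (or probability) that the gene oscillates.
#' @return numeric log proportion(s).
#' @export
expected_log_proportion <- function(theta, mesor, amplitude, acrophase, cycling = 1) {
  mesor + cycling * amplitude * cos(theta - acrophase)
}

#' Fit the mean-dispersion trend
#'
#' Estimates, for each sufficiently expressed gene, the maximum-likelihood NB
#' dispersion with per-cell means `lib_size * pseudobulk proportion` (phase
#' structure ignored), then least-squares fits a polynomial of log dispersion
#' on log proportion. Evaluation outside the fitted proportion range clamps to
#' the range endpoints. With `degree = 0` the trend is a single constant equal
#' to the pooled method-of-moments dispersion.
#'
#' @param cm a [phase_counts] object.
#' @param degree polynomial degree (default 2).
#' @param proportion_floor smallest pseudobulk proportion used in the fit.
#' @return an object of class `"dispersion_trend"` with coefficients `zeta`,
#'   the trusted `lambda_range`, and `lambda_floor`.
#' @export
fit_dispersion_trend <- function(cm, degree = 2, proportion_floor = 1e-5) {
  props <- pseudobulk_proportions(cm)
  keep <- which(props > proportion_floor)
  if (degree == 0) {
    # pooled method of moments: sum((x - m)^2 - m) / sum(m^2)
    m <- outer(cm$lib_sizes, props[keep])
    x <- cm$counts[, keep, drop = FALSE]
    delta <- max(sum((x - m)^2 - m) / sum(m^2), 1e-6)
    return(structure(list(zeta = log(delta), degree = 0,
                          lambda_range = range(props[keep]),
                          lambda_floor = proportion_floor),
                     class = "dispersion_trend"))
  }
  if (length(keep) < 50) stop("fewer than 50 genes pass the proportion floor")
  if (length(keep) < degree + 2) stop("too few usable genes for the requested degree")
  L <- cm$lib_sizes
  disp <- vapply(keep, function(j) {
    x <- cm$counts[, j]
    m <- L * props[j]
    nll <- function(logd) -sum(nb_log_pmf(x, m, exp(logd)))
    exp(stats::optimize(nll, c(-12, 3))$minimum)
  }, numeric(1))
  disp <- pmax(disp, 1e-6)
  ll <- log(props[keep])
  X <- stats::poly(ll, degree, raw = TRUE)
  fit <- stats::lm.fit(cbind(1, X), log(disp))
  structure(list(zeta = unname(fit$coefficients), degree = degree,
                 lambda_range = range(props[keep]),
                 lambda_floor = proportion_floor),
            class = "dispersion_trend")
}

#' Evaluate the dispersion trend
#'
#' @param object a `"dispersion_trend"` fit.
#' @param lambda transcript proportions at which to evaluate; clamped to the
#'   fitted range.
#' @param ... unused.
#' @return positive dispersions.
#' @export
predict.dispersion_trend <- function(object, lambda, ...) {
  lam <- pmin(pmax(lambda, object$lambda_range[1]), object$lambda_range[2])
  if (object$degree == 0) {
    out <- rep_len(exp(object$zeta), length(lam))
  } else {
    ll <- log(lam)
    logd <- object$zeta[1]
    for (d in seq_len(object$degree)) logd <- logd + object$zeta[d + 1] * ll^d
    out <- exp(logd)
  }
  dim(out) <- dim(lambda)
  out
}

#' @export
print.dispersion_trend <- function(x, ...) {
  cat(sprintf("dispersion trend: degree %d over lambda in [%.2g, %.2g]\n",
              x$degree, x$lambda_range[1], x$lambda_range[2]))
  invisible(x)
}

#' Constant dispersion model
#'
#' Convenience constructor for a flat mean-dispersion relationship, mainly for
#' simulation configs and tests.
#'
#' @param delta the dispersion value (>= 0).
#' @param lambda_range trusted proportion range.
#' @return a `"dispersion_trend"` object.
#' @export
constant_dispersion <- function(delta, lambda_range = c(1e-8, 1)) {
  structure(list(zeta = log(max(delta, 1e-12)), degree = 0,
                 lambda_range = lambda_range, lambda_floor = lambda_range[1]),
            class = "dispersion_trend")
}
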