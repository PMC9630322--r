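#' Von Mises density
#'
#' Density of the von Mises distribution, the circular analogue of the normal
#' distribution, parameterized by a location (radians) and a concentration
#' (inverse-variance-like; 0 gives the circular uniform).
#'
#' @param x numeric vector of angles (radians).
#' @param loc location parameter (radians).
#' @param conc concentration parameter (>= 0).
#' @param log logical; return log density?
#' @return numeric vector of (log) densities.
#' @export
dvonmises <- function(x, loc = 0, conc = 1, log = FALSE) {
  stopifnot(all(is.finite(conc)), all(conc >= 0))
  # exponentially scaled Bessel keeps large concentrations finite:
  # log I0(k) = log(besselI(k, 0, TRUE)) + k
  ld <- conc * (cos(x - loc) - 1) - log(2 * pi) - log(besselI(conc, 0, expon.scaled = TRUE))
  if (log) ld else exp(ld)
}

# mean resultant length A(k) = I1(k)/I0(k)
vm_A <- function(conc) {
  ifelse(conc == 0, 0,
         besselI(conc, 1, expon.scaled = TRUE) / besselI(conc, 0, expon.scaled = TRUE))
}

# entropy of von Mises: log(2 pi I0(k)) - k I1(k)/I0(k)
vm_entropy <- function(conc) {
  log(2 * pi) + log(besselI(conc, 0, expon.scaled = TRUE)) + conc - conc * vm_A(conc)
}

# dH/dk = -k A'(k) with A'(k) = 1 - A/k - A^2
vm_entropy_grad <- function(conc) {
  A <- vm_A(conc)
  dA <- ifelse(conc == 0, 0.5, 1 - A / conc - A^2)
  -conc * dA
}

#' Exact von Mises sampling
#'
#' Draws from a von Mises distribution by the Best-Fisher rejection algorithm
#' (exact; used where no pathwise gradient is needed).
#'
#' @inheritParams dvonmises
#' @param n number of draws; `loc` and `conc` are recycled to length `n`.
#' @return numeric vector of angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, loc = 0, conc = 1) {
  loc <- rep_len(loc, n)
  conc <- rep_len(conc, n)
  out <- numeric(n)
  unif <- conc < 1e-8
  out[unif] <- stats::runif(sum(unif), 0, 2 * pi)
  todo <- which(!unif)
  if (length(todo)) {
    k <- conc[todo]
    tau <- 1 + sqrt(1 + 4 * k^2)
    rho <- (tau - sqrt(2 * tau)) / (2 * k)
    rr <- (1 + rho^2) / (2 * rho)
    res <- rep(NA_real_, length(todo))
    idx <- seq_along(todo)
    while (length(idx)) {
      u1 <- stats::runif(length(idx))
      z <- cos(pi * u1)
      f <- (1 + rr[idx] * z) / (rr[idx] + z)
      ccs <- k[idx] * (rr[idx] - f)
      u2 <- stats::runif(length(idx))
      ok <- (ccs * (2 - ccs) - u2 > 0) | (log(ccs / u2) + 1 - ccs >= 0)
      if (any(ok)) {
        u3 <- stats::runif(sum(ok))
        res[idx[ok]] <- sign(u3 - 0.5) * acos(f[ok])
        idx <- idx[!ok]
      }
    }
    out[todo] <- res + loc[todo]
  }
  out[!unif] <- out[!unif] %% (2 * pi)
  out[unif] <- out[unif] %% (2 * pi)
  out
}

# Reparameterized deviates from VM(0, conc) with pathwise d(delta)/d(conc).
#
# Inverse-CDF transform of u ~ Uniform(0,1) on a fixed grid over (-pi, pi),
# with the concentration gradient obtained by implicit differentiation:
#   d delta / d conc = -(dF/dconc)(delta) / f(delta).
# For conc > 10 a resultant-matched wrapped-normal branch is used
# (sigma^2 = -2 log A(k)); the two branches agree closely at the switch point.
vm_sample_reparam <- function(conc, u, grid_n = 256) {
  n <- length(conc)
  stopifnot(length(u) == n)
  delta <- numeric(n)
  dd <- numeric(n)
  hi <- conc > 10
  if (any(hi)) {
    k <- conc[hi]
    A <- vm_A(k)
    dA <- 1 - A / k - A^2
    s2 <- -2 * log(A)
    z <- stats::qnorm(u[hi])
    delta[hi] <- z * sqrt(s2)
    # d delta / dk = delta * (d s2/dk) / (2 s2), with d s2/dk = -2 A'/A
    dd[hi] <- -delta[hi] * dA / (A * s2)
  }
  lo <- !hi & conc <= 2
  mid <- !hi & conc > 2
  # diffuse distributions need far fewer grid points
  if (any(lo)) {
    r <- vm_grid_invcdf(conc[lo], u[lo], 96L)
    delta[lo] <- r$delta; dd[lo] <- r$dd
  }
  if (any(mid)) {
    r <- vm_grid_invcdf(conc[mid], u[mid], grid_n)
    delta[mid] <- r$delta; dd[mid] <- r$dd
  }
  list(delta = delta, ddelta_dconc = dd)
}

vm_grid_invcdf <- function(k, uu, grid_n) {
  m <- length(k)
  gp <- grid_n + 1L
  tg <- seq(-pi, pi, length.out = gp)
  dt <- tg[2] - tg[1]
  # unnormalized scaled density, grid points as rows: exp(k (cos t - 1))
  f <- exp((cos(tg) - 1) %o% k)                    # gp x m
  Fc <- matrix(0, gp, m)
  Fc[-1, ] <- colcumsum((f[-1, , drop = FALSE] +
                           f[-gp, , drop = FALSE]) * (dt / 2))
  tot <- Fc[gp, ]
  Fn <- Fc * rep(1 / tot, each = gp)
  # last grid index with F < u, in 1..grid_n
  idx <- colSums(Fn < rep(uu, each = gp))
  idx <- pmin(pmax(idx, 1L), grid_n)
  at0 <- cbind(idx, seq_len(m)); at1 <- cbind(idx + 1L, seq_len(m))
  # invert the linear CDF interpolant on the bracketing cell
  frac <- (uu - Fn[at0]) / pmax(Fn[at1] - Fn[at0], 1e-300)
  d <- tg[idx] + frac * dt
  fd <- (f[at0] + frac * (f[at1] - f[at0])) / tot
  # dF/dconc (x) = int_{-pi}^{x} f(t) (cos t - A(k)) dt for the normalized f
  g <- f * (cos(tg) - rep(vm_A(k), each = gp))
  Gc <- matrix(0, gp, m)
  Gc[-1, ] <- colcumsum((g[-1, , drop = FALSE] +
                           g[-gp, , drop = FALSE]) * (dt / 2))
  gd <- (Gc[at0] + (d - tg[idx]) * g[at0]) / tot
  list(delta = d, dd = -gd / pmax(fd, 1e-300))
}

# column-wise cumulative sums via one cumsum over the flattened matrix with
# per-column offset correction (no loops)
colcumsum <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  V <- matrix(cumsum(M), nr, nc)
  if (nc > 1) V <- V - rep(c(0, V[nr, -nc]), each = nr)
  V
}

#' Circular mean
#'
#' Mean direction of a set of angles. For a (near-)zero resultant vector the
#' mean is undefined; the first angle is returned and flagged via the
#' `"tie"` attribute.
#'
#' @param x angles in radians.
#' @param w optional non-negative weights.
#' @return angle in `[0, 2*pi)`, with attribute `tie` (logical).
#' @export
circular_mean <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  S <- sum(w * sin(x)); C <- sum(w * cos(x))
  R <- sqrt(S^2 + C^2) / sum(w)
  if (R < 1e-10) {
    out <- x[1] %% (2 * pi)
    attr(out, "tie") <- TRUE
    return(out)
  }
  out <- atan2(S, C) %% (2 * pi)
  attr(out, "tie") <- FALSE
  out
}

# concentration whose central interval of half-width `half` (radians) holds
# `level` probability mass
vm_conc_for_interval <- function(half, level = 0.95) {
  stopifnot(half > 0, half < pi, level > 0, level < 1)
  mass <- function(k) {
    stats::integrate(function(t) dvonmises(t, 0, k), -half, half,
                     rel.tol = 1e-10)$value
  }
  stats::uniroot(function(k) mass(k) - level, c(1e-6, 5000), tol = 1e-8)$root
}

# Highest-density-region arcs for a circular density evaluated on an
# equally spaced grid. Returns a matrix of arcs (start, end) in radians,
# chosen as the smallest set of grid cells whose mass >= level.
hdr_arcs_from_grid <- function(grid, dens, level) {
  stopifnot(level > 0, level < 1, length(grid) == length(dens))
  n <- length(grid)
  step <- grid[2] - grid[1]
  mass <- dens * step
  mass <- mass / sum(mass)
  ord <- order(dens, decreasing = TRUE)
  csum <- cumsum(mass[ord])
  m <- which(csum >= level)[1]
  sel <- sort(ord[seq_len(m)])
  # contiguous runs on the circle; arcs are (start, end) with end = start + len,
  # end may exceed 2*pi to denote wrapping
  inset <- logical(n); inset[sel] <- TRUE
  prev <- inset[c(n, seq_len(n - 1L))]
  starts <- which(inset & !prev)
  if (length(starts) == 0L) {           # whole circle selected
    return(matrix(c(0, 2 * pi), 1, dimnames = list(NULL, c("start", "end"))))
  }
  arcs <- t(vapply(starts, function(b) {
    l <- 1L
    while (l < n && inset[(b + l - 1L) %% n + 1L]) l <- l + 1L
    s <- (grid[b] - step / 2) %% (2 * pi)
    c(start = s, end = s + l * step)
  }, numeric(2)))
  colnames(arcs) <- c("start", "end")
  arcs
}

# is angle x inside any arc of an arcs matrix (start in [0,2pi), end = start+len)
in_arcs <- function(x, arcs) {
  x <- x %% (2 * pi)
  any((x - arcs[, "start"]) %% (2 * pi) <= (arcs[, "end"] - arcs[, "start"]) + 1e-12)
}

arcs_total_length <- function(arcs) sum(arcs[, "end"] - arcs[, "start"])
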