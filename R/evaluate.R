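# Evaluation statistics: alignment, errors, calibration, stability,
# held-out clock likelihood, enrichment, and the PCA-angle baseline.

#' Optimal global shift aligning phase estimates to truth
#'
#' Methods without an absolute phase reference estimate phases up to a global
#' rotation (and, for projection methods, a reflection). This finds, by grid
#' search at 1-minute resolution, the shift `s` minimizing the total circular
#' error `sum_i arccos(cos(est_i - s - truth_i))`, optionally also trying the
#' reflected estimates `-est` and returning whichever is better.
#'
#' @param estimates,truths phase vectors (radians), equal length.
#' @param reflect also consider the reflected estimates (default TRUE).
#' @return list with `shift` (radians), `reflected` (logical), `shifted`
#'   (aligned estimates in `[0, 2*pi)`), `total_error`.
#' @export
optimal_shift <- function(estimates, truths, reflect = TRUE) {
  if (length(estimates) != length(truths)) stop("length mismatch")
  if (length(estimates) < 1) stop("empty input")
  grid <- seq(0, 2 * pi, length.out = 24 * 60 + 1)[-(24 * 60 + 1)]
  best <- function(est) {
    d <- outer(est - truths, grid, "-")
    tot <- colSums(acos(pmin(pmax(cos(d), -1), 1)))
    k <- which.min(tot)
    list(shift = grid[k], total = tot[k])
  }
  fwd <- best(estimates)
  out <- list(shift = fwd$shift, reflected = FALSE,
              shifted = (estimates - fwd$shift) %% (2 * pi),
              total_error = fwd$total)
  if (reflect) {
    rev <- best(-estimates)
    if (rev$total < fwd$total)
      out <- list(shift = rev$shift, reflected = TRUE,
                  shifted = (-estimates - rev$shift) %% (2 * pi),
                  total_error = rev$total)
  }
  out
}

#' Circular phase error in hours
#'
#' `12/pi * arccos(cos(truth - estimate))`: the shortest distance around the
#' 24 h circle, in `[0, 12]` hours.
#'
#' @param truth,estimate phases in radians.
#' @return numeric error(s) in hours.
#' @export
phase_error_hours <- function(truth, estimate) {
  12 / pi * acos(pmin(pmax(cos(truth - estimate), -1), 1))
}

#' Empirical CDF of phase errors
#'
#' @param errors phase errors in `[0, 12]` hours.
#' @return data.frame `(hour, fraction)` giving the right-continuous eCDF at
#'   each distinct error value, with an `ecdf` function attribute.
#' @export
error_ecdf <- function(errors) {
  if (length(errors) == 0) stop("empty input")
  if (any(errors < 0 | errors > 12)) stop("errors must be in [0, 12] hours")
  fn <- stats::ecdf(errors)
  hour <- sort(unique(errors))
  out <- data.frame(hour = hour, fraction = fn(hour))
  attr(out, "ecdf") <- fn
  out
}

#' Coverage calibration of HDR credible intervals
#'
#' For each requested credible level, the fraction of cells whose true phase
#' lies inside the HDR arc set of the fitted phase posterior.
#'
#' @param fit a `"cyclophase"` fit (or `"vi_state"`).
#' @param truths true cell phases (radians).
#' @param levels credible levels; defaults to the fit's levels (or
#'   `c(0.5, 0.8, 0.95)` for a bare state).
#' @return data.frame `(confidence, coverage)`.
#' @export
calibration_curve <- function(fit, truths, levels = NULL) {
  if (inherits(fit, "cyclophase")) {
    if (is.null(levels)) levels <- fit$credible_levels
    state <- fit$state
  } else {
    state <- fit
    if (is.null(levels)) levels <- c(0.5, 0.8, 0.95)
  }
  n <- length(state$cell_loc)
  stopifnot(length(truths) == n)
  cov <- vapply(levels, function(lv) {
    if (lv <= 0) return(0)
    hits <- vapply(seq_len(n), function(i)
      in_arcs(truths[i], hdr_interval(state, i, lv)), logical(1))
    mean(hits)
  }, numeric(1))
  data.frame(confidence = levels, coverage = cov)
}

#' Run-to-run stability of phase estimates
#'
#' For each cell, the mean absolute circular deviation (in hours) of repeated
#' runs' estimates from their circular mean:
#' `12/pi * mean_k arccos(cos(est_ik - circmean_i))`. For antipodal ties the
#' circular mean falls back to the first run's estimate (deterministic,
#' flagged).
#'
#' @param run_matrix cells x runs matrix of phase estimates (radians).
#' @return numeric vector of per-cell stability values (hours), with
#'   attribute `ties` (logical per cell).
#' @export
phase_stability <- function(run_matrix) {
  run_matrix <- as.matrix(run_matrix)
  if (ncol(run_matrix) < 2) stop("at least 2 runs per cell required")
  n <- nrow(run_matrix)
  ties <- logical(n)
  out <- vapply(seq_len(n), function(i) {
    cm <- circular_mean(run_matrix[i, ])
    ties[i] <<- isTRUE(attr(cm, "tie"))
    mean(phase_error_hours(run_matrix[i, ], as.numeric(cm)))
  }, numeric(1))
  attr(out, "ties") <- ties
  out
}

#' Held-out clock-gene likelihood, standardized against a random-phase null
#'
#' Fits, per clock gene, the Poisson log-linear model
#' `log lambda = mu + A cos(phase - phi)` (via the linear reparametrization
#' `a cos(phase) + b sin(phase)` with library-size offset) on training cells
#' using a method's training phase estimates, then evaluates the Poisson log
#' likelihood of test-cell clock counts at the method's test phase estimates.
#' The score is standardized against a null distribution of the same
#' quantity under uniform-random phases: `(loglik - median(null)) / sd(null)`.
#'
#' @param train,test disjoint [phase_counts] objects.
#' @param clock_genes genes present in both.
#' @param train_phases,test_phases the method's phase estimates (radians).
#' @param n_null null replicates (default 50).
#' @param seed seed for the null draws.
#' @return list with `score`, `loglik`, `null_logliks`, and the per-gene
#'   training coefficients `coef` (mesor, amplitude, acrophase).
#' @export
holdout_clock_likelihood <- function(train, test, clock_genes,
                                     train_phases, test_phases,
                                     n_null = 50, seed = 1) {
  missing <- setdiff(clock_genes, intersect(train$gene_ids, test$gene_ids))
  if (length(missing))
    stop("clock gene(s) missing from a split: ", paste(missing, collapse = ", "))
  stopifnot(length(train_phases) == nrow(train$counts),
            length(test_phases) == nrow(test$counts))
  fit_eval <- function(trp, tep) {
    cf <- clock_glm_fit(train, clock_genes, trp)
    list(coef = cf, loglik = clock_poisson_loglik(test, clock_genes, tep, cf))
  }
  obs <- fit_eval(train_phases, test_phases)
  set.seed(seed)
  null <- vapply(seq_len(n_null), function(b) {
    trp <- stats::runif(nrow(train$counts), 0, 2 * pi)
    tep <- stats::runif(nrow(test$counts), 0, 2 * pi)
    fit_eval(trp, tep)$loglik
  }, numeric(1))
  list(score = (obs$loglik - stats::median(null)) / stats::sd(null),
       loglik = obs$loglik, null_logliks = null, coef = obs$coef)
}

# per-gene Poisson GLM with offset log(L): log lam = mu + a cos + b sin
clock_glm_fit <- function(cm, clock_genes, phases) {
  sub <- subset_genes(cm, clock_genes)
  co <- cos(phases); si <- sin(phases)
  off <- log(sub$lib_sizes)
  t(vapply(seq_along(clock_genes), function(j) {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, co, si), sub$counts[, j],
                     family = stats::poisson(), offset = off))
    b <- unname(fit$coefficients)
    c(mesor = b[1], amplitude = sqrt(b[2]^2 + b[3]^2),
      acrophase = atan2(b[3], b[2]) %% (2 * pi))
  }, c(mesor = 0, amplitude = 0, acrophase = 0)))
}

clock_poisson_loglik <- function(cm, clock_genes, phases, cf) {
  sub <- subset_genes(cm, clock_genes)
  n <- length(phases)
  loglam <- matrix(cf[, "mesor"], n, length(clock_genes), byrow = TRUE) +
    (cos(phases) %o% cos(cf[, "acrophase"]) + sin(phases) %o% sin(cf[, "acrophase"])) *
    rep(cf[, "amplitude"], each = n)
  mu <- sub$lib_sizes * exp(loglam)
  sum(stats::dpois(sub$counts, mu, log = TRUE))
}

#' Empirical gene-set enrichment test
#'
#' Tests whether an observed gene set (e.g. de novo cyclers) overlaps a
#' target set more than random sets of the same size drawn from the universe:
#' `p = (1 + #(null overlaps >= observed)) / (n_null + 1)`.
#'
#' @param de_novo observed gene set (subset of `universe`).
#' @param target target gene set (subset of `universe`).
#' @param universe all candidate genes.
#' @param n_null random sets (default 1000).
#' @param seed integer seed.
#' @return list with `p`, `observed_overlap`, `null_overlaps`.
#' @export
enrichment_test <- function(de_novo, target, universe, n_null = 1000, seed = 1) {
  if (length(de_novo) == 0 || length(target) == 0) stop("empty gene set")
  if (!all(de_novo %in% universe) || !all(target %in% universe))
    stop("sets must be subsets of the universe")
  obs <- length(intersect(de_novo, target))
  set.seed(seed)
  k <- length(de_novo)
  null <- vapply(seq_len(n_null), function(b)
    length(intersect(sample(universe, k), target)), numeric(1))
  list(p = (1 + sum(null >= obs)) / (n_null + 1),
       observed_overlap = obs, null_overlaps = null)
}

#' PCA-angle baseline phase estimates
#'
#' Deterministic baseline: z-scores the log1p library-size-normalized counts
#' of a gene subset, takes the top two principal components, and assigns each
#' cell the angle `atan2(PC2, PC1)`. Each component's sign is oriented so its
#' largest-magnitude loading is positive, making the output reproducible.
#' Phases are arbitrary up to rotation/reflection; align with
#' [optimal_shift] before computing errors.
#'
#' @param cm a [phase_counts] object.
#' @param gene_subset at least 2 genes.
#' @param scale_factor library-size normalization target (counts per
#'   `scale_factor` total).
#' @return per-cell angles in `[0, 2*pi)`.
#' @export
pca_phase_baseline <- function(cm, gene_subset, scale_factor = 1e4) {
  if (length(gene_subset) < 2) stop("at least 2 genes required")
  sub <- subset_genes(cm, gene_subset)
  y <- log1p(sub$counts / sub$lib_sizes * scale_factor)
  y <- scale(y)
  y[, attr(y, "scaled:scale") == 0 | !is.finite(colSums(y))] <- 0
  pc <- stats::prcomp(y, center = FALSE, scale. = FALSE, rank. = 2)
  if (ncol(pc$rotation) < 2) stop("rank-deficient input: fewer than 2 components")
  if (pc$sdev[2] < 1e-12) stop("rank-deficient input")
  rot <- pc$rotation
  for (k in 1:2) {
    l <- rot[, k]
    if (l[which.max(abs(l))] < 0) { rot[, k] <- -l; pc$x[, k] <- -pc$x[, k] }
  }
  atan2(pc$x[, 2], pc$x[, 1]) %% (2 * pi)
}
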