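# Step 2: conditional gene fits and de novo cycler selection.

#' Conditional gene parameter fits given fixed cell phase posteriors
#'
#' For each candidate gene, optimizes that gene's variational parameters
#' (mesor, amplitude, acrophase, cycler probability) while holding the cell
#' phase posteriors of `state` fixed. Mesor/amplitude/acrophase gradients are
#' taken conditional on the gene cycling (Q = 1); the cycler probability
#' tracks the posterior responsibility of the cycling component. Genes are
#' mutually independent given the phases, so all genes are fit jointly in one
#' vectorized run.
#'
#' @param state an optimized `"vi_state"` carrying the cell phase posteriors.
#' @param cm a [phase_counts] object.
#' @param prior a [prior_spec].
#' @param disp a `"dispersion_trend"` fit.
#' @param genes candidate gene ids (default: all genes above the proportion
#'   floor that are not already cycling).
#' @param control a [phase_control].
#' @param map_q_draws posterior draws used for the MAP fraction of samples
#'   with non-zero amplitude.
#' @return data.frame with one row per gene: `gene`, `map_mesor`,
#'   `map_amplitude`, `map_acrophase`, `map_q_fraction`, `flagged` (all-zero
#'   input column).
#' @export
fit_gene_profiles <- function(state, cm, prior, disp, genes = NULL,
                              control = phase_control(), map_q_draws = 50) {
  if (is.null(genes)) {
    props <- pseudobulk_proportions(cm)
    genes <- setdiff(names(props)[props > control$proportion_floor], state$genes)
  }
  if (length(genes) == 0)
    return(data.frame(gene = character(), map_mesor = numeric(),
                      map_amplitude = numeric(), map_acrophase = numeric(),
                      map_q_fraction = numeric(), flagged = logical()))
  sub <- subset_genes(cm, genes)
  zero_col <- colSums(sub$counts) == 0
  rp <- resolve_prior(prior, cm, genes)
  p <- length(genes)
  set.seed(state$seed + 2L)
  # frozen phase draws from the Step-1 posterior
  n <- length(state$cell_loc)
  kcell <- exp(state$cell_logconc)
  fixed_theta <- lapply(seq_len(control$mc_samples), function(s)
    rvonmises(n, state$cell_loc, kcell))
  # acrophase start values from a quick harmonic regression of the
  # library-normalized counts on the phase point estimates; a random start
  # strands true cyclers whose acrophase is near-antiphase (amplitude
  # collapses before the acrophase can rotate)
  theta_hat <- phase_point_estimates(state)
  y <- sub$counts / sub$lib_sizes
  y <- sweep(y, 2, colMeans(y))
  phi0 <- atan2(colSums(y * sin(theta_hat)), colSums(y * cos(theta_hat))) %% (2 * pi)
  gst <- list(genes = genes,
              cell_loc = state$cell_loc, cell_logconc = state$cell_logconc,
              m_loc = unname(rp$mesor_loc), m_logscale = rep(log(0.1), p),
              phi_loc = phi0, phi_logconc = rep(log(0.5), p),
              a_loc = rep(stats::qlogis(0.1), p), a_logscale = rep(log(0.5), p),
              gamma_logit = rep(0, p),
              is_ref = rep(FALSE, p), seed = state$seed + 2L)
  class(gst) <- "vi_state"
  delta_j <- predict(disp, exp(rp$mesor_loc))
  kern <- nb_kernel(sub$counts, sub$lib_sizes, delta_j)
  parnames <- c("m_loc", "m_logscale", "phi_loc", "phi_logconc",
                "a_loc", "a_logscale", "gamma_logit")
  opt <- adam_init(gst[parnames])
  best <- -Inf; stall <- 0L; ema <- NULL
  for (t in seq_len(control$gene_epochs)) {
    eg <- vi_elbo_grad(gst, kern, rp, control$mc_samples,
                       fixed_theta = fixed_theta, cond_q1 = TRUE,
                       skip_flat = (t %% 5 != 0))
    stp <- adam_step(gst[parnames], eg$grads[parnames], opt, control$lr, t)
    gst[parnames] <- stp$pars
    opt <- stp$opt
    gst <- clamp_state(gst)
    ema <- if (is.null(ema)) eg$elbo else 0.7 * ema + 0.3 * eg$elbo
    thr <- if (is.finite(best)) best + control$tol * abs(best) else -Inf
    if (ema > thr) { best <- ema; stall <- 0L }
    else { stall <- stall + 1L; if (stall >= control$patience && t > 50) break }
  }
  qfrac <- map_q_fraction(gst, kern, rp, fixed_theta, map_q_draws)
  R <- rp$amp_max - rp$amp_min
  out <- data.frame(gene = genes,
                    map_mesor = gst$m_loc,
                    map_amplitude = rp$amp_min + R * stats::plogis(gst$a_loc),
                    map_acrophase = gst$phi_loc %% (2 * pi),
                    map_q_fraction = qfrac,
                    flagged = zero_col,
                    stringsAsFactors = FALSE)
  # all-zero columns: flat fit, never called cycling
  out$map_q_fraction[zero_col] <- 0
  out$map_amplitude[zero_col] <- rp$amp_min
  attr(out, "state") <- gst
  out
}

# Fraction of posterior draws in which the MAP cycling indicator is 1, i.e.
# the responsibility of the sinusoidal component exceeds 1/2.
#
# Two corrections keep the statistic honest for weakly expressed flat genes,
# whose conditional (Q = 1) fits overfit noise by a few nats:
#   - the cycling odds come from the PRIOR, not the fitted point q_gamma
#     (which tracks its own responsibilities - a self-reinforcing loop);
#   - each draw's sinusoid-vs-flat log likelihood ratio is importance-
#     corrected by log P(A, phi) - log q(A, phi), so the comparison is an
#     estimate of the per-gene marginal-likelihood ratio (prior-integrated,
#     carrying the Occam penalty for the two extra parameters) rather than a
#     plug-in ratio at the fitted values.
map_q_fraction <- function(gst, kern, rp, fixed_theta, n_draws) {
  p <- kern$p
  sm <- exp(gst$m_logscale); kphi <- exp(gst$phi_logconc); sa <- exp(gst$a_logscale)
  R <- rp$amp_max - rp$amp_min
  prior_odds <- rep(stats::qlogis(rp$gamma_shape[1] /
                                    (rp$gamma_shape[1] + rp$gamma_shape[2])), p)
  hits <- numeric(p)
  S <- length(fixed_theta)
  for (d in seq_len(n_draws)) {
    theta <- fixed_theta[[(d - 1L) %% S + 1L]]
    mu <- stats::rnorm(p, gst$m_loc, sm)
    phi <- rvonmises(p, gst$phi_loc, kphi)
    z <- stats::rnorm(p, gst$a_loc, sa)
    sA <- stats::plogis(z)
    uA <- pmin(pmax(sA, 1e-9), 1 - 1e-9)
    A <- rp$amp_min + R * sA
    res <- .nb_mix_grad(kern$x, kern$xr, kern$nbconst, kern$rj, kern$L,
                        kern$logL, theta, mu, A, phi, prior_odds,
                        FALSE, FALSE, TRUE)
    # prior - proposal correction for the sinusoid-only parameters (the
    # mesor draw is shared by both branches and cancels)
    corr <- log_prior_acrophase(phi, rp) -
      dvonmises(phi, gst$phi_loc, kphi, log = TRUE) +
      log_prior_amplitude(A, rp) -
      (stats::dnorm(z, gst$a_loc, sa, log = TRUE) - log(R * uA * (1 - uA)))
    lodds <- prior_odds + res$S1 - res$S0 + corr
    hits <- hits + (lodds > 0)
  }
  hits / n_draws
}

#' Amplitude Pearson residuals across genes
#'
#' Deviation of each gene's MAP amplitude from the amplitude expected at its
#' MAP mesor, in Pearson-residual units. The expected amplitude and its spread
#' are estimated by binning genes into mesor deciles, computing the mean and
#' SD of MAP amplitude per bin, and interpolating linearly between bin
#' centers. Large positive residuals mark genes with larger amplitude than
#' expected given their expression level.
#'
#' @param summaries data.frame from [fit_gene_profiles] (columns `map_mesor`,
#'   `map_amplitude`).
#' @param n_bins mesor bins (default 10).
#' @return numeric vector of residuals, one per row of `summaries`.
#' @export
amplitude_pearson_residual <- function(summaries, n_bins = 10) {
  m <- summaries$map_mesor
  a <- summaries$map_amplitude
  ng <- length(m)
  if (ng == 0) return(numeric(0))
  if (length(unique(m)) < 2 || ng < 2 * n_bins) {
    # degenerate: constant mesor or too few genes, fall back to global moments
    sdev <- max(stats::sd(a), 1e-8)
    return((a - mean(a)) / sdev)
  }
  qs <- unique(stats::quantile(m, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(m, qs, include.lowest = TRUE)
  centers <- tapply(m, bins, mean)
  mu_bin <- tapply(a, bins, mean)
  sd_bin <- tapply(a, bins, stats::sd)
  sd_bin[is.na(sd_bin) | sd_bin < 1e-8] <- max(stats::sd(a), 1e-8)
  ok <- !is.na(centers)
  if (sum(ok) < 2) {
    sdev <- max(stats::sd(a), 1e-8)
    return((a - mean(a)) / sdev)
  }
  trend <- stats::approx(centers[ok], mu_bin[ok], xout = m, rule = 2)$y
  spread <- stats::approx(centers[ok], sd_bin[ok], xout = m, rule = 2)$y
  (a - trend) / spread
}

#' Select de novo cycling genes
#'
#' Genes whose MAP fraction of samples with non-zero amplitude exceeds
#' `q_threshold` and whose amplitude Pearson residual exceeds
#' `residual_threshold`, excluding genes already cycling.
#'
#' @param summaries data.frame from [fit_gene_profiles], with a `residual`
#'   column (added by the caller from [amplitude_pearson_residual]).
#' @param q_threshold default 0.95.
#' @param residual_threshold default 2.
#' @param exclude gene ids never selected (current cyclers).
#' @return character vector of selected gene ids.
#' @export
select_de_novo <- function(summaries, q_threshold = 0.95, residual_threshold = 2,
                           exclude = character()) {
  stopifnot(is.finite(q_threshold))
  if (nrow(summaries) == 0) return(character(0))
  sel <- summaries$map_q_fraction > q_threshold &
    summaries$residual > residual_threshold &
    !summaries$flagged &
    !(summaries$gene %in% exclude)
  summaries$gene[sel]
}
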