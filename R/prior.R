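#' Prior specification for gene and cell parameters
#'
#' Collects all prior hyperparameters of the model: a per-cell phase prior
#' (von Mises or circular uniform), per-gene mesor normal prior (location set
#' empirically to the log pseudobulk proportion at fit time), per-gene
#' acrophase von Mises prior (circular uniform where no knowledge exists),
#' a shared transformed-Beta amplitude prior on `[amp_min, amp_max]`, and a
#' Beta prior on the cycler probability. One clock gene is the reference gene:
#' its acrophase prior is a point mass at 0 radians and its peak defines hour
#' zero of the cycle.
#'
#' @param clock_genes character vector of core clock gene ids.
#' @param reference_gene gene whose acrophase is fixed at 0 radians; must be a
#'   clock gene. Default: first entry of `clock_genes` (conventionally Arntl).
#' @param acrophase_loc named numeric vector of prior acrophase locations
#'   (radians) for (a subset of) the clock genes; genes without an entry get a
#'   circular-uniform acrophase prior.
#' @param acrophase_conc von Mises concentration(s) for the acrophase priors;
#'   scalar or named vector. Ignored for genes with uniform priors.
#' @param phase_loc,phase_conc optional per-cell von Mises phase prior
#'   (recycled); both `NULL` (default) gives the non-informative circular
#'   uniform prior.
#' @param mesor_scale SD of the normal mesor prior (natural-log units).
#' @param amp_bounds amplitude support `c(amp_min, amp_max)` in natural-log
#'   units; default `c(0, 1.5)` (peak-to-trough up to ~20-fold).
#' @param amp_shape Beta shape parameters of the rescaled amplitude; `c(1, 1)`
#'   is uniform over the support.
#' @param gamma_shape Beta shape parameters of the cycler probability prior.
#' @return an object of class `"prior_spec"`.
#' @export
prior_spec <- function(clock_genes, reference_gene = clock_genes[1],
                       acrophase_loc = NULL, acrophase_conc = 1,
                       phase_loc = NULL, phase_conc = NULL,
                       mesor_scale = 1, amp_bounds = c(0, 1.5),
                       amp_shape = c(1, 1), gamma_shape = c(1, 1)) {
  stopifnot(length(clock_genes) >= 1, length(reference_gene) == 1)
  if (!reference_gene %in% clock_genes)
    stop("reference gene must be a member of the clock gene list")
  if (amp_bounds[1] >= amp_bounds[2]) stop("amp_bounds must satisfy min < max")
  if (mesor_scale <= 0 || any(amp_shape <= 0) || any(gamma_shape <= 0))
    stop("prior scales and shapes must be positive")
  if (!is.null(acrophase_loc) && is.null(names(acrophase_loc)))
    stop("acrophase_loc must be a named vector")
  if (!is.null(acrophase_conc) && any(acrophase_conc <= 0))
    stop("acrophase_conc must be positive")
  if (xor(is.null(phase_loc), is.null(phase_conc)))
    stop("supply both phase_loc and phase_conc, or neither")
  if (!is.null(phase_conc) && any(phase_conc <= 0)) stop("phase_conc must be positive")
  structure(list(clock_genes = clock_genes, reference_gene = reference_gene,
                 acrophase_loc = acrophase_loc, acrophase_conc = acrophase_conc,
                 phase_loc = phase_loc, phase_conc = phase_conc,
                 mesor_scale = mesor_scale, amp_bounds = amp_bounds,
                 amp_shape = amp_shape, gamma_shape = gamma_shape),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf(paste0("prior_spec: %d clock genes (reference %s), amplitude in ",
                     "[%.2g, %.2g], %s cell phase prior\n"),
              length(x$clock_genes), x$reference_gene,
              x$amp_bounds[1], x$amp_bounds[2],
              if (is.null(x$phase_loc)) "uniform" else "von Mises"))
  invisible(x)
}

# expand a prior_spec into per-gene vectors for `genes` (mesor locations from
# the data) and per-cell phase prior vectors
resolve_prior <- function(prior, cm, genes) {
  props <- pseudobulk_proportions(cm)[genes]
  phi_loc <- rep(NA_real_, length(genes))          # NA = circular uniform
  phi_conc <- rep(NA_real_, length(genes))
  if (!is.null(prior$acrophase_loc)) {
    hit <- match(names(prior$acrophase_loc), genes)
    ok <- !is.na(hit)
    phi_loc[hit[ok]] <- prior$acrophase_loc[ok] %% (2 * pi)
    conc <- rep_len(prior$acrophase_conc, length(prior$acrophase_loc))
    phi_conc[hit[ok]] <- conc[ok]
  }
  is_ref <- genes == prior$reference_gene
  phi_loc[is_ref] <- 0
  n <- nrow(cm$counts)
  list(genes = genes,
       mesor_loc = log(pmax(props, 1e-12)),
       mesor_scale = rep_len(prior$mesor_scale, length(genes)),
       phi_loc = phi_loc, phi_conc = phi_conc, is_ref = is_ref,
       amp_min = prior$amp_bounds[1], amp_max = prior$amp_bounds[2],
       amp_shape = prior$amp_shape, gamma_shape = prior$gamma_shape,
       theta_loc = if (is.null(prior$phase_loc)) NULL else rep_len(prior$phase_loc, n),
       theta_conc = if (is.null(prior$phase_conc)) NULL else rep_len(prior$phase_conc, n))
}

# component log prior densities ------------------------------------------

log_prior_theta <- function(theta, rp) {
  if (is.null(rp$theta_loc)) rep(-log(2 * pi), length(theta))
  else dvonmises(theta, rp$theta_loc, rp$theta_conc, log = TRUE)
}

log_prior_mesor <- function(mu, rp) stats::dnorm(mu, rp$mesor_loc, rp$mesor_scale, log = TRUE)

# reference gene: point mass at 0 contributes 0 by convention (its acrophase
# is never a free variable)
log_prior_acrophase <- function(phi, rp) {
  out <- rep(-log(2 * pi), length(phi))
  inf <- !is.na(rp$phi_conc)
  if (any(inf)) out[inf] <- dvonmises(phi[inf], rp$phi_loc[inf], rp$phi_conc[inf], log = TRUE)
  out[rp$is_ref] <- 0
  out
}

log_prior_amplitude <- function(A, rp) {
  R <- rp$amp_max - rp$amp_min
  u <- (A - rp$amp_min) / R
  out <- rep(-Inf, length(A))
  ok <- u >= 0 & u <= 1
  out[ok] <- stats::dbeta(pmin(pmax(u[ok], 1e-12), 1 - 1e-12),
                          rp$amp_shape[1], rp$amp_shape[2], log = TRUE) - log(R)
  out
}

log_prior_gamma <- function(gamma, rp) {
  stats::dbeta(gamma, rp$gamma_shape[1], rp$gamma_shape[2], log = TRUE)
}

#' Log prior density of gene and cell parameters
#'
#' Sum of all component log prior densities for a set of genes and cells:
#' cell phases, mesors, acrophases, amplitudes, cycler probabilities, and the
#' Bernoulli mass of the cycling indicators given the cycler probabilities.
#' Circular-uniform components contribute `-log(2*pi)`; an amplitude outside
#' its bounds yields `-Inf`.
#'
#' @param theta per-cell phases (radians).
#' @param genes data.frame with columns `gene`, `mesor`, `amplitude`,
#'   `acrophase`, `gamma`, and optionally `cycling` (0/1).
#' @param prior a [prior_spec].
#' @param cm the [phase_counts] the prior is resolved against (mesor prior
#'   locations are empirical log pseudobulk proportions).
#' @return scalar log density.
#' @export
log_prior <- function(theta, genes, prior, cm) {
  rp <- resolve_prior(prior, cm, genes$gene)
  lp <- sum(log_prior_theta(theta, rp)) +
    sum(log_prior_mesor(genes$mesor, rp)) +
    sum(log_prior_acrophase(genes$acrophase, rp)) +
    sum(log_prior_amplitude(genes$amplitude, rp)) +
    sum(log_prior_gamma(genes$gamma, rp))
  if (!is.null(genes$cycling)) {
    g <- pmin(pmax(genes$gamma, 1e-12), 1 - 1e-12)
    lp <- lp + sum(ifelse(genes$cycling > 0, log(g), log1p(-g)))
  }
  lp
}
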