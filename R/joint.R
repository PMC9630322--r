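#' Unnormalized joint log posterior
#'
#' Sum of the NB log likelihood over all cells and the requested gene subset
#' (sinusoidal mean model, dispersion from the mean-dispersion trend) plus the
#' log prior of all included parameters.
#'
#' @param cm a [phase_counts] object.
#' @param theta per-cell phases (radians).
#' @param genes data.frame with columns `gene`, `mesor`, `amplitude`,
#'   `acrophase`, `gamma`, `cycling`; rows define the gene subset.
#' @param prior a [prior_spec].
#' @param disp a `"dispersion_trend"` fit.
#' @return scalar log density (up to the model evidence constant).
#' @export
log_joint <- function(cm, theta, genes, prior, disp) {
  if (nrow(genes) == 0) stop("empty gene subset")
  if (length(theta) != nrow(cm$counts)) stop("theta length must match cell count")
  sub <- subset_genes(cm, genes$gene)
  ll <- nb_loglik_matrix(sub$counts, sub$lib_sizes, theta,
                         genes$mesor, genes$amplitude, genes$acrophase,
                         genes$cycling, disp)
  sum(ll) + log_prior(theta, genes, prior, cm)
}

# cells x genes matrix of NB log pmf values under the sinusoidal mean model
nb_loglik_matrix <- function(x, L, theta, mu, A, phi, cycling, disp) {
  n <- nrow(x); p <- ncol(x)
  C <- cos(theta) %o% cos(phi) + sin(theta) %o% sin(phi)   # cos(theta_i - phi_j)
  loglam <- matrix(mu, n, p, byrow = TRUE) +
    matrix(cycling * A, n, p, byrow = TRUE) * C
  lam <- exp(loglam)
  m <- L * lam
  delta <- predict(disp, lam)
  out <- nb_log_pmf(as.vector(x), as.vector(m), as.vector(delta))
  dim(out) <- c(n, p)
  out
}
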