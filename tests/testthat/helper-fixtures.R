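# Shared fixtures and oracles. Everything is generated in code; expensive
# fits are cached in a session-level environment so several test files (and
# several acceptance criteria) can share one computation.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# standard simulation fixture: light-dark time course regime
std_sim <- function(n_cells, seed, n_ccgs = 20, n_flat = 500) {
  simulate_counts(sim_config(n_cells = n_cells, n_phase_grid = 4,
                             n_flat_genes = n_flat, n_ccgs = n_ccgs,
                             seed = seed),
                  constant_dispersion(0.1))
}

std_prior <- function(seed = 101) {
  jittered_acrophase_prior(clock_gene_params(), seed = seed,
                           reference_gene = "Arntl")
}

# tiny two-cell, one-gene instance with near-point gene priors, for
# quadrature oracles over the remaining latent variables
tiny_instance <- function(x = c(3, 1), L = c(5000, 5000)) {
  counts <- matrix(x, 2, 1, dimnames = list(c("c1", "c2"), "Arntl"))
  cm <- phase_counts(counts, lib_sizes = L)
  prior <- prior_spec("Arntl", amp_bounds = c(0.49, 0.51), mesor_scale = 0.01)
  disp <- constant_dispersion(0.1)
  list(cm = cm, prior = prior, disp = disp)
}

# evidence of the tiny instance by quadrature. With q1 = TRUE the gene is
# treated as cycling (the definition used by clock_evidence); otherwise the
# cycling indicator is marginalized at the fitted point cycler probability
# (the definition used by the ELBO). Cells are independent within each
# branch, so the phase integrals factor per cell.
tiny_evidence_quadrature <- function(ti, state, q1 = FALSE) {
  x <- ti$cm$counts[, 1]; L <- ti$cm$lib_sizes
  gam <- if (q1) 1 else stats::plogis(state$gamma_logit)
  mu0 <- log(pseudobulk_proportions(ti$cm)[1])
  mu_grid <- seq(mu0 - 5 * 0.01, mu0 + 5 * 0.01, length.out = 61)
  A_grid <- seq(0.49, 0.51, length.out = 21)
  th_grid <- seq(0, 2 * pi, length.out = 257)[-257]
  delta <- 0.1
  vals <- matrix(NA_real_, length(mu_grid), length(A_grid))
  for (a in seq_along(mu_grid)) for (b in seq_along(A_grid)) {
    mu <- mu_grid[a]; A <- A_grid[b]
    I <- vapply(seq_along(x), function(i) {
      m <- L[i] * exp(mu + A * cos(th_grid))
      mean(exp(nb_log_pmf(x[i], m, delta)))       # (1/2pi) d(theta) quadrature
    }, numeric(1))
    NB0 <- exp(nb_log_pmf(x, L * exp(mu), delta))
    lik <- gam * prod(I) + (1 - gam) * prod(NB0)
    vals[a, b] <- lik * stats::dnorm(mu, mu0, 0.01) * (1 / 0.02)
  }
  dmu <- mu_grid[2] - mu_grid[1]; dA <- A_grid[2] - A_grid[1]
  log(sum(vals) * dmu * dA)
}

# loop-based unnormalized joint log posterior (oracle for log_joint)
log_joint_loops <- function(cm, theta, genes, prior, disp) {
  total <- 0
  for (i in seq_len(nrow(cm$counts))) {
    for (k in seq_len(nrow(genes))) {
      j <- match(genes$gene[k], cm$gene_ids)
      lam <- exp(genes$mesor[k] + genes$cycling[k] * genes$amplitude[k] *
                   cos(theta[i] - genes$acrophase[k]))
      total <- total + nb_log_pmf(cm$counts[i, j], cm$lib_sizes[i] * lam,
                                  predict(disp, lam))
    }
  }
  total + log_prior(theta, genes, prior, cm)
}

# synthetic waveform table: nc cycler genes (24 h cosines with varying
# acrophase), nf flat genes, small multiplicative noise
synthetic_waveforms <- function(nc = 20, nf = 30, hours = seq(0, 46, by = 2),
                                noise = 0.02, seed = 3) {
  set.seed(seed)
  base <- 10^stats::runif(nc + nf, -5, -3.5)
  prop <- matrix(0, nc + nf, length(hours))
  for (g in seq_len(nc)) {
    prop[g, ] <- base[g] * exp(0.6 * cos(2 * pi * (hours - g) / 24))
  }
  for (g in nc + seq_len(nf)) prop[g, ] <- base[g]
  prop <- prop * exp(matrix(stats::rnorm(length(prop), 0, noise), nrow(prop)))
  waveform_table(prop, hours, gene = sprintf("wg%02d", seq_len(nc + nf)),
                 cycler = rep(c(TRUE, FALSE), c(nc, nf)))
}

quiet <- function(expr) suppressMessages(expr)

subset_cm <- function(cm, k) {
  phase_counts(cm$counts[, seq_len(k), drop = FALSE],
               cm$cell_ids, cm$gene_ids[seq_len(k)], cm$lib_sizes)
}

subset_cells_f <- function(cm, idx) {
  phase_counts(cm$counts[idx, , drop = FALSE], cm$cell_ids[idx], cm$gene_ids,
               cm$lib_sizes[idx])
}

# small recovery fit shared by several VI tests
rec_fit <- function() {
  cached("fit_rec_state", {
    sim <- cached("sim_vi_rec", std_sim(200, seed = 31, n_ccgs = 0, n_flat = 30))
    pr <- std_prior(seed = 33)
    disp <- constant_dispersion(0.1)
    st <- vi_init(sim$counts, pr, clock_gene_params()$gene, disp, seed = 9)
    st <- vi_optimize(st, sim$counts, pr, disp, phase_control(epochs = 400, seed = 9))
    list(st = st, sim = sim, pr = pr, disp = disp)
  })
}
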