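# Core probabilistic pieces: NB pmf, sinusoidal mean, dispersion trend,
# priors, joint density.

test_that("nb_log_pmf matches the mean/dispersion parametrization", {
  # Poisson limit
  x <- 0:20
  expect_equal(nb_log_pmf(x, 5, 1e-12), dpois(x, 5, log = TRUE), tolerance = 1e-6)
  # normalization over the support for a range of dispersions
  for (delta in c(0.01, 0.1, 0.3, 1, 5)) {
    total <- sum(exp(nb_log_pmf(0:10000, 5, delta)))
    expect_equal(total, 1, tolerance = 1e-8)
  }
  # mean/variance relationship Var = mu + delta mu^2, by Monte Carlo
  set.seed(42)
  draws <- rnbinom(1e6, size = 1 / 0.5, mu = 10)
  expect_equal(mean(draws), 10, tolerance = 0.02)
  expect_equal(var(draws), 10 + 0.5 * 100, tolerance = 0.02)
  # input validation
  expect_error(nb_log_pmf(-1, 5, 0.1), "negative")
  expect_error(nb_log_pmf(1, Inf, 0.1), "non-finite")
})

test_that("expected log proportion follows the sinusoid and is periodic", {
  expect_equal(expected_log_proportion(1.2, -9, 0.7, 1.2, 1), -9 + 0.7)  # peak
  expect_equal(expected_log_proportion(0.4, -9, 0.7, 0.4 - pi / 2, 1), -9)
  expect_equal(expected_log_proportion(3, -9, 0.7, 1, 0), -9)            # flat
  th <- seq(0, 2 * pi, length.out = 7)
  expect_equal(expected_log_proportion(th, -8, 0.5, 1),
               expected_log_proportion(th + 2 * pi, -8, 0.5, 1))
  expect_equal(expected_log_proportion(th, -8, 0.5, 1),
               expected_log_proportion(th, -8, 0.5, 1 + 2 * pi))
})

test_that("dispersion trend recovers simulated dispersions", {
  set.seed(7)
  n <- 500; p <- 120
  props <- 10^runif(p, -4, -3)
  L <- rpois(n, 8000)
  x <- matrix(rnbinom(n * p, size = 1 / 0.4, mu = outer(L, props)), n, p)
  cm <- phase_counts(x, lib_sizes = L)
  dt <- fit_dispersion_trend(cm, degree = 2)
  lam <- 10^seq(log10(dt$lambda_range[1]), log10(dt$lambda_range[2]), length.out = 20)
  pred <- predict(dt, lam)
  expect_true(all(pred > 0))
  expect_true(all(abs(pred - 0.4) / 0.4 < 0.2))
  # clamping outside the fitted range
  expect_equal(predict(dt, dt$lambda_range[2] * 100),
               predict(dt, dt$lambda_range[2]))

  # Poisson counts: near-zero dispersion recovered
  xp <- matrix(rpois(n * p, outer(L, props)), n, p)
  dtp <- fit_dispersion_trend(phase_counts(xp, lib_sizes = L), degree = 2)
  expect_true(all(predict(dtp, lam) <= 0.05))

  # degree 0 equals the pooled method-of-moments estimate (at the
  # pseudobulk proportions the fit actually uses)
  dt0 <- fit_dispersion_trend(cm, degree = 0)
  m <- outer(L, pseudobulk_proportions(cm))
  mom <- sum((x - m)^2 - m) / sum(m^2)
  expect_equal(unname(predict(dt0, 1e-4)), mom, tolerance = 1e-10)

  # too few genes
  expect_error(fit_dispersion_trend(subset_cm(cm, 10), degree = 2), "50 genes")
})


test_that("log prior components integrate and bound correctly", {
  pr <- prior_spec("Arntl", acrophase_loc = c(Per2 = 1), acrophase_conc = 3)
  cm <- std_sim(30, seed = 2, n_ccgs = 0, n_flat = 10)$counts
  rp <- cyclophase:::resolve_prior(pr, cm, c("Arntl", "Per2"))
  # acrophase von Mises density integrates to 1
  th <- seq(0, 2 * pi, length.out = 4097)[-4097]
  dens <- exp(cyclophase:::log_prior_acrophase(th, list(
    phi_conc = rep(3, length(th)), phi_loc = rep(1, length(th)),
    is_ref = rep(FALSE, length(th)))))
  expect_equal(sum(dens) * (th[2] - th[1]), 1, tolerance = 1e-6)
  # uniform Beta cycler prior contributes zero log density
  expect_equal(cyclophase:::log_prior_gamma(0.37, rp), 0)
  # amplitude density: uniform Beta on the bounds
  genes <- data.frame(gene = "Per2", mesor = rp$mesor_loc[2], amplitude = 0,
                      acrophase = 1, gamma = 0.5, cycling = 1)
  rpa <- cyclophase:::resolve_prior(prior_spec("Arntl", amp_bounds = c(0, 1.5)),
                                    cm, "Per2")
  expect_equal(cyclophase:::log_prior_amplitude(0, rpa), log(1 / 1.5))
  expect_equal(cyclophase:::log_prior_amplitude(2, rpa), -Inf)
})

test_that("log_joint matches a loop-based oracle and is order-invariant", {
  sim <- std_sim(3, seed = 5, n_ccgs = 0, n_flat = 0)
  cm <- subset_cm(sim$counts, 2)
  pr <- prior_spec(cm$gene_ids[1])
  disp <- constant_dispersion(0.2)
  genes <- data.frame(gene = cm$gene_ids, mesor = c(-8.5, -9.2),
                      amplitude = c(0.5, 0.2), acrophase = c(0, 2),
                      gamma = c(0.7, 0.3), cycling = c(1, 0))
  theta <- c(0.3, 2.5, 5.1)
  expect_equal(log_joint(cm, theta, genes, pr, disp),
               log_joint_loops(cm, theta, genes, pr, disp), tolerance = 1e-9)
  # invariance to gene and cell ordering
  perm_g <- c(2, 1); perm_c <- c(3, 1, 2)
  cm2 <- phase_counts(cm$counts[perm_c, perm_g], cm$cell_ids[perm_c],
                      cm$gene_ids[perm_g], cm$lib_sizes[perm_c])
  expect_equal(log_joint(cm2, theta[perm_c], genes[perm_g, ], pr, disp),
               log_joint(cm, theta, genes, pr, disp), tolerance = 1e-10)
  # single flat gene equals one NB term plus priors
  cm1 <- subset_cm(subset_cells_f(cm, 1), 1)
  g1 <- genes[2, ]; g1$gene <- cm1$gene_ids[1]
  lam <- exp(g1$mesor)
  manual <- nb_log_pmf(cm1$counts[1, 1], cm1$lib_sizes[1] * lam,
                       predict(disp, lam)) +
    log_prior(theta[1], g1, prior_spec(cm1$gene_ids[1]), cm1)
  expect_equal(log_joint(cm1, theta[1], g1, prior_spec(cm1$gene_ids[1]), disp),
               manual, tolerance = 1e-10)
  # duplicating every cell doubles the likelihood portion exactly
  pr0 <- prior_spec(cm$gene_ids[1])
  lik <- function(cmx, th) {
    log_joint(cmx, th, genes, pr0, disp) - log_prior(th, genes, pr0, cmx)
  }
  cmd <- phase_counts(rbind(cm$counts, cm$counts),
                      c(cm$cell_ids, paste0(cm$cell_ids, "_b")),
                      cm$gene_ids, c(cm$lib_sizes, cm$lib_sizes))
  expect_equal(lik(cmd, c(theta, theta)), 2 * lik(cm, theta), tolerance = 1e-9)
  expect_error(log_joint(cm, theta, genes[0, ], pr, disp), "empty")
})
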