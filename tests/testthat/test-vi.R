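# Variational engine: initialization, ELBO bound, optimization, point
# estimates, credible arcs, evidence, permutation Bayes factor.

test_that("initialization sets empirical mesors, near-uniform phases, and is deterministic", {
  sim <- cached("sim_vi_small", std_sim(120, seed = 21, n_ccgs = 0, n_flat = 30))
  cm <- sim$counts
  pr <- std_prior()
  disp <- constant_dispersion(0.1)
  st <- vi_init(cm, pr, clock_gene_params()$gene, disp, seed = 4)
  expect_equal(length(st$genes), 12)
  props <- pseudobulk_proportions(cm)[st$genes]
  expect_equal(st$m_loc, unname(log(props)), tolerance = 1e-12)
  expect_true(all(exp(st$cell_logconc) <= 0.5))   # near-uniform at start
  expect_equal(st$phi_loc[st$genes == "Arntl"], 0)
  st2 <- vi_init(cm, pr, clock_gene_params()$gene, disp, seed = 4)
  expect_identical(st, st2)
  expect_error(vi_init(cm, pr, c("Arntl", "NotAGene"), disp), "NotAGene")
})

test_that("Monte Carlo ELBO never exceeds the quadrature evidence on a tiny instance", {
  ti <- tiny_instance()
  st <- vi_init(ti$cm, ti$prior, "Arntl", ti$disp, seed = 3)
  ctl <- phase_control(epochs = 120, seed = 3)
  st <- vi_optimize(st, ti$cm, ti$prior, ti$disp, ctl)
  oracle <- tiny_evidence_quadrature(ti, st)
  reps <- vapply(1:24, function(k) {
    set.seed(500 + k)
    vi_elbo(st, ti$cm, ti$prior, ti$disp, n_samples = 40)
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lte(mean(reps), oracle + 3 * se)
  expect_gte(mean(reps), oracle - 5)   # and the bound is not vacuous
  # more samples shrink the estimator's spread
  reps_small <- vapply(1:30, function(k) {
    set.seed(900 + k); vi_elbo(st, ti$cm, ti$prior, ti$disp, n_samples = 3)
  }, numeric(1))
  reps_big <- vapply(1:30, function(k) {
    set.seed(900 + k); vi_elbo(st, ti$cm, ti$prior, ti$disp, n_samples = 60)
  }, numeric(1))
  expect_lt(var(reps_big), var(reps_small))
})

test_that("optimization recovers simulated phases and stays diffuse on flat data", {
  sim <- cached("sim_vi_rec", std_sim(200, seed = 31, n_ccgs = 0, n_flat = 30))
  cm <- sim$counts
  pr <- std_prior(seed = 33)
  disp <- constant_dispersion(0.1)
  ctl <- phase_control(epochs = 400, seed = 9)
  st <- rec_fit()$st
  est <- phase_point_estimates(st)
  al <- optimal_shift(est, sim$phases, reflect = FALSE)
  err <- phase_error_hours(sim$phases, al$shifted)
  expect_lt(median(err), 2.5)
  # circular correlation between aligned estimates and truth
  cc <- cor(cbind(cos(al$shifted), sin(al$shifted)),
            cbind(cos(sim$phases), sin(sim$phases)))
  expect_gt(max(abs(cc)), 0.8)
  conc_rec <- exp(st$cell_logconc)

  # flat "clock" genes: phases must stay uncertain
  flat_table <- clock_gene_params()
  flat_table$amplitude <- 0
  simf <- simulate_counts(sim_config(n_cells = 200, n_flat_genes = 30, n_ccgs = 0,
                                     clock_table = flat_table, seed = 32),
                          constant_dispersion(0.1))
  stf <- vi_init(simf$counts, pr, clock_gene_params()$gene, disp, seed = 9)
  stf <- vi_optimize(stf, simf$counts, pr, disp, ctl)
  expect_lt(median(exp(stf$cell_logconc)), median(conc_rec))
  expect_lt(median(exp(stf$cell_logconc)), 1)

  # determinism under a fixed seed
  st2 <- vi_init(cm, pr, clock_gene_params()$gene, disp, seed = 9)
  st2 <- vi_optimize(st2, cm, pr, disp, ctl)
  expect_identical(phase_point_estimates(st), phase_point_estimates(st2))

})

test_that("a one-cell one-gene fit runs and returns a finite ELBO", {
  cm <- phase_counts(matrix(4, 1, 1, dimnames = list("c", "Arntl")),
                     lib_sizes = 5000)
  pr <- prior_spec("Arntl")
  disp <- constant_dispersion(0.1)
  st <- vi_init(cm, pr, "Arntl", disp, seed = 1)
  st <- vi_optimize(st, cm, pr, disp, phase_control(epochs = 40, seed = 1))
  expect_true(all(is.finite(attr(st, "elbo_trace"))))
})

test_that("phase point estimates are circular means of the posteriors", {
  st <- structure(list(cell_loc = c(1.0, 0.1 + 2 * pi, -0.3),
                       cell_logconc = log(c(5, 5, 5)), seed = 1L),
                  class = "vi_state")
  est <- phase_point_estimates(st)
  expect_equal(est[1], 1.0)
  expect_true(all(est >= 0 & est < 2 * pi))
  # matches the circular mean of many exact draws
  set.seed(8)
  draws <- rvonmises(1e5, loc = 1.0, conc = 5)
  expect_equal(as.numeric(circular_mean(draws)), est[1], tolerance = 0.01)
})

test_that("HDR credible arcs behave for von Mises posteriors", {
  st <- structure(list(cell_loc = c(2.0), cell_logconc = log(8), seed = 1L),
                  class = "vi_state")
  arcs <- hdr_interval(st, 1, 0.95)
  expect_equal(nrow(arcs), 1)
  mid <- ((arcs[1, "start"] + arcs[1, "end"]) / 2) %% (2 * pi)
  expect_equal(as.numeric(mid), 2.0, tolerance = 2 * (2 * pi / 512))
  mass <- integrate(function(t) dvonmises(t, 2.0, 8),
                    arcs[1, "start"], arcs[1, "end"])$value
  expect_gte(mass, 0.95 - 1e-6)
  long <- hdr_interval(st, 1, 0.9999)
  expect_gt(cyclophase:::arcs_total_length(long),
            cyclophase:::arcs_total_length(arcs))
  expect_error(hdr_interval(st, 1, 1.2), "confidence")
})

test_that("clock evidence tracks the quadrature oracle and rewards the fit", {
  ti <- tiny_instance()
  st <- vi_init(ti$cm, ti$prior, "Arntl", ti$disp, seed = 3)
  st <- vi_optimize(st, ti$cm, ti$prior, ti$disp, phase_control(epochs = 120, seed = 3))
  ev <- clock_evidence(st, ti$cm, ti$prior, ti$disp, "Arntl",
                       n_samples = 2048, seed = 11)
  oracle <- tiny_evidence_quadrature(ti, st, q1 = TRUE)
  expect_lt(abs(ev - oracle), 0.1)
  # identical seed gives identical estimate
  ev2 <- clock_evidence(st, ti$cm, ti$prior, ti$disp, "Arntl",
                        n_samples = 2048, seed = 11)
  expect_identical(ev, ev2)

  # fit explains the clock better than an unoptimized random state
  rec <- rec_fit()
  ev_fit <- clock_evidence(rec$st, rec$sim$counts, rec$pr, rec$disp,
                           n_samples = 256, seed = 5)
  st0 <- vi_init(rec$sim$counts, rec$pr, clock_gene_params()$gene, rec$disp,
                 seed = 77)
  ev_raw <- clock_evidence(st0, rec$sim$counts, rec$pr, rec$disp,
                           n_samples = 256, seed = 5)
  expect_gt(ev_fit, ev_raw)
})

test_that("permutation Bayes factor separates rhythmic from permuted data", {
  rec <- rec_fit()
  ctl <- phase_control(epochs = 300, seed = 9)
  bf <- bayes_factor_vs_permuted(rec$st, rec$sim$counts, rec$pr, rec$disp,
                                 control = ctl, seed = 19)
  expect_gt(bf, 2)   # strongly rhythmic simulation
})
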