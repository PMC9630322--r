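# Step 2: conditional gene fits, amplitude Pearson residuals, de novo
# selection, and the outer fitting loop.

# build a state whose phase posteriors sit at the true phases (sharp),
# mimicking a well-converged Step 1
informed_state <- function(cm, prior, disp, phases, conc = 50, seed = 5) {
  st <- vi_init(cm, prior, clock_gene_params()$gene, disp, seed = seed)
  st$cell_loc <- phases
  st$cell_logconc <- rep(log(conc), length(phases))
  st
}

test_that("conditional gene fits separate cyclers from flat genes", {
  sim <- cached("sim_det", std_sim(300, seed = 41, n_ccgs = 10, n_flat = 60))
  cm <- sim$counts
  pr <- std_prior()
  disp <- constant_dispersion(0.1)
  st <- informed_state(cm, pr, disp, sim$phases)
  pool <- setdiff(cm$gene_ids, clock_gene_params()$gene)
  sm <- fit_gene_profiles(st, cm, pr, disp, pool, phase_control(seed = 2))
  truth <- sim$gene_params[match(sm$gene, sim$gene_params$gene), ]
  strong <- truth$is_ccg & truth$amplitude >= 0.5 & truth$mesor > log(5e-5)
  expect_true(all(sm$map_q_fraction[strong] > 0.95))
  # acrophase recovery for the strong cyclers, within one hour
  dphi <- phase_error_hours(truth$acrophase[strong], sm$map_acrophase[strong])
  expect_true(all(dphi < 1))
  # amplitude recovery in the right ballpark
  expect_gt(cor(sm$map_amplitude[truth$is_ccg], truth$amplitude[truth$is_ccg]), 0.7)
  # flat genes rarely reach high cycling support
  expect_lt(mean(sm$map_q_fraction[!truth$is_ccg] > 0.95), 0.05)
  cached("det_summaries", list(sm = sm, truth = truth, st = st, sim = sim,
                               pr = pr, disp = disp))
})

test_that("duplicated gene columns get identical summaries", {
  sim <- cached("sim_det", std_sim(300, seed = 41, n_ccgs = 10, n_flat = 60))
  cm <- sim$counts
  dup <- cbind(cm$counts, dup1 = cm$counts[, "Ccg001"])
  cmd <- phase_counts(dup, cm$cell_ids, c(cm$gene_ids, "CcgDup"), cm$lib_sizes)
  pr <- std_prior(); disp <- constant_dispersion(0.1)
  st <- informed_state(cmd, pr, disp, sim$phases)
  sm <- fit_gene_profiles(st, cmd, pr, disp, c("Ccg001", "CcgDup"),
                          phase_control(seed = 2))
  # fits are stochastic (independent Monte Carlo draws per gene), so the two
  # copies agree up to Monte Carlo error
  expect_lt(abs(sm$map_amplitude[1] - sm$map_amplitude[2]), 0.05)
  expect_lt(phase_error_hours(sm$map_acrophase[1], sm$map_acrophase[2]), 0.5)
  expect_lt(abs(sm$map_q_fraction[1] - sm$map_q_fraction[2]), 0.1)
})

test_that("all-zero gene columns yield a flagged flat fit", {
  sim <- cached("sim_det", std_sim(300, seed = 41, n_ccgs = 10, n_flat = 60))
  cm <- sim$counts
  z <- cbind(cm$counts, ZeroG = 0)
  cmz <- phase_counts(z, cm$cell_ids, c(cm$gene_ids, "ZeroG"), cm$lib_sizes)
  pr <- std_prior(); disp <- constant_dispersion(0.1)
  st <- informed_state(cmz, pr, disp, sim$phases)
  sm <- fit_gene_profiles(st, cmz, pr, disp, c("Flat0001", "ZeroG"),
                          phase_control(seed = 2))
  expect_true(sm$flagged[sm$gene == "ZeroG"])
  expect_equal(sm$map_q_fraction[sm$gene == "ZeroG"], 0)
})

test_that("amplitude Pearson residuals measure deviation from the mesor trend", {
  set.seed(3)
  n <- 200
  mesor <- seq(-11, -7, length.out = n)
  trend <- 0.1 + 0.02 * (mesor + 9)
  spread <- 0.05
  amp <- trend + rnorm(n, 0, spread)
  sm <- data.frame(gene = sprintf("g%03d", 1:n), map_mesor = mesor,
                   map_amplitude = amp)
  r <- amplitude_pearson_residual(sm)
  expect_lt(abs(mean(r)), 0.1)
  # a constructed outlier at trend + 2 spread lands near residual 2
  sm2 <- sm
  sm2$map_amplitude[100] <- trend[100] + 2 * spread
  r2 <- amplitude_pearson_residual(sm2)
  expect_equal(r2[100], 2, tolerance = 0.35)
  # a gene exactly on the trend has residual ~ 0
  sm3 <- sm; sm3$map_amplitude[50] <- trend[50]
  expect_lt(abs(amplitude_pearson_residual(sm3)[50]), 0.35)
  # degenerate constant mesor falls back to global standardization
  smc <- data.frame(gene = c("a", "b", "c"), map_mesor = -9,
                    map_amplitude = c(0.1, 0.2, 0.3))
  rc <- amplitude_pearson_residual(smc)
  expect_equal(mean(rc), 0, tolerance = 1e-10)
})

test_that("de novo selection applies both thresholds and exclusions", {
  expect_equal(select_de_novo(data.frame()[0, ]), character(0))
  det <- cached("det_summaries", stop("needs conditional fit test"))
  sm <- det$sm
  sm$residual <- amplitude_pearson_residual(sm)
  sel <- select_de_novo(sm, 0.95, 2)
  truth <- det$truth
  expect_true(all(sel %in% truth$gene[truth$is_ccg]))   # precision 1
  expect_gte(length(sel), 5)
  expect_equal(select_de_novo(sm, 0.95, Inf), character(0))
  expect_equal(setdiff(select_de_novo(sm, 0.95, 2, exclude = sel[1]), sel[-1]),
               character(0))
})

test_that("the outer loop keeps helpful cyclers and respects max_iterations", {
  sim <- cached("sim_det", std_sim(300, seed = 41, n_ccgs = 10, n_flat = 60))
  pr <- std_prior()
  disp <- constant_dispersion(0.1)
  f1 <- quiet(cyclophase(sim$counts, clock_gene_params()$gene, prior = pr,
                         disp = disp,
                         control = phase_control(max_iterations = 1, seed = 7)))
  expect_equal(nrow(f1$trace), 1)
  expect_equal(f1$de_novo, character(0))
  expect_setequal(f1$cycling_genes, clock_gene_params()$gene)
  # trace columns and the best-iteration invariant
  expect_true(all(c("iteration", "evidence", "log10_bayes_factor") %in%
                    names(f1$trace)))
  expect_equal(f1$trace$evidence[f1$best_iteration], max(f1$trace$evidence))
})
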