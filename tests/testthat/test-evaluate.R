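# Evaluation statistics: alignment, errors, calibration, stability,
# held-out clock likelihood, enrichment, PCA baseline.

test_that("optimal shift aligns constant offsets and matches a fine-grid oracle", {
  set.seed(11)
  truth <- runif(40, 0, 2 * pi)
  self <- optimal_shift(truth, truth, reflect = FALSE)
  expect_lt(abs(self$shift), 2 * pi / 1440 + 1e-9)
  off <- optimal_shift((truth + 1.3) %% (2 * pi), truth, reflect = FALSE)
  expect_equal(off$shift, 1.3, tolerance = 2 * pi / 1440)
  # reflection handling: a mirrored estimate set is recovered
  refl <- optimal_shift((-truth + 0.7) %% (2 * pi), truth)
  expect_true(refl$reflected)
  expect_lt(median(phase_error_hours(truth, refl$shifted)), 0.02)
  # brute-force fine grid oracle on noisy random instances
  fine_shift <- function(est, tru) {
    grid <- seq(0, 2 * pi, length.out = 86401)[-86401]
    tot <- vapply(grid, function(s)
      sum(acos(pmin(pmax(cos(est - s - tru), -1), 1))), numeric(1))
    grid[which.min(tot)]
  }
  for (k in 1:5) {
    set.seed(100 + k)
    tru <- runif(25, 0, 2 * pi)
    est <- (tru + 0.9 + rnorm(25, 0, 0.4)) %% (2 * pi)
    got <- optimal_shift(est, tru, reflect = FALSE)$shift
    expect_lt(abs(got - fine_shift(est, tru)) %% (2 * pi), 2 * pi / 1440 + 1e-9)
  }
  # shift equivariance: shifting estimates by c shifts the optimum by c
  base <- optimal_shift(truth + 0.4, truth, reflect = FALSE)$shift
  plus <- optimal_shift(truth + 0.4 + 1.1, truth, reflect = FALSE)$shift
  expect_equal((plus - base) %% (2 * pi), 1.1, tolerance = 2 * 2 * pi / 1440)
  expect_error(optimal_shift(1:3, 1:4), "length")
})

test_that("phase errors follow the circular-distance formula", {
  expect_equal(phase_error_hours(1.1, 1.1), 0)
  expect_equal(phase_error_hours(0, pi), 12)
  expect_equal(phase_error_hours(0, pi / 6), 2)
  th <- runif(50, 0, 2 * pi); es <- runif(50, 0, 2 * pi)
  e <- phase_error_hours(th, es)
  expect_true(all(e >= 0 & e <= 12))
  expect_equal(phase_error_hours(th + 2 * pi, es), e, tolerance = 1e-9)
  expect_equal(phase_error_hours(th, es + 2 * pi), e, tolerance = 1e-9)
  expect_equal(phase_error_hours(es, th), e, tolerance = 1e-9)   # symmetry
})

test_that("the error eCDF is a right-continuous step function ending at 1", {
  e <- error_ecdf(c(0, 0, 0))
  expect_equal(attr(e, "ecdf")(0), 1)
  e3 <- error_ecdf(3)
  expect_equal(attr(e3, "ecdf")(2.9), 0)
  expect_equal(attr(e3, "ecdf")(3), 1)
  set.seed(12)
  u <- runif(1e5, 0, 12)
  eu <- error_ecdf(u)
  expect_equal(attr(eu, "ecdf")(6), 0.5, tolerance = 0.01)
  expect_equal(max(eu$fraction), 1)
  expect_error(error_ecdf(numeric(0)), "empty")
  expect_error(error_ecdf(c(1, 13)), "\\[0, 12\\]")
})

test_that("calibration coverage is exact for matched posteriors", {
  # degenerate point-mass-like posteriors centred at the truth
  truth <- runif(300, 0, 2 * pi)
  st <- structure(list(cell_loc = truth, cell_logconc = rep(log(490), 300),
                       seed = 1L), class = "vi_state")
  cal <- calibration_curve(st, truth, levels = c(0.5, 0.9))
  expect_equal(cal$coverage, c(1, 1))
  expect_equal(calibration_curve(st, truth, levels = 0)$coverage, 0)
  # posteriors equal to the generating conditional: coverage matches level
  set.seed(13)
  n <- 2000
  locs <- runif(n, 0, 2 * pi)
  kappa <- 6
  truths <- rvonmises(n, locs, kappa)
  stg <- structure(list(cell_loc = locs, cell_logconc = rep(log(kappa), n),
                        seed = 1L), class = "vi_state")
  calg <- calibration_curve(stg, truths, levels = c(0.5, 0.8, 0.95))
  expect_equal(calg$coverage, c(0.5, 0.8, 0.95), tolerance = 0.06)
})

test_that("stability reproduces hand-computed circular deviations", {
  expect_equal(as.numeric(phase_stability(cbind(rep(1, 4), rep(1, 4)))),
               rep(0, 4))
  s <- phase_stability(matrix(c(0, pi / 6), 1))
  expect_equal(as.numeric(s), 1, tolerance = 1e-9)       # mean dev of {0, pi/6} is 1 h
  anti <- phase_stability(matrix(c(0, pi), 1))
  expect_equal(as.numeric(anti), 6, tolerance = 1e-9)    # tie falls back to run 1
  expect_true(attr(anti, "ties")[1])
  expect_error(phase_stability(matrix(1, 2, 1)), "2 runs")
})

test_that("held-out clock likelihood rewards truth and centres random phases", {
  sim <- cached("sim_hold", std_sim(600, seed = 51, n_ccgs = 0, n_flat = 10))
  cm <- sim$counts
  idx <- 1:300
  train <- subset_cells_f(cm, idx); test <- subset_cells_f(cm, -idx)
  clock <- clock_gene_params()$gene
  out <- holdout_clock_likelihood(train, test, clock,
                                  sim$phases[idx], sim$phases[-idx],
                                  n_null = 50, seed = 3)
  expect_gt(out$score, 3)
  # a random method is, by construction, within the null's spread
  set.seed(14)
  rnd <- holdout_clock_likelihood(train, test, clock,
                                  runif(300, 0, 2 * pi), runif(300, 0, 2 * pi),
                                  n_null = 50, seed = 3)
  expect_lt(abs(rnd$score), 2.5)
  expect_error(holdout_clock_likelihood(train, test, c(clock, "Nope"),
                                        sim$phases[idx], sim$phases[-idx]),
               "Nope")
})

test_that("the Poisson GLM recovers sinusoidal gene parameters", {
  set.seed(15)
  n <- 5000
  th <- runif(n, 0, 2 * pi)
  L <- rpois(n, 8000)
  mu <- -8.2; A <- 0.9; phi <- 2.4
  x <- rpois(n, L * exp(mu + A * cos(th - phi)))
  cm <- phase_counts(matrix(x, n, 1, dimnames = list(NULL, "g")), lib_sizes = L)
  cf <- cyclophase:::clock_glm_fit(cm, "g", th)
  expect_equal(unname(cf[1, "mesor"]), mu, tolerance = 0.05)
  expect_equal(unname(cf[1, "amplitude"]), A, tolerance = 0.05)
  expect_equal(unname(cf[1, "acrophase"]), phi, tolerance = 0.05)
})

test_that("empirical enrichment matches the hypergeometric tail", {
  universe <- sprintf("u%04d", 1:1000)
  target <- universe[1:100]
  de_novo <- c(universe[1:5], universe[501:515])   # overlap 5 of 20
  res <- enrichment_test(de_novo, target, universe, n_null = 1e5, seed = 2)
  exact <- phyper(4, 100, 900, 20, lower.tail = FALSE)
  expect_equal(res$p, exact, tolerance = 5 * sqrt(exact * (1 - exact) / 1e5) / exact)
  expect_gt(res$p, 0); expect_lte(res$p, 1)
  # subset of a small target is strongly enriched
  strong <- enrichment_test(universe[1:10], target, universe, seed = 2)
  expect_lte(strong$p, 0.01)
  # target = universe is never enriched beyond chance
  expect_equal(enrichment_test(universe[1:10], universe, universe, n_null = 200,
                               seed = 2)$p, 1)
  # reproducible under a fixed seed
  expect_identical(enrichment_test(de_novo, target, universe, 500, seed = 7)$p,
                   enrichment_test(de_novo, target, universe, 500, seed = 7)$p)
  expect_error(enrichment_test(character(0), target, universe), "empty")
})

test_that("the PCA angle baseline is exact on circular data and deterministic", {
  n <- 200
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  # two genes whose z-scored expression embeds the circle exactly
  y <- cbind(g1 = round(1000 + 300 * cos(th)), g2 = round(1000 + 300 * sin(th)))
  cm <- phase_counts(y, lib_sizes = rep(2000, n))
  est <- pca_phase_baseline(cm, c("g1", "g2"))
  al <- optimal_shift(est, th)
  expect_lt(max(phase_error_hours(th, al$shifted)), 0.35)
  expect_identical(est, pca_phase_baseline(cm, c("g1", "g2")))
  # pure noise: post-shift median error is ~ 6 h (uninformative)
  set.seed(16)
  noise <- matrix(rpois(2000 * 20, 5), 2000, 20)
  colnames(noise) <- sprintf("n%02d", 1:20)
  cmn <- phase_counts(noise, lib_sizes = rep(1000, 2000))
  estn <- pca_phase_baseline(cmn, colnames(noise))
  aln <- optimal_shift(estn, runif(2000, 0, 2 * pi))
  expect_lt(abs(median(phase_error_hours(runif(2000, 0, 2 * pi), aln$shifted)) - 6),
            0.5)
  expect_error(pca_phase_baseline(cmn, "n01"), "2 genes")
})
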