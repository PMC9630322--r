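# Count simulators and waveform diagnostics.

#' Built-in clock gene parameter table
#'
#' Twelve canonical core clock genes with staggered acrophases (Arntl peak
#' defines hour 0), mesor proportions spanning 1e-5 to 1e-3 and amplitudes
#' between 0.3 and 1.0 natural-log units. This is a synthetic reference table
#' shipped so that simulations need no external data; values are in the range
#' reported for mouse peripheral tissues.
#'
#' @return data.frame with columns `gene`, `mesor` (log proportion),
#'   `amplitude`, `acrophase` (radians).
#' @export
clock_gene_params <- function() {
  genes <- c("Arntl", "Npas2", "Clock", "Nr1d1", "Nr1d2", "Dbp", "Tef", "Hlf",
             "Per1", "Per2", "Per3", "Cry1")
  hours <- c(0, 1, 2, 7, 8, 10, 10.5, 11, 12, 14, 13, 18)  # peak time (h after Arntl)
  mesor_prop <- c(2e-4, 3e-5, 1e-4, 5e-4, 1e-4, 3e-4, 5e-5, 3e-5,
                  1e-4, 2e-4, 5e-5, 1e-3)
  amplitude <- c(0.8, 0.5, 0.3, 1.0, 0.6, 1.0, 0.7, 0.5, 0.6, 0.8, 0.7, 0.4)
  data.frame(gene = genes, mesor = log(mesor_prop), amplitude = amplitude,
             acrophase = hours * pi / 12, stringsAsFactors = FALSE)
}

# fixed pools the simulator samples from (with replacement)
ccg_param_pool <- function(n = 40) {
  # fixed table; deterministic permutation decorrelates mesor from amplitude
  perm <- (seq_len(n) * 17L) %% n + 1L
  data.frame(gene = sprintf("Ccg%02d", seq_len(n)),
             mesor = log(10^seq(-5, -3, length.out = n))[perm],
             amplitude = rep(seq(0.3, 1.0, length.out = 8), length.out = n),
             acrophase = (seq_len(n) * 2 * pi * 0.618) %% (2 * pi),
             stringsAsFactors = FALSE)
}

flat_param_pool <- function(n = 100) {
  data.frame(gene = sprintf("Flat%03d", seq_len(n)),
             mesor = log(10^seq(-5, -3, length.out = n)),
             amplitude = 0, acrophase = 0, stringsAsFactors = FALSE)
}

#' Simulation configuration for the NB generative simulator
#'
#' Describes a synthetic single-cell experiment: cell count, log library size
#' distribution, the discrete phase grid cells are drawn from (4 equally
#' spaced phases mimics a light-dark time course; 23 an unsynchronized
#' culture), and the gene complement (clock genes from a parameter table,
#' clock-controlled genes and flat genes sampled with replacement from fixed
#' pools).
#'
#' @param n_cells number of cells.
#' @param lib_log_mean,lib_log_sd mean and SD of natural-log library size
#'   (defaults: median 10,000 UMI, SD 0.3).
#' @param n_phase_grid number of equally spaced phases (default 4).
#' @param n_flat_genes,n_ccgs counts of flat and clock-controlled genes.
#' @param clock_table data.frame like [clock_gene_params()].
#' @param seed integer seed.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_cells = 1000, lib_log_mean = log(10000), lib_log_sd = 0.3,
                       n_phase_grid = 4, n_flat_genes = 500, n_ccgs = 20,
                       clock_table = clock_gene_params(), seed = 1) {
  stopifnot(n_phase_grid >= 1, n_cells >= 1, lib_log_sd > 0,
            n_flat_genes >= 0, n_ccgs >= 0)
  structure(list(n_cells = n_cells, lib_log_mean = lib_log_mean,
                 lib_log_sd = lib_log_sd, n_phase_grid = n_phase_grid,
                 n_flat_genes = n_flat_genes, n_ccgs = n_ccgs,
                 clock_table = clock_table, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate UMI counts from the NB sinusoidal generative model
#'
#' Cell phases are drawn uniformly from `n_phase_grid` equally spaced phases,
#' log library sizes from a normal distribution, gene parameters from the
#' clock table and the CCG/flat pools (with replacement), and counts from the
#' negative binomial model with the supplied mean-dispersion trend.
#'
#' @param cfg a [sim_config].
#' @param disp a `"dispersion_trend"` (e.g. [constant_dispersion]).
#' @return list with `counts` (a [phase_counts]), `phases` (true radians),
#'   `gene_params` (data.frame incl. `is_clock`, `is_ccg`).
#' @export
simulate_counts <- function(cfg, disp = constant_dispersion(0.1)) {
  set.seed(cfg$seed)
  grid <- seq(0, 2 * pi, length.out = cfg$n_phase_grid + 1)[seq_len(cfg$n_phase_grid)]
  phases <- grid[sample.int(cfg$n_phase_grid, cfg$n_cells, replace = TRUE)]
  L <- pmax(round(exp(stats::rnorm(cfg$n_cells, cfg$lib_log_mean, cfg$lib_log_sd))), 1)
  gp <- cfg$clock_table
  gp$is_clock <- TRUE; gp$is_ccg <- FALSE
  if (cfg$n_ccgs > 0) {
    pool <- ccg_param_pool()
    rows <- pool[sample.int(nrow(pool), cfg$n_ccgs, replace = TRUE), ]
    rows$gene <- sprintf("Ccg%03d", seq_len(cfg$n_ccgs))
    rows$is_clock <- FALSE; rows$is_ccg <- TRUE
    gp <- rbind(gp, rows)
  }
  if (cfg$n_flat_genes > 0) {
    pool <- flat_param_pool()
    rows <- pool[sample.int(nrow(pool), cfg$n_flat_genes, replace = TRUE), ]
    rows$gene <- sprintf("Flat%04d", seq_len(cfg$n_flat_genes))
    rows$is_clock <- FALSE; rows$is_ccg <- FALSE
    gp <- rbind(gp, rows)
  }
  rownames(gp) <- NULL
  n <- cfg$n_cells; p <- nrow(gp)
  loglam <- matrix(gp$mesor, n, p, byrow = TRUE) +
    (cos(phases) %o% cos(gp$acrophase) + sin(phases) %o% sin(gp$acrophase)) *
    rep(gp$amplitude, each = n)
  lam <- exp(loglam)
  m <- L * lam
  delta <- predict(disp, lam)
  x <- stats::rnbinom(n * p, size = 1 / pmax(as.vector(delta), 1e-12),
                      mu = as.vector(m))
  dim(x) <- c(n, p)
  cm <- phase_counts(x, sprintf("cell_%04d", seq_len(n)), gp$gene, lib_sizes = L)
  list(counts = cm, phases = phases, gene_params = gp)
}

#' Read a waveform table
#'
#' TSV with gene ids in the first column and one column per timepoint, header
#' giving timepoint hours; values are transcript proportions. An optional
#' `cycler` logical column flags true cyclers.
#'
#' @param path TSV file.
#' @return list of class `"waveform_table"`: `gene`, `hours`, `proportions`
#'   (genes x timepoints), `cycler`.
#' @export
read_waveform_table <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  gene <- d[[1]]
  cyc_col <- match("cycler", names(d))
  val <- d[, setdiff(seq_along(d), c(1, cyc_col)), drop = FALSE]
  hours <- as.numeric(names(val))
  if (anyNA(hours)) stop("header must give timepoint hours")
  waveform_table(as.matrix(val), hours, gene,
                 cycler = if (!is.na(cyc_col)) as.logical(d[[cyc_col]]) else NULL)
}

#' Construct a waveform table
#'
#' @param proportions genes x timepoints matrix of transcript proportions.
#' @param hours strictly increasing, equally spaced timepoint hours.
#' @param gene gene ids.
#' @param cycler optional logical cycler flags.
#' @return list of class `"waveform_table"`.
#' @export
waveform_table <- function(proportions, hours, gene = rownames(proportions),
                           cycler = NULL) {
  proportions <- as.matrix(proportions)
  if (is.null(gene)) gene <- sprintf("gene_%d", seq_len(nrow(proportions)))
  if (any(proportions < 0)) stop("proportions must be >= 0")
  if (length(hours) != ncol(proportions)) stop("hours/column mismatch")
  dh <- diff(hours)
  if (any(dh <= 0) || max(abs(dh - dh[1])) > 1e-8)
    stop("timepoints must be strictly increasing and equally spaced")
  if (is.null(cycler)) cycler <- rep(NA, nrow(proportions))
  structure(list(gene = gene, hours = hours, proportions = proportions,
                 cycler = cycler), class = "waveform_table")
}

#' Simulate cells from measured waveforms
#'
#' Poisson counts driven by per-timepoint gene proportions: flat genes
#' (cycler flag `FALSE`) have their proportions replaced by the
#' across-timepoint median; library sizes are drawn log10-normal (defaults:
#' median 5000 UMI, SD 0.5 log10 units); each cell's expected count is its
#' gene proportion times its library size. The true cell phase is the
#' timepoint hour converted to radians (`hour * pi/12`, mod `2*pi`).
#'
#' @param wt a [waveform_table].
#' @param cells_per_timepoint cells simulated per timepoint (default 200).
#' @param lib_log10_mean,lib_log10_sd log10 library size distribution.
#' @param seed integer seed.
#' @return list with `counts` (a [phase_counts]) and `phases` (true radians).
#' @export
simulate_from_waveforms <- function(wt, cells_per_timepoint = 200,
                                    lib_log10_mean = log10(5000),
                                    lib_log10_sd = 0.5, seed = 1) {
  set.seed(seed)
  prop <- wt$proportions
  flat <- which(!is.na(wt$cycler) & !wt$cycler)
  if (length(flat))
    prop[flat, ] <- matrix(apply(prop[flat, , drop = FALSE], 1, stats::median),
                           length(flat), ncol(prop))
  tp <- rep(seq_along(wt$hours), each = cells_per_timepoint)
  n <- length(tp)
  L <- pmax(round(10^stats::rnorm(n, lib_log10_mean, lib_log10_sd)), 1)
  lam <- t(prop)[tp, , drop = FALSE]            # cells x genes
  x <- stats::rpois(length(lam), as.vector(L * lam))
  dim(x) <- dim(lam)
  cm <- phase_counts(x, sprintf("cell_%05d", seq_len(n)), wt$gene, lib_sizes = L)
  list(counts = cm, phases = (wt$hours[tp] * pi / 12) %% (2 * pi),
       timepoint = wt$hours[tp])
}

#' Circadian FFT fraction of a waveform
#'
#' Amplitude of the 24 h Fourier component divided by the sum of all non-DC
#' component amplitudes (one-sided spectrum). Requires equally spaced
#' timepoints spanning a whole number of 24 h periods. A constant signal
#' returns 0 with attribute `flagged = TRUE`.
#'
#' @param values proportions at each timepoint.
#' @param hours equally spaced timepoint hours.
#' @return fraction in `[0, 1]`.
#' @export
circadian_fft_fraction <- function(values, hours) {
  n <- length(values)
  if (length(hours) != n) stop("length mismatch")
  dh <- diff(hours)
  if (any(dh <= 0) || max(abs(dh - dh[1])) > 1e-8) stop("irregular sampling")
  span <- n * dh[1]
  k24 <- span / 24
  if (abs(k24 - round(k24)) > 1e-8)
    stop("timepoints must span a whole number of 24 h periods")
  k24 <- round(k24)
  amps <- Mod(stats::fft(values))[2:(floor(n / 2) + 1)]
  tot <- sum(amps)
  if (tot < 1e-12 * max(abs(values), 1)) {
    out <- 0; attr(out, "flagged") <- TRUE
    return(out)
  }
  out <- amps[k24] / tot
  attr(out, "flagged") <- FALSE
  out
}

#' Likelihood ratio statistic of a waveform against a flat profile
#'
#' `2 * (loglik under the gene's waveform - loglik under the flat
#' across-timepoint median)` for Poisson counts with expected value
#' `proportion * library size`.
#'
#' @param x counts for one gene, one per cell.
#' @param timepoint_idx timepoint index (into `proportions`) of each cell.
#' @param proportions per-timepoint proportions of the gene.
#' @param lib_sizes per-cell library sizes.
#' @return scalar LRT statistic.
#' @export
waveform_lrt <- function(x, timepoint_idx, proportions, lib_sizes) {
  stopifnot(length(x) == length(timepoint_idx), length(x) == length(lib_sizes))
  mu1 <- pmax(proportions[timepoint_idx] * lib_sizes, 1e-12)
  mu0 <- pmax(stats::median(proportions) * lib_sizes, 1e-12)
  2 * (sum(stats::dpois(x, mu1, log = TRUE)) - sum(stats::dpois(x, mu0, log = TRUE)))
}

#' Harmonic-regression cycler calls on a waveform table
#'
#' Per-gene F-test of a 24 h cosinor fit (`~ cos + sin`) against an
#' intercept-only model on the waveform proportions, with Benjamini-Hochberg
#' correction. This is a deliberately simple rhythm caller used to partition
#' genes into cyclers and flat genes; it is not a reimplementation of
#' non-parametric rank-based rhythm detectors.
#'
#' @param wt a [waveform_table] with at least 8 timepoints.
#' @param q_threshold BH q-value threshold (default 0.05).
#' @return data.frame with `gene`, `p`, `q`, `cycler`.
#' @export
harmonic_cycler_call <- function(wt, q_threshold = 0.05) {
  if (length(wt$hours) < 8) stop("at least 8 timepoints required")
  co <- cos(2 * pi * wt$hours / 24); si <- sin(2 * pi * wt$hours / 24)
  X <- cbind(1, co, si)
  pvals <- apply(wt$proportions, 1, function(y) {
    f1 <- stats::lm.fit(X, y)
    rss1 <- sum(f1$residuals^2)
    rss0 <- sum((y - mean(y))^2)
    df2 <- length(y) - 3
    if (rss1 < 1e-30) return(if (rss0 > 1e-30) 0 else 1)
    Fstat <- ((rss0 - rss1) / 2) / (rss1 / df2)
    stats::pf(Fstat, 2, df2, lower.tail = FALSE)
  })
  q <- stats::p.adjust(pvals, "BH")
  data.frame(gene = wt$gene, p = pvals, q = q, cycler = q < q_threshold,
             stringsAsFactors = FALSE)
}

#' Jittered clock acrophase priors
#'
#' Builds the informative-but-imperfect acrophase priors used in simulation
#' studies: prior locations are the true clock acrophases plus independent
#' normal shifts (SD in hours, default 2 h), and the von Mises scale is set
#' so the central 95% prior interval has a given width (default 4 h).
#'
#' @param clock_table data.frame like [clock_gene_params()].
#' @param jitter_sd_hours SD of the location shift, hours.
#' @param interval_hours width of the central `level` interval, hours.
#' @param level interval mass (default 0.95).
#' @param seed integer seed for the shifts.
#' @param ... passed to [prior_spec] (e.g. `reference_gene`).
#' @return a [prior_spec] with von Mises acrophase priors for the clock genes.
#' @export
jittered_acrophase_prior <- function(clock_table, jitter_sd_hours = 2,
                                     interval_hours = 4, level = 0.95,
                                     seed = 1, ...) {
  set.seed(seed)
  loc <- (clock_table$acrophase +
            stats::rnorm(nrow(clock_table), 0, jitter_sd_hours * pi / 12)) %% (2 * pi)
  names(loc) <- clock_table$gene
  conc <- vm_conc_for_interval(interval_hours / 2 * pi / 12, level)
  prior_spec(clock_table$gene, acrophase_loc = loc, acrophase_conc = conc, ...)
}
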