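#' Fit circadian cell phases from single-cell UMI counts
#'
#' The main fitting function. Alternates (Step 1) stochastic variational
#' optimization of the joint posterior over cell phases and the parameters of
#' the current cycling genes with (Step 2) conditional fits of all remaining
#' genes and selection of de novo cyclers. After each iteration the Bayesian
#' evidence of the core clock genes and its log10 Bayes factor against a fit
#' on a permuted clock matrix are computed; the loop stops when the evidence
#' worsens, when the fit is no better than random (Bayes factor <= 0), when
#' Step 2 finds no new cyclers, or at `max_iterations`. The state from the
#' best-evidence iteration is returned, so de novo cyclers are only kept if
#' they do not worsen the clock evidence.
#'
#' Phases are radians in `[0, 2*pi)`; hour conversions use `hours = radians *
#' 12/pi`, with hour 0 defined by the acrophase of the reference gene.
#'
#' @param cm a [phase_counts] object (or a cells-by-genes count matrix).
#' @param clock_genes character vector of core clock gene ids present in `cm`.
#' @param prior a [prior_spec]; default is a non-informative prior with the
#'   first clock gene as reference.
#' @param disp a `"dispersion_trend"`; fit from the data by default.
#' @param control a [phase_control].
#' @param verbose print per-iteration progress.
#' @return an object of class `"cyclophase"`; see [summary.cyclophase],
#'   [predict.cyclophase], [coef.cyclophase].
#' @examples
#' sim <- simulate_counts(sim_config(n_cells = 80, n_flat_genes = 30, n_ccgs = 0,
#'                                   seed = 1), constant_dispersion(0.1))
#' fit <- cyclophase(sim$counts, clock_gene_params()$gene,
#'                   control = phase_control(max_iterations = 1, epochs = 40, seed = 1))
#' predict(fit, type = "hours")[1:5]
#' @export
cyclophase <- function(cm, clock_genes, prior = NULL, disp = NULL,
                       control = phase_control(), verbose = FALSE) {
  if (!inherits(cm, "phase_counts")) cm <- phase_counts(cm)
  if (is.null(prior)) prior <- prior_spec(clock_genes)
  if (is.null(disp)) disp <- default_dispersion(cm, control$proportion_floor)
  missing <- setdiff(clock_genes, cm$gene_ids)
  if (length(missing))
    stop("clock gene(s) absent from count matrix: ", paste(missing, collapse = ", "))

  props <- pseudobulk_proportions(cm)
  candidates <- setdiff(names(props)[props > control$proportion_floor], clock_genes)

  cycling <- clock_genes
  states <- list(); evidence <- numeric(0); bf <- numeric(0)
  n_cycling <- integer(0)
  stopping <- "max_iterations"
  ev_seed <- control$seed + 7777L
  summaries <- NULL
  ev_perm <- NULL

  for (it in seq_len(control$max_iterations)) {
    if (it == 1) {
      st <- vi_init(cm, prior, cycling, disp, seed = control$seed)
    } else {
      st <- extend_state(states[[it - 1]], cycling, cm, prior,
                         seed = control$seed + it, summaries = summaries)
    }
    st$seed <- control$seed + it
    if (verbose) message(sprintf("iteration %d: optimizing %d cycling genes", it,
                                 length(cycling)))
    st <- vi_optimize(st, cm, prior, disp, control)
    states[[it]] <- st
    # average the importance-sampling bound over a few seeds so iteration
    # comparisons are not dominated by single-draw Monte Carlo noise
    ev <- mean(vapply(0:2, function(k)
      clock_evidence(st, cm, prior, disp, clock_genes,
                     n_samples = control$evidence_samples,
                     seed = ev_seed + k), numeric(1)))
    if (is.null(ev_perm)) {
      # the permuted-clock reference fit does not depend on the iteration
      ev_perm <- permuted_clock_evidence(cm, prior, disp, clock_genes, control,
                                         seed = control$seed + 31L, ev_seed = ev_seed)
    }
    evidence <- c(evidence, ev)
    bf <- c(bf, (ev - ev_perm) / log(10))
    n_cycling <- c(n_cycling, length(cycling))
    if (verbose) message(sprintf("  clock evidence %.1f, log10 BF %.1f", ev,
                                 bf[it]))
    if (bf[it] <= 0) { stopping <- "worse_than_random"; break }
    if (it > 1 && ev < evidence[it - 1] - control$evidence_tol) {
      stopping <- "evidence_worsened"; break
    }
    if (it == control$max_iterations) { stopping <- "max_iterations"; break }
    # Step 2: conditional fits of the non-cycling candidates
    pool <- setdiff(candidates, cycling)
    if (length(pool) == 0) { stopping <- "converged"; break }
    summaries <- fit_gene_profiles(st, cm, prior, disp, pool, control)
    summaries$residual <- amplitude_pearson_residual(summaries)
    new_genes <- select_de_novo(summaries, control$q_threshold,
                                control$residual_threshold, exclude = cycling)
    if (verbose) message(sprintf("  %d de novo cyclers selected", length(new_genes)))
    if (length(new_genes) == 0) { stopping <- "converged"; break }
    cycling <- c(cycling, new_genes)
  }

  # latest iteration whose evidence is within tolerance of the best: richer
  # cycling sets are preferred when the clock evidence is statistically tied
  best_it <- max(which(evidence >= max(evidence) - control$evidence_tol))
  best <- states[[best_it]]
  phases <- phase_point_estimates(best)
  names(phases) <- cm$cell_ids
  hdr <- lapply(control$credible_levels, function(lv)
    lapply(seq_along(phases), function(i) hdr_interval(best, i, lv)))
  names(hdr) <- sprintf("%g", control$credible_levels)

  structure(list(
    state = best, states = states, phases = phases,
    hours = phases * 12 / pi,
    hdr = hdr, credible_levels = control$credible_levels,
    cycling_genes = best$genes,
    de_novo = setdiff(best$genes, clock_genes),
    clock_genes = clock_genes,
    gene_summaries = summaries,
    trace = data.frame(iteration = seq_along(evidence), evidence = evidence,
                       log10_bayes_factor = bf, n_cycling = n_cycling),
    stopping_reason = stopping, best_iteration = best_it,
    prior = prior, disp = disp, control = control,
    n_cells = nrow(cm$counts), n_genes = ncol(cm$counts),
    call = match.call()
  ), class = "cyclophase")
}

# dispersion default: mean-dispersion trend when enough genes clear the
# floor, pooled constant otherwise
default_dispersion <- function(cm, proportion_floor = 1e-5) {
  props <- pseudobulk_proportions(cm)
  if (sum(props > proportion_floor) >= 50)
    fit_dispersion_trend(cm, degree = 2, proportion_floor = proportion_floor)
  else
    fit_dispersion_trend(cm, degree = 0, proportion_floor = proportion_floor)
}

# evidence of a fresh fit on a clock matrix with cells permuted independently
# within each clock gene column (stratified by library size, see
# permute_clock_columns)
permuted_clock_evidence <- function(cm, prior, disp, clock_genes, control, seed,
                                    ev_seed) {
  cm_perm <- permute_clock_columns(cm, clock_genes, seed)
  st0 <- vi_init(cm_perm, prior, clock_genes, disp, seed = seed)
  stp <- vi_optimize(st0, cm_perm, prior, disp, control)
  mean(vapply(0:2, function(k)
    clock_evidence(stp, cm_perm, prior, disp, clock_genes,
                   n_samples = control$evidence_samples,
                   seed = ev_seed + k), numeric(1)))
}

# warm start: keep cell posteriors and previously fitted gene parameters,
# append parameters for newly added genes (initialized from their Step-2
# conditional fits where available)
extend_state <- function(st, genes, cm, prior, seed, summaries = NULL) {
  new <- setdiff(genes, st$genes)
  if (length(new) == 0) { st$genes <- genes; return(st) }
  set.seed(seed)
  rp <- resolve_prior(prior, cm, new)
  k <- length(new)
  phi0 <- stats::runif(k, 0, 2 * pi)
  a0 <- rep(0, k)
  g0 <- rep(0, k)
  if (!is.null(summaries)) {
    hit <- match(new, summaries$gene)
    ok <- !is.na(hit)
    phi0[ok] <- summaries$map_acrophase[hit[ok]]
    R <- rp$amp_max - rp$amp_min
    u <- pmin(pmax((summaries$map_amplitude[hit[ok]] - rp$amp_min) / R, 0.01), 0.99)
    a0[ok] <- stats::qlogis(u)
    g0[ok] <- stats::qlogis(pmin(pmax(summaries$map_q_fraction[hit[ok]], 0.05), 0.95))
  }
  st$genes <- c(st$genes, new)
  st$m_loc <- c(st$m_loc, unname(rp$mesor_loc))
  st$m_logscale <- c(st$m_logscale, rep(log(0.1), k))
  st$phi_loc <- c(st$phi_loc, phi0)
  st$phi_logconc <- c(st$phi_logconc, rep(log(0.5), k))
  st$a_loc <- c(st$a_loc, a0)
  st$a_logscale <- c(st$a_logscale, rep(log(0.5), k))
  st$gamma_logit <- c(st$gamma_logit, g0)
  st$is_ref <- c(st$is_ref, rep(FALSE, k))
  st
}

# ---- S3 methods ----------------------------------------------------------

#' @export
print.cyclophase <- function(x, ...) {
  cat(sprintf("cyclophase fit: %d cells, %d genes\n", x$n_cells, x$n_genes))
  cat(sprintf("  cycling genes: %d (%d clock + %d de novo)\n",
              length(x$cycling_genes), length(x$clock_genes), length(x$de_novo)))
  cat(sprintf("  iterations: %d (best %d), stopping: %s\n",
              nrow(x$trace), x$best_iteration, x$stopping_reason))
  cat(sprintf("  clock evidence %.1f nats, log10 Bayes factor %.1f\n",
              x$trace$evidence[x$best_iteration],
              x$trace$log10_bayes_factor[x$best_iteration]))
  invisible(x)
}

#' Summary of a circadian phase fit
#'
#' @param object a `"cyclophase"` fit.
#' @param ... unused.
#' @return the fit, invisibly; prints the evidence trace, phase-concentration
#'   quartiles and the de novo cycler list.
#' @export
summary.cyclophase <- function(object, ...) {
  print(object)
  cat("\nEvidence trace:\n")
  print(object$trace, row.names = FALSE)
  conc <- exp(object$state$cell_logconc)
  cat("\nPosterior phase concentration quartiles:",
      paste(signif(stats::quantile(conc, c(0.25, 0.5, 0.75)), 3), collapse = " / "),
      "\n")
  if (length(object$de_novo))
    cat("\nDe novo cyclers:", paste(object$de_novo, collapse = ", "), "\n")
  invisible(object)
}

#' Gene parameter point estimates
#'
#' MAP (variational location) parameter estimates of the cycling genes:
#' mesor (log proportion), amplitude (log units), acrophase (radians and
#' hours), and the fitted cycler probability.
#'
#' @param object a `"cyclophase"` fit.
#' @param ... unused.
#' @return data.frame, one row per cycling gene.
#' @export
coef.cyclophase <- function(object, ...) {
  st <- object$state
  R <- object$prior$amp_bounds[2] - object$prior$amp_bounds[1]
  data.frame(gene = st$genes,
             mesor = st$m_loc,
             amplitude = object$prior$amp_bounds[1] + R * stats::plogis(st$a_loc),
             acrophase = st$phi_loc %% (2 * pi),
             acrophase_hours = (st$phi_loc %% (2 * pi)) * 12 / pi,
             gamma = stats::plogis(st$gamma_logit),
             is_clock = st$genes %in% object$clock_genes,
             stringsAsFactors = FALSE)
}

#' Predicted cell phases or fitted means
#'
#' @param object a `"cyclophase"` fit.
#' @param type `"phase"` (radians), `"hours"`, or `"proportion"` (fitted
#'   expected transcript proportions for the cycling genes, cells x genes;
#'   multiply by library sizes for expected counts).
#' @param ... unused.
#' @export
predict.cyclophase <- function(object, type = c("phase", "hours", "proportion"), ...) {
  type <- match.arg(type)
  if (type == "phase") return(object$phases)
  if (type == "hours") return(object$hours)
  exp(fitted_log_proportions(object))
}

fitted_log_proportions <- function(object) {
  cf <- coef(object)
  theta <- object$phases
  loglam <- outer(rep(1, length(theta)), cf$mesor) +
    (cos(theta) %o% cos(cf$acrophase) + sin(theta) %o% sin(cf$acrophase)) *
    rep(cf$amplitude * (cf$gamma > 0.5), each = length(theta))
  dimnames(loglam) <- list(names(theta), cf$gene)
  loglam
}

#' @export
fitted.cyclophase <- function(object, ...) exp(fitted_log_proportions(object))

#' Pearson residuals of the fitted count model
#'
#' `(x - m) / sqrt(m + delta * m^2)` for the cycling genes at the MAP gene
#' parameters and posterior mean phases; requires the counts the model was
#' fit to.
#'
#' @param object a `"cyclophase"` fit.
#' @param cm the [phase_counts] used for fitting.
#' @param ... unused.
#' @export
residuals.cyclophase <- function(object, cm, ...) {
  if (!inherits(cm, "phase_counts")) cm <- phase_counts(cm)
  sub <- subset_genes(cm, object$cycling_genes)
  lam <- exp(fitted_log_proportions(object))
  m <- sub$lib_sizes * lam
  delta <- predict(object$disp, lam)
  (sub$counts - m) / sqrt(m + delta * m^2)
}

#' Simulate counts from a fitted phase model
#'
#' Draws negative binomial counts for the cycling genes at the MAP gene
#' parameters and posterior mean phases (library sizes must be supplied since
#' the fit does not store the data).
#'
#' @param object a `"cyclophase"` fit.
#' @param nsim number of replicate matrices.
#' @param seed integer seed.
#' @param lib_sizes per-cell library sizes.
#' @param ... unused.
#' @return a list of `nsim` count matrices.
#' @export
simulate.cyclophase <- function(object, nsim = 1, seed = 1, lib_sizes, ...) {
  set.seed(seed)
  lam <- exp(fitted_log_proportions(object))
  m <- lib_sizes * lam
  delta <- predict(object$disp, lam)
  size <- 1 / pmax(delta, 1e-12)
  lapply(seq_len(nsim), function(s) {
    out <- stats::rnbinom(length(m), size = size, mu = m)
    dim(out) <- dim(m); dimnames(out) <- dimnames(m)
    out
  })
}

#' Plot a circadian phase fit
#'
#' Left: histogram of posterior mean phases (hours). Right: MAP amplitude vs
#' mesor of the Step-2 gene fits with de novo cyclers highlighted (when Step 2
#' was run).
#'
#' @param x a `"cyclophase"` fit.
#' @param ... passed to [graphics::hist].
#' @export
plot.cyclophase <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, if (is.null(x$gene_summaries)) 1 else 2))
  on.exit(graphics::par(op))
  graphics::hist(x$hours, breaks = seq(0, 24, by = 1),
                 main = "Posterior mean cell phases", xlab = "phase (h)", ...)
  if (!is.null(x$gene_summaries)) {
    gs <- x$gene_summaries
    denovo <- gs$gene %in% x$de_novo
    graphics::plot(gs$map_mesor, gs$map_amplitude,
                   col = ifelse(denovo, "firebrick", "grey50"),
                   pch = ifelse(denovo, 19, 1),
                   xlab = "MAP mesor (log proportion)", ylab = "MAP amplitude",
                   main = "Gene fits (de novo cyclers in red)")
  }
  invisible(x)
}
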