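# File formats: count matrices in (10x-dialect MatrixMarket triplet or dense
# TSV), gene lists, and the TSV phase report.

#' Read a UMI count matrix
#'
#' Two formats are supported. `"mtx"`: a directory (or matrix.mtx path) in
#' the 10x MatrixMarket dialect — `matrix.mtx` (genes x cells),
#' `barcodes.tsv`, `features.tsv`/`genes.tsv` (column 2, the symbol, is used
#' for gene matching; falls back to column 1). `"tsv"`: dense cells x genes
#' table, header row of gene ids, first column of cell ids. Cells with
#' library size below `lib_floor` are dropped with a message.
#'
#' @param path file or directory path.
#' @param format `"mtx"`, `"tsv"`, or `"auto"` (by extension/contents).
#' @param lib_floor minimum UMI count per retained cell (default 1000).
#' @return a [phase_counts] object.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "tsv"), lib_floor = 1000) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "mtx") {
    dirp <- if (dir.exists(path)) path else dirname(path)
    mtx <- if (dir.exists(path)) file.path(path, "matrix.mtx") else path
    m <- Matrix::readMM(mtx)
    bc <- utils::read.delim(file.path(dirp, "barcodes.tsv"), header = FALSE,
                            stringsAsFactors = FALSE)[[1]]
    featf <- file.path(dirp, "features.tsv")
    if (!file.exists(featf)) featf <- file.path(dirp, "genes.tsv")
    feat <- utils::read.delim(featf, header = FALSE, stringsAsFactors = FALSE)
    genes <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]
    if (nrow(m) != length(genes) || ncol(m) != length(bc))
      stop("dimension mismatch between matrix and sidecar files")
    counts <- t(as.matrix(m))                 # cells x genes
    dimnames(counts) <- list(bc, genes)
  } else {
    d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    counts <- as.matrix(d[, -1, drop = FALSE])
    rownames(counts) <- d[[1]]
  }
  if (any(counts != round(counts))) stop("non-integer count entries")
  lib <- rowSums(counts)
  drop <- lib < lib_floor
  if (any(drop))
    message(sprintf("dropping %d cell(s) with library size < %g", sum(drop), lib_floor))
  counts <- counts[!drop, , drop = FALSE]
  if (nrow(counts) == 0) stop("no cells pass the library size floor")
  phase_counts(counts)
}

#' Write a count matrix
#'
#' Inverse of [read_counts]: `"tsv"` writes the dense cells x genes table;
#' `"mtx"` writes `matrix.mtx` + `barcodes.tsv` + `features.tsv` (genes x
#' cells) into a directory.
#'
#' @param cm a [phase_counts] object.
#' @param path output file (tsv) or directory (mtx).
#' @param format `"tsv"` or `"mtx"`.
#' @export
write_counts <- function(cm, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- data.frame(cell_id = cm$cell_ids, cm$counts, check.names = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(t(cm$counts), sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(cm$cell_ids, file.path(path, "barcodes.tsv"))
    utils::write.table(data.frame(cm$gene_ids, cm$gene_ids),
                       file.path(path, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# encode HDR arcs as "startH-endH" hour strings joined by ";"
format_arcs_hours <- function(arcs) {
  paste(sprintf("%.3f-%.3f", arcs[, "start"] * 12 / pi,
                arcs[, "end"] * 12 / pi), collapse = ";")
}

#' Write the phase report of a fit
#'
#' Writes four TSV files into `dir`: `cells.tsv` (cell id, phase radians,
#' phase hours in `[0, 24)`, HDR arcs per credible level), `genes.tsv` (MAP
#' gene parameters, cycler statistics, clock/de novo flags), `trace.tsv`
#' (per-iteration evidence and Bayes factor), and `run.tsv` (seed, stopping
#' reason, config hash).
#'
#' @param fit a `"cyclophase"` fit.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_phase_report <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- data.frame(cell_id = names(fit$phases),
                      phase_radians = as.numeric(fit$phases),
                      phase_hours = as.numeric(fit$hours))
  for (lv in names(fit$hdr))
    cells[[paste0("hdr_", lv)]] <- vapply(fit$hdr[[lv]], format_arcs_hours, character(1))
  utils::write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cf <- coef(fit)
  genes <- data.frame(gene = cf$gene, map_mesor = cf$mesor,
                      map_amplitude = cf$amplitude, map_acrophase = cf$acrophase,
                      gamma = cf$gamma,
                      is_clock = cf$is_clock,
                      is_de_novo = cf$gene %in% fit$de_novo)
  if (!is.null(fit$gene_summaries)) {
    gs <- fit$gene_summaries
    extra <- data.frame(gene = gs$gene, map_mesor = gs$map_mesor,
                        map_amplitude = gs$map_amplitude,
                        map_acrophase = gs$map_acrophase,
                        gamma = gs$map_q_fraction,
                        is_clock = FALSE,
                        is_de_novo = gs$gene %in% fit$de_novo)
    genes <- rbind(genes, extra[!extra$gene %in% genes$gene, ])
    genes$map_q_fraction <- gs$map_q_fraction[match(genes$gene, gs$gene)]
    genes$residual <- gs$residual[match(genes$gene, gs$gene)]
  }
  utils::write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fit$trace, file.path(dir, "trace.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- fit$control
  run <- data.frame(
    key = c("seed", "stopping_reason", "best_iteration", "n_cells", "n_genes",
            "config_hash"),
    value = c(cfg$seed, fit$stopping_reason, fit$best_iteration, fit$n_cells,
              fit$n_genes, config_hash(cfg)))
  utils::write.table(run, file.path(dir, "run.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

config_hash <- function(control) {
  s <- paste(names(control), vapply(control, function(v) paste(format(v), collapse = ","),
                                    character(1)), collapse = ";")
  # small stable FNV-1a style hash; avoids external digest dependencies
  h <- 216613626
  for (ch in utf8ToInt(s)) h <- (bitwXor(as.integer(h), ch) * 16777619) %% 268435456
  sprintf("%07x", as.integer(h))
}
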