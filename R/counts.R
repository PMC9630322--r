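#' UMI count matrix container
#'
#' Bundles an integer cells-by-genes UMI count matrix with cell and gene
#' identifiers and per-cell library sizes (row sums unless overridden).
#' All model fitting and simulation functions in the package take and return
#' this container.
#'
#' @param counts numeric matrix (cells x genes) of non-negative integers, or a
#'   `Matrix` sparse matrix (densified on construction; datasets targeted here
#'   fit comfortably in memory).
#' @param cell_ids,gene_ids character identifiers; default taken from dimnames
#'   or generated.
#' @param lib_sizes optional per-cell library sizes; defaults to row sums.
#' @return an object of class `"phase_counts"`: a list with elements `counts`,
#'   `cell_ids`, `gene_ids`, `lib_sizes`.
#' @export
phase_counts <- function(counts, cell_ids = NULL, gene_ids = NULL, lib_sizes = NULL) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be finite non-negative integers")
  storage.mode(counts) <- "double"
  n <- nrow(counts); p <- ncol(counts)
  if (is.null(cell_ids)) cell_ids <- rownames(counts)
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- colnames(counts)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%d", seq_len(p))
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (length(cell_ids) != n || length(gene_ids) != p) stop("id length mismatch")
  if (is.null(lib_sizes)) lib_sizes <- rowSums(counts)
  if (any(lib_sizes <= 0)) stop("every retained cell must have library size > 0")
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
                 lib_sizes = as.numeric(lib_sizes)),
            class = "phase_counts")
}

#' @export
print.phase_counts <- function(x, ...) {
  cat(sprintf("phase_counts: %d cells x %d genes, median library size %s\n",
              nrow(x$counts), ncol(x$counts),
              format(stats::median(x$lib_sizes), big.mark = ",")))
  invisible(x)
}

#' @export
dim.phase_counts <- function(x) dim(x$counts)

# subset by gene ids (keeps lib sizes of the full transcriptome)
subset_genes <- function(cm, genes) {
  idx <- match(genes, cm$gene_ids)
  if (anyNA(idx)) stop("gene(s) not present: ", paste(genes[is.na(idx)], collapse = ", "))
  phase_counts(cm$counts[, idx, drop = FALSE], cm$cell_ids, cm$gene_ids[idx], cm$lib_sizes)
}

subset_cells <- function(cm, idx) {
  phase_counts(cm$counts[idx, , drop = FALSE], cm$cell_ids[idx], cm$gene_ids,
               cm$lib_sizes[idx])
}

#' Pseudobulk gene proportions
#'
#' Summed counts per gene over all cells divided by the total count, the
#' expression measure used by the analysis-gene floor (default 1e-5).
#'
#' @param cm a [phase_counts] object.
#' @return named numeric vector of proportions.
#' @export
pseudobulk_proportions <- function(cm) {
  p <- colSums(cm$counts) / sum(cm$lib_sizes)
  names(p) <- cm$gene_ids
  p
}
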