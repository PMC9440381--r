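#' Construct a validated count matrix
#'
#' A count matrix bundles integer read counts (genes x samples) with one
#' positive gene length per gene. Gene and sample identifiers are taken from
#' the dimnames and must be unique.
#'
#' @param counts Integer matrix, genes in rows, samples in columns, with
#'   complete dimnames.
#' @param gene_lengths Named numeric vector of gene lengths in bases, one
#'   entry per gene of `counts`.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `gene_lengths`, `gene_ids`, `sample_ids`.
#' @export
#' @examples
#' m <- matrix(c(3L, 5L, 0L, 7L), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' cm <- count_matrix(m, c(g1 = 1000, g2 = 2000))
count_matrix <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene row names and sample column names", call. = FALSE)
  }
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (anyDuplicated(gene_ids)) stop("duplicate gene IDs", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs", call. = FALSE)
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  if (anyNA(counts)) stop("counts contain missing values", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (is.null(names(gene_lengths))) {
    if (length(gene_lengths) != length(gene_ids)) {
      stop("gene_lengths must be named or match the gene count", call. = FALSE)
    }
    names(gene_lengths) <- gene_ids
  }
  missing_len <- setdiff(gene_ids, names(gene_lengths))
  if (length(missing_len) > 0) {
    stop("missing gene length for: ", paste(utils::head(missing_len, 5), collapse = ", "),
         call. = FALSE)
  }
  gene_lengths <- as.numeric(gene_lengths[gene_ids])
  names(gene_lengths) <- gene_ids
  if (anyNA(gene_lengths) || any(gene_lengths <= 0)) {
    stop("gene lengths must be positive", call. = FALSE)
  }
  structure(list(counts = counts, gene_lengths = gene_lengths,
                 gene_ids = gene_ids, sample_ids = sample_ids),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  cat(sprintf("  total reads: %s\n", format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' Construct validated sample group labels
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param group Character or factor with values `"case"` / `"control"`,
#'   one per sample.
#' @return A named factor with levels `control`, `case`, class
#'   `sample_labels`.
#' @export
sample_labels <- function(sample_ids, group) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs in labels", call. = FALSE)
  group <- as.character(group)
  if (length(group) != length(sample_ids)) {
    stop("one group label per sample required", call. = FALSE)
  }
  bad <- setdiff(unique(group), c("case", "control"))
  if (length(bad) > 0) {
    stop("group labels must be 'case' or 'control', found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- factor(group, levels = c("control", "case"))
  names(out) <- sample_ids
  if (!all(c("case", "control") %in% group)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  class(out) <- c("sample_labels", "factor")
  out
}

# Check that labels cover exactly the samples of a matrix-like object and
# return them in that column order.
align_labels <- function(labels, sample_ids) {
  if (!all(sample_ids %in% names(labels))) {
    stop("missing group label for: ",
         paste(utils::head(setdiff(sample_ids, names(labels)), 5), collapse = ", "),
         call. = FALSE)
  }
  out <- labels[sample_ids]
  class(out) <- c("sample_labels", "factor")
  out
}

#' Construct a validated TPM matrix
#'
#' Every sample column of a TPM matrix sums to 1e6. Matrices produced
#' internally are validated tightly; externally loaded matrices (which may
#' have been rounded) are accepted with a warning when a column deviates by
#' more than 0.1%.
#'
#' @param values Nonnegative numeric matrix, genes x samples, with dimnames.
#' @param external Relax the column-sum check for a deposited/rounded matrix.
#' @return A numeric matrix of class `tpm_matrix`.
#' @export
tpm_matrix <- function(values, external = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("TPM matrix must have gene row names and sample column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene IDs", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate sample IDs", call. = FALSE)
  if (!is.numeric(values) || anyNA(values)) stop("TPM values must be numeric", call. = FALSE)
  if (any(values < 0)) stop("TPM values must be nonnegative", call. = FALSE)
  dev <- abs(colSums(values) - 1e6) / 1e6
  if (external) {
    if (any(dev > 1e-3)) {
      warning(sprintf("%d sample column(s) deviate from a 1e6 TPM sum by > 0.1%%",
                      sum(dev > 1e-3)), call. = FALSE)
    }
  } else if (any(dev > 1e-6)) {
    stop("TPM columns must sum to 1e6 (relative tolerance 1e-6)", call. = FALSE)
  }
  class(values) <- c("tpm_matrix", class(values))
  values
}
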