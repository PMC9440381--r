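#' Normalize read counts to transcripts per million
#'
#' Per sample, each gene's count is divided by its length in kilobases to
#' give a per-kilobase rate, and the rates are rescaled to sum to one
#' million: `TPM_g = rate_g / sum(rate) * 1e6` with
#' `rate_g = count_g / (length_g / 1000)`.
#'
#' @param counts A [count_matrix()].
#' @return A [tpm_matrix()] whose columns each sum to 1e6.
#' @export
#' @examples
#' m <- matrix(c(100L, 300L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' compute_tpm(count_matrix(m, c(g1 = 2000, g2 = 1000)))
compute_tpm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  if (any(colSums(counts$counts) == 0)) {
    stop("all-zero sample column: TPM normalization undefined", call. = FALSE)
  }
  rate <- counts$counts / (counts$gene_lengths / 1000)
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  dimnames(tpm) <- dimnames(counts$counts)
  tpm_matrix(tpm)
}

#' Log-transform a TPM matrix
#'
#' Elementwise `log2(tpm + pseudo_count)`; strictly monotone in TPM.
#'
#' @param tpm A [tpm_matrix()] (or plain nonnegative matrix).
#' @param pseudo_count Positive pseudo-count, default 1.
#' @return Numeric matrix with attribute `scale_tag = "log_tpm"`.
#' @export
log_transform <- function(tpm, pseudo_count = 1) {
  if (pseudo_count <= 0) stop("pseudo_count must be > 0", call. = FALSE)
  out <- log2(unclass(tpm) + pseudo_count)
  attr(out, "scale_tag") <- "log_tpm"
  out
}

#' Filter genes by total read count
#'
#' Keeps genes whose total count across all samples is strictly greater
#' than `min_total`, preserving order. This is the read-count filter used
#' before the volcano comparison (interpreted as a total over samples with
#' strict inequality).
#'
#' @param counts A [count_matrix()].
#' @param min_total Nonnegative threshold.
#' @return A filtered [count_matrix()].
#' @export
filter_genes <- function(counts, min_total) {
  stopifnot(inherits(counts, "count_matrix"), min_total >= 0)
  keep <- rowSums(counts$counts) > min_total
  if (!any(keep)) stop("gene filter removed every gene", call. = FALSE)
  if (sum(keep) == 1) {
    warning("only one gene passes the filter; downstream analyses need >= 2",
            call. = FALSE)
  }
  count_matrix(counts$counts[keep, , drop = FALSE], counts$gene_lengths[keep])
}

#' Standardize each gene to mean zero, unit variance
#'
#' Rows with zero variance are flagged and left unstandardized (only
#' centered by 0, scaled by 1); the network stage drops them.
#'
#' @param x Numeric genes-by-samples matrix (typically log TPM).
#' @return Matrix with attributes `center`, `scale`, `constant` (logical per
#'   gene) and `scale_tag = "standardized"`.
#' @export
standardize_genes <- function(x) {
  x <- unclass(x)
  ctr <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  constant <- sdv < 1e-12
  ctr[constant] <- 0
  sdv[constant] <- 1
  out <- (x - ctr) / sdv
  attr(out, "center") <- ctr
  attr(out, "scale") <- sdv
  attr(out, "constant") <- constant
  attr(out, "scale_tag") <- "standardized"
  out
}

#' Simplified differential expression (volcano baseline)
#'
#' A deliberately plain per-gene comparison used only as a marginal baseline
#' against which the network analysis is contrasted: genes passing the
#' read-count filter are tested with an unequal-variance two-sample t test
#' on `log2(TPM + pseudo_count)`; fold change is the difference of group
#' means (case minus control); p-values are adjusted by Benjamini-Hochberg.
#'
#' @param tpm A [tpm_matrix()].
#' @param labels A [sample_labels()] factor covering the samples.
#' @param counts The matching [count_matrix()] used for the filter.
#' @param min_total Read-count filter threshold (strictly greater than).
#' @param pseudo_count Pseudo-count for the log transform.
#' @return data.frame sorted by p-value with columns `gene_id`, `log2fc`,
#'   `statistic`, `p`, `p_adj`, `passed_filter` (filtered genes appear last
#'   with `NA` statistics).
#' @export
simple_de <- function(tpm, labels, counts, min_total = 6, pseudo_count = 1) {
  labels <- align_labels(labels, colnames(tpm))
  if (sum(labels == "case") < 2 || sum(labels == "control") < 2) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  if (!identical(rownames(counts$counts), rownames(tpm))) {
    counts_use <- counts$counts[rownames(tpm), , drop = FALSE]
  } else {
    counts_use <- counts$counts
  }
  pass <- rowSums(counts_use) > min_total
  lg <- log_transform(tpm, pseudo_count)
  is_case <- labels == "case"

  test_one <- function(v) {
    a <- v[is_case]; b <- v[!is_case]
    fc <- mean(a) - mean(b)
    if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12) {
      # degenerate: constant within both groups
      return(c(fc, 0, if (abs(fc) < 1e-12) 1 else 0))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    c(fc, unname(tt$statistic), tt$p.value)
  }

  res <- matrix(NA_real_, nrow(tpm), 3)
  if (any(pass)) {
    res[pass, ] <- t(apply(lg[pass, , drop = FALSE], 1, test_one))
  }
  out <- data.frame(gene_id = rownames(tpm),
                    log2fc = res[, 1], statistic = res[, 2], p = res[, 3],
                    p_adj = NA_real_, passed_filter = pass,
                    stringsAsFactors = FALSE)
  out$p_adj[pass] <- stats::p.adjust(out$p[pass], method = "BH")
  out <- out[order(out$p, out$gene_id, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}
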