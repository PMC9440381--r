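# Shared fixture builders. Everything is generated in code; no stored data.

# A small count matrix with deterministic contents.
toy_counts <- function() {
  m <- matrix(c(3L, 5L, 0L, 7L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  count_matrix(m, c(g1 = 1000, g2 = 2000))
}

# Random count fixture of arbitrary shape.
random_counts <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda = 50), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  count_matrix(m, stats::setNames(sample(500:3000, n_genes, replace = TRUE),
                                  rownames(m)))
}

# Write a counts/lengths/labels file triple in the package dialect and
# return the paths.
write_count_files <- function(cm, labels, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  cp <- file.path(dir, "counts.tsv")
  lp <- file.path(dir, "lengths.tsv")
  bp <- file.path(dir, "labels.tsv")
  write_matrix_tsv(cm$counts, cp)
  utils::write.table(data.frame(gene_id = cm$gene_ids, length = cm$gene_lengths),
                     lp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(labels),
                                group = as.character(labels)),
                     bp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(counts = cp, lengths = lp, labels = bp)
}

# Marker-panel TPM fixture: k lognormal marker genes plus a filler gene
# absorbing the rest of the library, so marker TPM values are effectively
# independent of each other. Optionally gene 1 carries a multiplicative
# group effect of `shift_sd` within-gene standard deviations.
marker_tpm <- function(seed, k = 9, n = 40, shift_sd = 0) {
  set.seed(seed)
  y <- rep(c(1L, 0L), c(ceiling(n / 2), floor(n / 2)))
  X <- matrix(exp(rnorm(n * k, 5, 0.6)), n, k)
  if (shift_sd != 0) X[, 1] <- X[, 1] * exp(shift_sd * 0.6 * y)
  genes <- sprintf("G%02d", seq_len(k))
  m <- t(X)
  rownames(m) <- genes
  m <- rbind(m, FILLER = 1e6 - colSums(m))
  colnames(m) <- sprintf("s%03d", seq_len(n))
  lab <- sample_labels(colnames(m), ifelse(y == 1, "case", "control"))
  list(tpm = tpm_matrix(m), labels = lab, genes = genes)
}

# Exhaustive best-subset logistic AIC search via plain glm (independent of
# the package's fitting code); returns the sorted gene set minimizing AIC.
exhaustive_subset_aic <- function(genes, tpm, labels) {
  y <- as.integer(labels == "case")
  X <- t(unclass(tpm))[, genes, drop = FALSE]
  k <- length(genes)
  best_aic <- Inf
  best_set <- NULL
  for (m in 0:(2^k - 1)) {
    set <- genes[bitwAnd(m, 2^(seq_len(k) - 1)) > 0]
    df <- if (length(set) == 0) data.frame(y = y)
          else data.frame(y = y, X[, set, drop = FALSE])
    f <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    if (f$aic < best_aic - 1e-8) {
      best_aic <- f$aic
      best_set <- sort(set)
    }
  }
  list(set = best_set, aic = best_aic)
}

# Directly simulated 3-variable chain u -> v -> w with smooth monotone
# links, bypassing the count layer.
chain_data <- function(n, seed) {
  set.seed(seed)
  u <- rnorm(n)
  v <- tanh(u) * 1.5 + rnorm(n, 0, 0.3)
  w <- sign(v) * sqrt(abs(v)) * 1.2 + rnorm(n, 0, 0.3)
  x <- rbind(u = u, v = v, w = w)
  colnames(x) <- sprintf("s%03d", seq_len(n))
  x
}
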