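# Tabular dialect: tab- or comma-separated, header row of sample IDs, first
# column header "gene_id". Decimal point, no thousands separators.

.sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty file: ", path, call. = FALSE)
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_com <- lengths(regmatches(first, gregexpr(",", first)))
  if (n_tab >= n_com) "\t" else ","
}

.read_table <- function(path) {
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty or malformed table: ", path, call. = FALSE)
  df
}

.table_to_matrix <- function(df) {
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene IDs in matrix file: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell in matrix file", call. = FALSE)
  rownames(m) <- ids
  m
}

.read_keyed <- function(path) {
  df <- .read_table(path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate IDs in ", path, call. = FALSE)
  vals <- df[[2]]
  names(vals) <- ids
  vals
}

#' Read a count matrix with gene lengths and sample labels
#'
#' All three files share the tabular dialect: TSV (or CSV), header row, first
#' column keyed by ID. The counts file has sample IDs as column headers; the
#' lengths file maps `gene_id` to length in bases; the labels file maps
#' sample ID to `case`/`control`. Row and column order is preserved.
#'
#' @param path Counts file.
#' @param lengths_path Gene length file.
#' @param labels_path Sample label file.
#' @return A list with elements `counts` (a [count_matrix()]) and `labels`
#'   (a [sample_labels()] factor aligned to the sample columns).
#' @export
read_count_matrix <- function(path, lengths_path, labels_path) {
  m <- .table_to_matrix(.read_table(path))
  if (anyNA(m)) stop("missing count value", call. = FALSE)
  if (any(m < 0)) stop("negative count", call. = FALSE)
  if (any(abs(m - round(m)) > 1e-8)) stop("non-integer count", call. = FALSE)
  lengths <- .read_keyed(lengths_path)
  labels_raw <- .read_keyed(labels_path)
  labels <- sample_labels(names(labels_raw), as.character(labels_raw))
  cm <- count_matrix(m, lengths)
  list(counts = cm, labels = align_labels(labels, cm$sample_ids))
}

#' Read a TPM matrix with sample labels
#'
#' Accepts the dialect of deposited TPM matrices (tab- or comma-separated,
#' Ensembl-style gene IDs in the first column, one column per sample).
#' Column sums are checked against 1e6 with the relaxed external tolerance:
#' a deviation beyond 0.1% warns rather than errors, because deposited
#' matrices may have been rounded.
#'
#' @inheritParams read_count_matrix
#' @return A list with elements `tpm` (a [tpm_matrix()]) and `labels`.
#' @export
read_tpm_matrix <- function(path, labels_path) {
  m <- .table_to_matrix(.read_table(path))
  if (anyNA(m)) stop("non-numeric cell in TPM matrix", call. = FALSE)
  if (any(m < 0)) stop("negative TPM value", call. = FALSE)
  tpm <- tpm_matrix(m, external = TRUE)
  labels_raw <- .read_keyed(labels_path)
  labels <- sample_labels(names(labels_raw), as.character(labels_raw))
  list(tpm = tpm, labels = align_labels(labels, colnames(tpm)))
}

#' Write a genes-by-samples matrix in the package's tabular dialect
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Normalize the various edge carriers to a two-column data.frame.
edge_frame <- function(x) {
  if (inherits(x, "ecv_network")) return(x$edges[, c("parent", "child"), drop = FALSE])
  if (inherits(x, "differential_edges")) {
    sel <- x$table[x$table$selected, c("parent", "child"), drop = FALSE]
    rownames(sel) <- NULL
    return(sel)
  }
  if (is.data.frame(x) && all(c("parent", "child") %in% names(x))) {
    return(x[, c("parent", "child"), drop = FALSE])
  }
  stop("cannot interpret object as an edge set", call. = FALSE)
}

#' Write a network or edge set as a SIF file
#'
#' One line per edge, `parent<TAB>regulates<TAB>child`, sorted lexically by
#' parent then child so output is deterministic.
#'
#' @param network An `ecv_network`, `differential_edges` object, or a
#'   data.frame with `parent` and `child` columns.
#' @param path Output path.
#' @export
write_network_sif <- function(network, path) {
  e <- edge_frame(network)
  if (nrow(e) > 0) {
    e <- e[order(e$parent, e$child), , drop = FALSE]
    lines <- paste(e$parent, "regulates", e$child, sep = "\t")
  } else {
    lines <- character(0)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a SIF file back into an edge data.frame
#'
#' @param path SIF file written by [write_network_sif()].
#' @return data.frame with `parent` and `child` columns.
#' @export
read_network_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(parent = character(0), child = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3)) stop("malformed SIF line", call. = FALSE)
  data.frame(parent = vapply(parts, `[[`, "", 1),
             child = vapply(parts, `[[`, "", 3),
             stringsAsFactors = FALSE)
}

#' Serialize a fitted network to JSON
#'
#' Stores nodes, edges, spline knots and coefficients, intercepts, residual
#' variances and the network score; enough to re-evaluate every smoother.
#'
#' @param network An `ecv_network`.
#' @param path Output path.
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "ecv_network"))
  obj <- list(
    genes = network$genes,
    score = network$score,
    seed = network$seed,
    intercepts = as.list(network$intercepts),
    sigma2 = as.list(network$sigma2),
    edges = lapply(seq_len(nrow(network$edges)), function(i) {
      key <- edge_key(network$edges$parent[i], network$edges$child[i])
      sm <- network$smoothers[[key]]
      list(parent = network$edges$parent[i], child = network$edges$child[i],
           knots = sm$knots, coef = sm$coef, center = sm$center)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write the analysis report tables
#'
#' Produces three deterministic TSV tables in `dir`:
#' `subnetwork_genes.tsv` (one row per member gene, with the best-AUC flag,
#' one row per subnetwork member gene), `differential_edges.tsv`
#' (full edge ranking with group means and deltas) and
#' `classification_summary.tsv` (stepwise/tree selections, interaction screen
#' and LOOCV performance).
#'
#' @param report A `discrimination_report` from [discrimination_report()].
#' @param edge_set A `differential_edges` object.
#' @param subnets Completed subnetworks from [subnetwork_stats()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, edge_set, subnets, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gene_tab <- subnetwork_gene_table(subnets)
  rep_genes <- vapply(subnets, function(s) s$representative, "")
  if (!all(report$candidates %in% gene_tab$gene_id)) {
    stop("report candidates are not members of the supplied subnetworks", call. = FALSE)
  }
  f1 <- file.path(dir, "subnetwork_genes.tsv")
  utils::write.table(gene_tab, f1, sep = "\t", quote = FALSE, row.names = FALSE)

  f2 <- file.path(dir, "differential_edges.tsv")
  utils::write.table(edge_set$table, f2, sep = "\t", quote = FALSE, row.names = FALSE)

  summ <- data.frame(
    field = c("stepwise_selected", "stepwise_aic", "tree_selected",
              "loocv_feature", "loocv_sensitivity", "loocv_specificity",
              "interactions_retained"),
    value = c(paste(report$stepwise$selected, collapse = ","),
              format(report$stepwise$aic, digits = 10),
              paste(report$tree_genes, collapse = ","),
              paste(report$loocv_features, collapse = ","),
              format(report$loocv$sensitivity, digits = 10),
              format(report$loocv$specificity, digits = 10),
              paste(report$interactions$gene[report$interactions$retained],
                    collapse = ",")),
    stringsAsFactors = FALSE
  )
  f3 <- file.path(dir, "classification_summary.tsv")
  utils::write.table(summ, f3, sep = "\t", quote = FALSE, row.names = FALSE)

  f4 <- file.path(dir, "interaction_screen.tsv")
  utils::write.table(report$interactions, f4, sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(c(f1, f2, f3, f4))
}

# One row per member gene across subnetworks, best-AUC flag on the
# representative.
subnetwork_gene_table <- function(subnets) {
  rows <- lapply(subnets, function(s) {
    data.frame(subnetwork = s$id, gene_id = s$genes,
               auc = if (!is.null(s$auc)) as.numeric(s$auc[s$genes]) else NA_real_,
               best_auc = s$genes == s$representative,
               best_auc_value = ifelse(s$genes == s$representative,
                                       s$representative_auc, NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
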