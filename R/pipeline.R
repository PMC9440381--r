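#' Run the full differential-network analysis pipeline
#'
#' Executes normalize -> learn -> ECv -> differential edges -> subnetworks
#' -> discrimination on either a count matrix (with gene lengths and
#' labels) or a pre-normalized TPM matrix, writing every artifact to
#' `out_dir`: the TPM matrix, the basal network (SIF + JSON), the ECv
#' matrix, the ranked differential edge table, the subnetwork gene table,
#' the classification summary, a volcano-style marginal DE table (when
#' counts are available) and a parameter log. All outputs are a
#' deterministic function of (inputs, config, seed).
#'
#' @param config A [pipeline_config()].
#' @param counts A [count_matrix()] or path to a counts table.
#' @param lengths Path to the gene length table (when `counts` is a path).
#' @param labels A [sample_labels()] factor or path to the label table.
#' @param tpm A [tpm_matrix()] or path to a TPM table (alternative input).
#' @param network_genes Optional subset of genes on which the network is
#'   estimated (TPM normalization and the volcano table still use the full
#'   matrix). Typical use: the network is learned on a preselected gene
#'   panel while the rest of the transcriptome only enters normalization.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the artifact bundle: list with `tpm`, `network`,
#'   `ecv`, `edges`, `subnets`, `report`, `de` (or `NULL`), `files`.
#' @export
run_pipeline <- function(config = pipeline_config(), counts = NULL,
                         lengths = NULL, labels = NULL, tpm = NULL,
                         network_genes = NULL, out_dir) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- c("ecvnet pipeline log",
                 sprintf("seed=%d", config$seed))

  cm <- NULL; de <- NULL
  stage("input", {
    if (!is.null(counts)) {
      if (is.character(counts)) {
        inp <- read_count_matrix(counts, lengths, labels)
        cm <- inp$counts; labels <- inp$labels
      } else {
        cm <- counts
        labels <- align_labels(labels, cm$sample_ids)
      }
    } else if (!is.null(tpm)) {
      if (is.character(tpm)) {
        inp <- read_tpm_matrix(tpm, labels)
        tpm <- inp$tpm; labels <- inp$labels
      } else {
        labels <- align_labels(labels, colnames(tpm))
      }
    } else {
      stop("either counts or tpm input is required")
    }
  })

  tpm_mat <- stage("normalize", {
    if (!is.null(cm)) compute_tpm(cm) else tpm
  })
  log_lines <- c(log_lines,
                 sprintf("normalize: genes=%d samples=%d",
                         nrow(tpm_mat), ncol(tpm_mat)))

  if (!is.null(cm)) {
    de <- stage("volcano", {
      simple_de(tpm_mat, labels, cm, min_total = config$de_count_filter,
                pseudo_count = config$pseudo_count)
    })
    log_lines <- c(log_lines,
                   sprintf("volcano: min_total=%d tested=%d",
                           config$de_count_filter, sum(de$passed_filter)))
  }

  network <- stage("learn", {
    lg <- log_transform(tpm_mat, config$pseudo_count)
    if (!is.null(network_genes)) {
      missing <- setdiff(network_genes, rownames(lg))
      if (length(missing) > 0) {
        stop("network_genes absent from matrix: ",
             paste(utils::head(missing, 5), collapse = ", "))
      }
      lg <- lg[network_genes, , drop = FALSE]
      attr(lg, "scale_tag") <- "log_tpm"
    }
    ecv_network(lg, config, seed = config$seed)
  })
  log_lines <- c(log_lines,
                 sprintf("learn: edges=%d score=%.6f restarts=%d max_parents=%d spline_df=%d",
                         nrow(network$edges), network$score, config$restarts,
                         config$max_parents, config$spline_df))

  ecv <- stage("ecv", compute_ecv(network))
  edges <- stage("diffedges", {
    differential_edges(ecv, labels, q = config$top_fraction,
                       floor_n = config$min_selected_edges,
                       absolute = config$ecv_absolute)
  })
  log_lines <- c(log_lines,
                 sprintf("diffedges: q=%g floor=%d selected=%d",
                         config$top_fraction, config$min_selected_edges,
                         edges$n_selected))

  subnets <- stage("subnet", {
    subnetwork_stats(extract_subnetworks(edges), tpm_mat, labels)
  })
  log_lines <- c(log_lines, sprintf("subnet: components=%d", length(subnets)))

  report <- stage("classify", {
    discrimination_report(subnets, tpm_mat, labels, config)
  })
  log_lines <- c(log_lines,
                 sprintf("classify: primary=%s loocv_sens=%.4f loocv_spec=%.4f ensemble=%d",
                         report$primary, report$loocv$sensitivity,
                         report$loocv$specificity, config$ensemble_size))

  files <- stage("write", {
    f <- c(
      tpm = write_matrix_tsv(unclass(tpm_mat), file.path(out_dir, "tpm.tsv")),
      network_sif = write_network_sif(network, file.path(out_dir, "network.sif")),
      network_json = write_network_json(network, file.path(out_dir, "network.json")),
      ecv = write_matrix_tsv(unclass(ecv), file.path(out_dir, "ecv.tsv")),
      selected_sif = write_network_sif(edges, file.path(out_dir, "selected_edges.sif"))
    )
    f <- c(f, report = write_report(report, edges, subnets, out_dir))
    if (!is.null(de)) {
      vf <- file.path(out_dir, "volcano.tsv")
      utils::write.table(de, vf, sep = "\t", quote = FALSE, row.names = FALSE)
      f <- c(f, volcano = vf)
    }
    log_file <- file.path(out_dir, "log.txt")
    writeLines(log_lines, log_file)
    c(f, log = log_file)
  })

  invisible(list(tpm = tpm_mat, network = network, ecv = ecv, edges = edges,
                 subnets = subnets, report = report, de = de, files = files))
}
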