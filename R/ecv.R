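#' Compute edge contribution values
#'
#' The edge contribution value (ECv) of edge `u -> v` in sample `s` is the
#' fitted centered smoother of that edge evaluated at sample `s`'s
#' expression of the parent `u`. It is a per-sample, per-edge activity
#' score on the scale the network was fitted on.
#'
#' @param network A fitted [ecv_network()].
#' @param data Optional genes-by-samples matrix on the same scale and
#'   standardization used for fitting (defaults to the training data; raw
#'   log-TPM input is standardized with the stored training parameters).
#' @return Edges-by-samples numeric matrix of class `ecv_matrix`, row names
#'   `parent~child`, with the edge table attached as attribute `edges`.
#' @export
compute_ecv <- function(network, data = NULL) {
  stopifnot(inherits(network, "ecv_network"))
  x <- if (is.null(data)) network$data else .standardize_like(network, data)
  missing <- setdiff(unique(network$edges$parent), rownames(x))
  if (length(missing) > 0) {
    stop("genes missing from data: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  e <- network$edges
  out <- matrix(NA_real_, nrow(e), ncol(x),
                dimnames = list(edge_key(e$parent, e$child), colnames(x)))
  for (i in seq_len(nrow(e))) {
    sm <- network$smoothers[[edge_key(e$parent[i], e$child[i])]]
    out[i, ] <- evaluate_smoother(sm, x[e$parent[i], ])
  }
  attr(out, "edges") <- e
  class(out) <- c("ecv_matrix", class(out))
  out
}

# Number of edges selected for a basal network of E edges: the top
# round(q * E), floored and capped.
selection_count <- function(q, n_edges, floor_n = 1L) {
  as.integer(min(max(as.integer(floor_n), as.integer(round(q * n_edges))),
                 n_edges))
}

#' Rank edges by between-group difference in average ECv
#'
#' For every basal edge the unweighted mean ECv is computed per group and
#' the edges are ranked by the absolute difference `delta`. The top
#' `max(floor_n, round(q * E))` edges (capped at `E`) are selected as
#' differentially regulated, ties broken lexically by (parent, child).
#'
#' @param ecv An `ecv_matrix` from [compute_ecv()].
#' @param labels A [sample_labels()] factor covering its samples.
#' @param q Selection fraction (default: the top 0.001% convention, i.e. 1e-5).
#' @param floor_n Minimum number of edges to select.
#' @param absolute Take group means of absolute ECv rather than signed ECv
#'   before differencing.
#' @return Object of class `differential_edges`: list with `table` (all
#'   edges: parent, child, mean_case, mean_control, delta, rank, selected),
#'   `selected` (the selected subset), `q`, `n_selected`.
#' @export
differential_edges <- function(ecv, labels, q = 1e-5, floor_n = 1L,
                               absolute = FALSE) {
  if (!(q > 0 && q <= 1)) stop("q must satisfy 0 < q <= 1", call. = FALSE)
  labels <- align_labels(labels, colnames(ecv))
  if (!any(labels == "case") || !any(labels == "control")) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  vals <- unclass(ecv)
  if (absolute) vals <- abs(vals)
  is_case <- labels == "case"
  mean_case <- rowMeans(vals[, is_case, drop = FALSE])
  mean_control <- rowMeans(vals[, !is_case, drop = FALSE])
  e <- attr(ecv, "edges")
  tab <- data.frame(parent = e$parent, child = e$child,
                    mean_case = mean_case, mean_control = mean_control,
                    delta = abs(mean_case - mean_control),
                    stringsAsFactors = FALSE)
  ord <- order(-tab$delta, tab$parent, tab$child)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  n_sel <- selection_count(q, nrow(tab), floor_n)
  tab$selected <- tab$rank <= n_sel
  rownames(tab) <- NULL
  structure(list(table = tab,
                 selected = tab[tab$selected, , drop = FALSE],
                 q = q, n_selected = n_sel),
            class = "differential_edges")
}

#' @export
print.differential_edges <- function(x, ...) {
  cat(sprintf("differential_edges: %d of %d edges selected (q = %g)\n",
              x$n_selected, nrow(x$table), x$q))
  print(utils::head(x$selected, 10))
  invisible(x)
}

#' Extract subnetworks as weakly connected components
#'
#' Groups the selected differential edges into weakly connected components
#' (edge direction ignored for grouping, preserved in membership).
#' Components are ordered by decreasing size, ties by their
#' lexicographically smallest gene.
#'
#' @param selected A `differential_edges` object (or a data.frame with
#'   `parent`/`child` columns, optionally `delta`).
#' @return List of subnetworks: each a list with `id`, `genes` (sorted),
#'   `edges` (member edge data.frame).
#' @export
extract_subnetworks <- function(selected) {
  e <- if (inherits(selected, "differential_edges")) selected$selected else selected
  if (nrow(e) == 0) stop("empty differential edge selection", call. = FALSE)
  g <- igraph::graph_from_data_frame(e[, c("parent", "child")], directed = TRUE)
  comp <- igraph::components(g, mode = "weak")
  membership <- comp$membership
  comp_ids <- seq_len(comp$no)
  subs <- lapply(comp_ids, function(ci) {
    genes <- sort(names(membership)[membership == ci])
    keep <- e$parent %in% genes & e$child %in% genes
    me <- e[keep, , drop = FALSE]
    rownames(me) <- NULL
    list(genes = genes, edges = me)
  })
  ord <- order(-vapply(subs, function(s) length(s$genes), 0L),
               vapply(subs, function(s) s$genes[[1]], ""))
  subs <- subs[ord]
  for (i in seq_along(subs)) subs[[i]]$id <- i
  subs
}

#' Complete subnetworks with correlation and AUC statistics
#'
#' For each subnetwork: the minimum absolute pairwise Pearson correlation
#' of member genes' TPM values, each member gene's direction-folded AUC for
#' separating cases from controls, and the representative gene (highest
#' folded AUC; ties broken by the larger incident edge delta, then
#' lexically).
#'
#' @param subnets Output of [extract_subnetworks()].
#' @param tpm A [tpm_matrix()] covering all member genes.
#' @param labels A [sample_labels()] factor.
#' @return The subnetworks, each augmented with `min_abs_cor`, `auc` (named
#'   vector of folded AUCs), `representative`, `representative_auc`.
#' @export
subnetwork_stats <- function(subnets, tpm, labels) {
  labels <- align_labels(labels, colnames(tpm))
  all_genes <- unique(unlist(lapply(subnets, `[[`, "genes")))
  missing <- setdiff(all_genes, rownames(tpm))
  if (length(missing) > 0) {
    stop("genes missing from TPM matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  lapply(subnets, function(s) {
    gs <- s$genes
    if (length(gs) >= 2) {
      cm <- stats::cor(t(unclass(tpm)[gs, , drop = FALSE]), method = "pearson")
      s$min_abs_cor <- min(abs(cm[upper.tri(cm)]))
    } else {
      s$min_abs_cor <- NA_real_
    }
    aucs <- vapply(gs, function(g) auc(unclass(tpm)[g, ], labels)$folded, 0)
    names(aucs) <- gs
    s$auc <- aucs
    # incident delta per gene (0 when the edge table carries no delta)
    inc <- vapply(gs, function(g) {
      if (!"delta" %in% names(s$edges)) return(0)
      hit <- s$edges$parent == g | s$edges$child == g
      if (!any(hit)) 0 else max(s$edges$delta[hit])
    }, 0)
    ord <- order(-aucs, -inc, gs)
    s$representative <- gs[ord][1]
    s$representative_auc <- unname(aucs[s$representative])
    s
  })
}
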