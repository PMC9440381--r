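# Undirected edge keys for skeleton-level comparisons.
.skeleton_keys <- function(edges) {
  if (nrow(edges) == 0) return(character(0))
  unique(paste(pmin(edges$parent, edges$child),
               pmax(edges$parent, edges$child), sep = "--"))
}

#' Skeleton precision, recall and F1 of an estimated edge set
#'
#' Compares estimated and true edge sets at the skeleton (undirected)
#' level, the standard yardstick for structure recovery when orientation
#' is only weakly identifiable.
#'
#' @param estimated,truth data.frames with `parent`/`child` columns (an
#'   `ecv_network` or `synthetic_truth` may be passed directly).
#' @return List with `precision`, `recall`, `f1`, `n_estimated`, `n_true`.
#' @export
skeleton_f1 <- function(estimated, truth) {
  if (inherits(estimated, "ecv_network")) estimated <- estimated$edges
  if (inherits(truth, "synthetic_truth")) truth <- truth$edges
  ek <- .skeleton_keys(estimated)
  tk <- .skeleton_keys(truth)
  tp <- length(intersect(ek, tk))
  precision <- if (length(ek) == 0) 0 else tp / length(ek)
  recall <- if (length(tk) == 0) 0 else tp / length(tk)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_estimated = length(ek), n_true = length(tk))
}

#' Recall of perturbed edges within a ranked selection
#'
#' Fraction of truly perturbed edges that appear among the selected
#' differential edges. By default matching is at skeleton level, since the
#' orientation of a perturbed pair is not identifiable from a single
#' pooled fit.
#'
#' @param selected A `differential_edges` object or data.frame of selected
#'   edges.
#' @param perturbed data.frame of perturbed edges (e.g.
#'   `truth$perturbed`).
#' @param directed Require matching orientation.
#' @return Recall in `[0, 1]` (`NA` if there are no perturbed edges).
#' @export
edge_recall <- function(selected, perturbed, directed = FALSE) {
  if (inherits(selected, "differential_edges")) selected <- selected$selected
  if (nrow(perturbed) == 0) return(NA_real_)
  if (directed) {
    sk <- paste(selected$parent, selected$child, sep = "->")
    pk <- paste(perturbed$parent, perturbed$child, sep = "->")
  } else {
    sk <- .skeleton_keys(selected)
    pk <- .skeleton_keys(perturbed)
  }
  mean(pk %in% sk)
}
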