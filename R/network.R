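edge_key <- function(parent, child) {
  if (length(parent) == 0) return(character(0))
  paste0(parent, "~", child)
}

#' Fit a centered spline smoother of one variable on another
#'
#' Least-squares cubic B-spline regression of `y` on `x` with `spline_df`
#' coefficients. The fitted contribution is centered to mean zero over the
#' training samples (the mean is absorbed into the node intercept), and the
#' smoother extrapolates linearly beyond the observed range of `x`.
#'
#' @param x Parent values (not all identical).
#' @param y Child values (same length, at least `spline_df + 2`).
#' @param spline_df Number of spline coefficients (>= 4).
#' @return An object of class `ecv_smoother` with fields `knots`, `coef`,
#'   `center`, `intercept` and attribute `contribution` (the centered fitted
#'   contribution at the training points).
#' @export
fit_smoother <- function(x, y, spline_df = 4L) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < spline_df + 2) {
    stop("need at least spline_df + 2 samples", call. = FALSE)
  }
  knots <- spline_knots(x, spline_df)
  B <- spline_basis(knots, x)
  fit <- ls_fit_blocks(y, list(B), warn_ridge = TRUE)
  g <- drop(B %*% fit$coef[[1]])
  center <- mean(g)
  sm <- structure(list(knots = knots, coef = fit$coef[[1]], center = center,
                       intercept = fit$intercept + center, df = spline_df),
                  class = "ecv_smoother")
  attr(sm, "contribution") <- g - center
  sm
}

#' Evaluate a fitted smoother's centered contribution
#'
#' @param sm An `ecv_smoother`.
#' @param x Values at which to evaluate (any real numbers; linear
#'   extrapolation beyond the boundary knots).
#' @return Numeric vector of centered contributions.
#' @export
evaluate_smoother <- function(sm, x) {
  drop(spline_basis(sm$knots, x) %*% sm$coef) - sm$center
}

#' BIC-penalized local score of a child given a parent set
#'
#' Gaussian log-likelihood of the residuals from the additive spline fit of
#' the child on its parents, penalized BIC-style:
#' `score = -2 * logLik + log(n) * k`, with `k` counting the intercept, the
#' spline coefficients and the residual variance. Lower is better; the
#' network score decomposes as the sum of its node scores.
#'
#' @param child Gene ID of the child.
#' @param parents Character vector of parent gene IDs (may be empty).
#' @param data Genes-by-samples numeric matrix.
#' @param config A [pipeline_config()] (only `spline_df`, `max_parents` used).
#' @return Scalar score.
#' @export
local_score <- function(child, parents, data, config = pipeline_config()) {
  if (child %in% parents) stop("child cannot be its own parent", call. = FALSE)
  if (length(parents) > config$max_parents) {
    stop("parent set exceeds max_parents", call. = FALSE)
  }
  bases <- lapply(parents, function(p) {
    knots <- spline_knots(data[p, ], config$spline_df)
    spline_basis(knots, data[p, ])
  })
  .local_score_from_bases(data[child, ], bases, config$spline_df)
}

.local_score_from_bases <- function(y, bases, spline_df) {
  n <- length(y)
  if (length(bases) == 0) {
    mu <- mean(y)
    sigma2 <- max(mean((y - mu)^2), 1e-12)
    k <- 2
  } else {
    fit <- ls_fit_blocks(y, bases)
    sigma2 <- max(fit$rss / n, 1e-12)
    k <- 1 + length(bases) * spline_df + 1
  }
  n * (log(2 * pi * sigma2) + 1) + log(n) * k
}

#' Candidate parents by absolute rank correlation
#'
#' For each gene, the `k` other genes with the largest absolute Spearman
#' correlation, ties broken by gene ID. Restricting the structure search to
#' these candidates keeps the search tractable.
#'
#' @param data Genes-by-samples matrix.
#' @param k Number of candidates per gene.
#' @return Named list mapping each gene to its ordered candidate vector.
#' @export
candidate_parents <- function(data, k) {
  stopifnot(k >= 1)
  genes <- rownames(data)
  rho <- suppressWarnings(stats::cor(t(data), method = "spearman"))
  rho[is.na(rho)] <- 0
  out <- lapply(genes, function(g) {
    others <- setdiff(genes, g)
    a <- abs(rho[g, others])
    ord <- order(-a, others)
    others[ord][seq_len(min(k, length(others)))]
  })
  names(out) <- genes
  out
}

# --- structure search internals ------------------------------------------

# reachable(from, to): TRUE if a directed path from -> ... -> to exists.
.reachable <- function(from, to, children) {
  if (from == to) return(TRUE)
  seen <- character(0)
  stack <- from
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (w in children[[v]]) {
      if (w == to) return(TRUE)
      if (!(w %in% seen)) {
        seen <- c(seen, w)
        stack <- c(stack, w)
      }
    }
  }
  FALSE
}

.hill_climb <- function(data, genes, cand, bases, config, pair_p, pair_c,
                        pair_order, cache, init_parents = NULL) {
  spline_df <- config$spline_df
  max_parents <- config$max_parents
  parents <- stats::setNames(rep(list(character(0)), length(genes)), genes)
  children <- stats::setNames(rep(list(character(0)), length(genes)), genes)

  score_of <- function(child, pa) {
    key <- paste0(child, "|", paste(sort(pa), collapse = ","))
    val <- cache[[key]]
    if (is.null(val)) {
      val <- .local_score_from_bases(data[child, ], bases[pa], spline_df)
      cache[[key]] <- val
    }
    val
  }

  if (!is.null(init_parents)) {
    parents <- init_parents
    for (g in genes) for (p in parents[[g]]) {
      children[[p]] <- c(children[[p]], g)
    }
  }
  node_scores <- vapply(genes, function(g) score_of(g, parents[[g]]), 0)
  total <- sum(node_scores)

  repeat {
    improved <- FALSE
    for (i in pair_order) {
      p <- pair_p[i]; c_ <- pair_c[i]
      if (p %in% parents[[c_]]) {
        # deletion
        new_pa <- setdiff(parents[[c_]], p)
        d <- score_of(c_, new_pa) - node_scores[[c_]]
        if (d < -1e-9) {
          parents[[c_]] <- new_pa
          children[[p]] <- setdiff(children[[p]], c_)
          node_scores[[c_]] <- node_scores[[c_]] + d
          total <- total + d
          improved <- TRUE
          break
        }
        # reversal: remove p->c, add c->p
        if (length(parents[[p]]) < max_parents && (c_ %in% cand[[p]])) {
          children[[p]] <- setdiff(children[[p]], c_)
          cyc <- .reachable(p, c_, children)
          children[[p]] <- c(children[[p]], c_)
          if (!cyc) {
            s_c <- score_of(c_, setdiff(parents[[c_]], p))
            s_p <- score_of(p, c(parents[[p]], c_))
            d <- (s_c + s_p) - (node_scores[[c_]] + node_scores[[p]])
            if (d < -1e-9) {
              parents[[c_]] <- setdiff(parents[[c_]], p)
              children[[p]] <- setdiff(children[[p]], c_)
              parents[[p]] <- c(parents[[p]], c_)
              children[[c_]] <- c(children[[c_]], p)
              node_scores[[c_]] <- s_c
              node_scores[[p]] <- s_p
              total <- sum(node_scores)
              improved <- TRUE
              break
            }
          }
        }
      } else {
        # addition
        if (length(parents[[c_]]) >= max_parents) next
        if (.reachable(c_, p, children)) next   # would create a cycle
        new_pa <- c(parents[[c_]], p)
        d <- score_of(c_, new_pa) - node_scores[[c_]]
        if (d < -1e-9) {
          parents[[c_]] <- new_pa
          children[[p]] <- c(children[[p]], c_)
          node_scores[[c_]] <- node_scores[[c_]] + d
          total <- total + d
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  list(parents = parents, score = total)
}

#' Estimate the basal gene expression network
#'
#' Score-based search for a directed acyclic gene network in which each
#' child is modelled as an intercept plus a sum of centered cubic-spline
#' functions of its parents with Gaussian noise. The search is greedy
#' hill-climbing over add/delete/reverse moves (first improvement in a
#' deterministic enumeration order, seeded random orders on restarts),
#' restricted to the rank-correlation candidate parents and to at most
#' `max_parents` parents per gene, with acyclicity enforced by an
#' incremental reachability check. The network is fitted once on all
#' samples pooled; groups are contrasted downstream via ECv only.
#'
#' @param x Genes-by-samples numeric matrix (log TPM recommended). Unless
#'   already standardized, each gene is standardized to mean 0 / sd 1 when
#'   `config$standardize` is `TRUE`. Constant genes are dropped with a
#'   warning.
#' @param config A [pipeline_config()].
#' @param seed Master seed for the restart orders (defaults to
#'   `config$seed`).
#' @return An object of class `ecv_network`; see Details.
#' @details The returned object carries the edge list, one fitted
#'   [fit_smoother()]-style smoother per edge, per-node intercepts and
#'   residual variances, the total BIC-style score (the sum of the node
#'   local scores), the standardization used, and the training data, so
#'   that ECv computation and prediction are self-contained.
#' @seealso [compute_ecv()], [check_reproducibility()], [local_score()]
#' @export
ecv_network <- function(x, config = pipeline_config(), seed = config$seed) {
  x <- unclass(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("x must have gene row names and sample column names", call. = FALSE)
  }
  if (ncol(x) < 8) stop("need at least 8 samples", call. = FALSE)
  if (nrow(x) < 2) stop("need at least 2 genes", call. = FALSE)

  if (!identical(attr(x, "scale_tag"), "standardized") && config$standardize) {
    x <- standardize_genes(x)
  }
  constant <- apply(x, 1, function(v) stats::sd(v) < 1e-12)
  if (any(constant)) {
    warning(sprintf("dropping %d constant gene(s) before structure search",
                    sum(constant)), call. = FALSE)
    keep_attr <- attributes(x)[c("center", "scale", "scale_tag")]
    x <- x[!constant, , drop = FALSE]
    if (!is.null(keep_attr$center)) {
      attr(x, "center") <- keep_attr$center[!constant]
      attr(x, "scale") <- keep_attr$scale[!constant]
      attr(x, "scale_tag") <- keep_attr$scale_tag
    }
  }
  genes <- rownames(x)
  if (length(genes) < 2) stop("fewer than 2 non-constant genes", call. = FALSE)

  cand <- candidate_parents(x, config$candidate_parents_k)
  knots_list <- lapply(genes, function(g) spline_knots(x[g, ], config$spline_df))
  names(knots_list) <- genes
  bases <- lapply(genes, function(g) spline_basis(knots_list[[g]], x[g, ]))
  names(bases) <- genes

  # deterministic base enumeration of (parent, child) candidate pairs,
  # lexical by (parent, child)
  pair_p <- unlist(lapply(genes, function(c_) cand[[c_]]))
  pair_c <- rep(genes, times = lengths(cand[genes]))
  ord0 <- order(pair_p, pair_c)
  pair_p <- pair_p[ord0]; pair_c <- pair_c[ord0]

  # Search: per restart, a first-improvement climb from the empty graph
  # (deterministic lexical move order on restart 1, seeded random orders
  # after), followed by seeded iterated local search: the restart's
  # optimum is perturbed by random edge deletions and re-climbed, keeping
  # improvements. Local scores are cached across all climbs.
  cache <- new.env(parent = emptyenv())
  best <- NULL
  for (r in seq_len(config$restarts)) {
    set.seed(stage_seed(seed, "restart", r))
    ord <- if (r == 1L) seq_along(pair_p) else sample.int(length(pair_p))
    res <- .hill_climb(x, genes, cand, bases, config, pair_p, pair_c, ord, cache)
    if (is.null(best) || res$score < best$score - 1e-9) best <- res
  }
  # iterated local search around the incumbent: perturb by random edge
  # deletions and re-climb with a random move order, keeping improvements
  set.seed(stage_seed(seed, "learn"))
  for (j in seq_len(6L * config$restarts)) {
    pert <- lapply(best$parents, function(pa) {
      pa[stats::runif(length(pa)) > 0.35]
    })
    ordj <- sample.int(length(pair_p))
    resj <- .hill_climb(x, genes, cand, bases, config, pair_p, pair_c,
                        ordj, cache, init_parents = pert)
    if (resj$score < best$score - 1e-9) best <- resj
  }

  # final joint fits per node
  parents <- best$parents
  smoothers <- list()
  intercepts <- stats::setNames(numeric(length(genes)), genes)
  sigma2 <- stats::setNames(numeric(length(genes)), genes)
  edges_p <- character(0); edges_c <- character(0)
  n <- ncol(x)
  for (g in genes) {
    pa <- parents[[g]]
    y <- x[g, ]
    if (length(pa) == 0) {
      intercepts[[g]] <- mean(y)
      sigma2[[g]] <- max(mean((y - mean(y))^2), 1e-12)
      next
    }
    fit <- ls_fit_blocks(y, bases[pa])
    ctr_sum <- 0
    for (j in seq_along(pa)) {
      p <- pa[[j]]
      gvals <- drop(bases[[p]] %*% fit$coef[[j]])
      ctr <- mean(gvals)
      ctr_sum <- ctr_sum + ctr
      smoothers[[edge_key(p, g)]] <- structure(
        list(knots = knots_list[[p]], coef = fit$coef[[j]], center = ctr,
             parent = p, child = g, df = config$spline_df),
        class = "ecv_smoother")
      edges_p <- c(edges_p, p); edges_c <- c(edges_c, g)
    }
    intercepts[[g]] <- fit$intercept + ctr_sum
    sigma2[[g]] <- max(fit$rss / n, 1e-12)
  }
  edges <- data.frame(parent = edges_p, child = edges_c, stringsAsFactors = FALSE)
  edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
  rownames(edges) <- NULL

  structure(list(
    genes = genes, sample_ids = colnames(x), edges = edges,
    smoothers = smoothers, intercepts = intercepts, sigma2 = sigma2,
    parents = parents, score = best$score,
    data = x,
    standardized = identical(attr(x, "scale_tag"), "standardized"),
    center = attr(x, "center"), scale = attr(x, "scale"),
    config = config, seed = seed
  ), class = "ecv_network")
}

#' Triplicate-style reproducibility check of the structure search
#'
#' Runs [ecv_network()] once per supplied seed and reports whether all
#' estimated edge sets are identical, together with the pairwise Jaccard
#' indices of the edge sets. Mirrors the practice of repeating the network
#' estimation several times and confirming that the structure is stable.
#'
#' @param x Genes-by-samples matrix as for [ecv_network()].
#' @param config A [pipeline_config()].
#' @param seeds Vector of (typically three) seeds.
#' @return List with `identical` (flag), `jaccard` (matrix), `edge_sets`
#'   and the fitted networks.
#' @export
check_reproducibility <- function(x, config = pipeline_config(),
                                  seeds = c(1L, 2L, 3L)) {
  fits <- lapply(seeds, function(s) ecv_network(x, config, seed = s))
  sets <- lapply(fits, function(f) sort(edge_key(f$edges$parent, f$edges$child)))
  m <- length(sets)
  jac <- matrix(1, m, m, dimnames = list(paste0("seed", seeds), paste0("seed", seeds)))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    u <- union(sets[[i]], sets[[j]])
    jac[i, j] <- if (length(u) == 0) 1 else length(intersect(sets[[i]], sets[[j]])) / length(u)
  }
  list(identical = all(vapply(sets, identical, TRUE, y = sets[[1]])),
       jaccard = jac, edge_sets = sets, fits = fits)
}

# --- S3 methods -----------------------------------------------------------

#' @export
print.ecv_network <- function(x, ...) {
  cat(sprintf("ecv_network: %d genes, %d directed edges (score %.2f)\n",
              length(x$genes), nrow(x$edges), x$score))
  invisible(x)
}

#' @export
summary.ecv_network <- function(object, ...) {
  np <- lengths(object$parents)
  out <- list(n_genes = length(object$genes), n_edges = nrow(object$edges),
              score = object$score,
              parents_per_gene = table(factor(np, levels = 0:object$config$max_parents)),
              seed = object$seed)
  class(out) <- "summary.ecv_network"
  out
}

#' @export
print.summary.ecv_network <- function(x, ...) {
  cat(sprintf("Basal gene network: %d genes, %d edges, score %.3f (seed %d)\n",
              x$n_genes, x$n_edges, x$score, x$seed))
  cat("parents per gene:\n")
  print(x$parents_per_gene)
  invisible(x)
}

#' @export
coef.ecv_network <- function(object, ...) {
  lapply(object$smoothers, function(sm) sm$coef)
}

# Apply the stored training standardization to new data on the log-TPM scale.
.standardize_like <- function(object, newdata) {
  newdata <- unclass(newdata)
  if (identical(attr(newdata, "scale_tag"), "standardized")) return(newdata)
  if (!object$standardized) return(newdata)
  missing <- setdiff(object$genes, rownames(newdata))
  if (length(missing) > 0) {
    stop("genes missing from data: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  nd <- newdata[object$genes, , drop = FALSE]
  (nd - object$center[object$genes]) / object$scale[object$genes]
}

#' Predict from a fitted gene network
#'
#' @param object An `ecv_network`.
#' @param newdata Optional genes-by-samples matrix on the scale the network
#'   was fitted on (log TPM if the fit standardized internally; the stored
#'   training standardization is then applied). Defaults to training data.
#' @param type `"ecv"` for the edge-by-sample ECv matrix, `"response"` for
#'   per-node fitted values.
#' @param ... Unused.
#' @export
predict.ecv_network <- function(object, newdata = NULL,
                                type = c("ecv", "response"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$data else .standardize_like(object, newdata)
  if (type == "ecv") return(compute_ecv(object, x))
  out <- matrix(NA_real_, length(object$genes), ncol(x),
                dimnames = list(object$genes, colnames(x)))
  for (g in object$genes) {
    v <- rep(object$intercepts[[g]], ncol(x))
    for (p in object$parents[[g]]) {
      sm <- object$smoothers[[edge_key(p, g)]]
      v <- v + evaluate_smoother(sm, x[p, ])
    }
    out[g, ] <- v
  }
  out
}

#' @export
residuals.ecv_network <- function(object, ...) {
  object$data[object$genes, , drop = FALSE] -
    predict.ecv_network(object, type = "response")
}

#' Simulate samples from a fitted gene network
#'
#' Draws samples on the fitting scale by evaluating each node's intercept
#' and parent smoothers in topological order and adding Gaussian noise with
#' the fitted residual variance.
#'
#' @param object An `ecv_network`.
#' @param nsim Number of samples to draw.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return Genes-by-`nsim` numeric matrix.
#' @export
simulate.ecv_network <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ord <- topological_order(object$genes, object$edges)
  out <- matrix(NA_real_, length(object$genes), nsim,
                dimnames = list(object$genes, paste0("sim", seq_len(nsim))))
  for (g in ord) {
    v <- rep(object$intercepts[[g]], nsim)
    for (p in object$parents[[g]]) {
      sm <- object$smoothers[[edge_key(p, g)]]
      v <- v + evaluate_smoother(sm, out[p, ])
    }
    out[g, ] <- v + stats::rnorm(nsim, 0, sqrt(object$sigma2[[g]]))
  }
  out
}

#' @export
plot.ecv_network <- function(x, ...) {
  g <- igraph::graph_from_data_frame(x$edges, directed = TRUE,
                                     vertices = x$genes)
  graphics::plot(g, vertex.size = 8, edge.arrow.size = 0.4,
                 layout = igraph::layout_with_fr(g, niter = 200), ...)
  invisible(x)
}

#' Topologically sort genes given a directed edge set
#'
#' Errors if the edge set contains a cycle; used both as an invariant check
#' and to schedule simulation.
#'
#' @param genes Character vector of node names.
#' @param edges data.frame with `parent`, `child` columns.
#' @return Character vector: the genes in a topological order.
#' @export
topological_order <- function(genes, edges) {
  indeg <- stats::setNames(integer(length(genes)), genes)
  kids <- stats::setNames(rep(list(character(0)), length(genes)), genes)
  for (i in seq_len(nrow(edges))) {
    indeg[[edges$child[i]]] <- indeg[[edges$child[i]]] + 1L
    kids[[edges$parent[i]]] <- c(kids[[edges$parent[i]]], edges$child[i])
  }
  queue <- sort(names(indeg)[indeg == 0L])
  out <- character(0)
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    out <- c(out, v)
    for (w in kids[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- sort(c(queue, w))
    }
  }
  if (length(out) != length(genes)) stop("edge set contains a cycle", call. = FALSE)
  out
}
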