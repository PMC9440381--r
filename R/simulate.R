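# Hand-coded Cox-de Boor recursion. This is the package's independent route
# for evaluating B-spline expansions: it shares no code with the
# splineDesign-based basis used by the fitting path, so tests can compare
# the two implementations of the same mathematics.
deboor_basis <- function(knots, x, degree = 3L) {
  K <- length(knots) - degree - 1L
  n <- length(x)
  B <- matrix(0, n, K)
  lo <- knots[degree + 1L]
  hi <- knots[length(knots) - degree]
  x <- pmin(pmax(x, lo), hi)
  # order-1 (degree-0) indicator functions on half-open intervals, with the
  # rightmost nonempty interval closed so x == hi is handled exactly
  nb0 <- length(knots) - 1L
  N <- matrix(0, n, nb0)
  for (j in seq_len(nb0)) {
    up <- knots[j + 1L]
    N[, j] <- as.numeric(x >= knots[j] &
                           (x < up | (x == hi & up == hi & knots[j] < hi)))
  }
  for (d in seq_len(degree)) {
    nb <- nb0 - d
    Nn <- matrix(0, n, nb)
    for (j in seq_len(nb)) {
      d1 <- knots[j + d] - knots[j]
      d2 <- knots[j + d + 1L] - knots[j + 1L]
      t1 <- if (d1 > 0) (x - knots[j]) / d1 * N[, j] else 0
      t2 <- if (d2 > 0) (knots[j + d + 1L] - x) / d2 * N[, j + 1L] else 0
      Nn[, j] <- t1 + t2
    }
    N <- Nn
  }
  B[, ] <- N[, seq_len(K)]
  B
}

# Fixed knot grid shared by all true edge functions: cubic basis on [-4, 4]
# with 6 interior knots (10 basis functions). Inputs are clamped to the
# boundary, so functions saturate outside the grid.
.truth_knots <- function() {
  c(rep(-4, 4), seq(-3, 3, length.out = 6), rep(4, 4))
}

# Evaluate a true edge function (B-spline coefficient vector on the fixed
# grid) at x, continuing linearly beyond the grid so that dependencies are
# preserved for inputs outside the central range.
truth_eval <- function(coef, x) {
  knots <- .truth_knots()
  lo <- knots[4L]; hi <- knots[length(knots) - 3L]
  xc <- pmin(pmax(x, lo), hi)
  v <- drop(deboor_basis(knots, xc) %*% coef)
  out_lo <- x < lo; out_hi <- x > hi
  if (any(out_lo)) {
    h <- (hi - lo) * 1e-6
    slope <- (drop(deboor_basis(knots, lo + h) %*% coef) -
                drop(deboor_basis(knots, lo) %*% coef)) / h
    v[out_lo] <- v[out_lo] + (x[out_lo] - lo) * slope
  }
  if (any(out_hi)) {
    h <- (hi - lo) * 1e-6
    slope <- (drop(deboor_basis(knots, hi) %*% coef) -
                drop(deboor_basis(knots, hi - h) %*% coef)) / h
    v[out_hi] <- v[out_hi] + (x[out_hi] - hi) * slope
  }
  v
}

# Draw one monotone edge function: sorted uniform basis coefficients
# (monotone spline), random direction, rescaled so the response has spread
# `amplitude` over the central input range, plus a nonzero activity offset.
# Ablating the edge therefore removes both a dependence and a mean input
# to the child, as losing a regulator does.
.draw_edge_function <- function(amplitude) {
  K <- length(.truth_knots()) - 4L
  cf <- sort(stats::runif(K))
  if (stats::runif(1) < 0.5) cf <- rev(cf)
  grid <- seq(-2.5, 2.5, length.out = 101)
  f0 <- truth_eval(cf, grid)
  s <- stats::sd(f0)
  offset <- stats::runif(1, -amplitude / 2, amplitude / 2)
  # affine transform of the coefficients (full bases sum to one, so the
  # constant shift folds into the coefficients)
  amplitude * (cf - mean(f0)) / s + offset
}

#' Generate a known ground-truth gene network
#'
#' Samples an acyclic directed network over a random topological order:
#' each (earlier, later) gene pair carries an edge with probability
#' `density`, children are capped at `max_parents` parents, and every edge
#' gets a random monotone cubic-spline function on a fixed knot grid with
#' response spread `amplitude` and a nonzero activity offset. `n_perturb`
#' edges are chosen uniformly as perturbed: in case samples their function
#' is multiplied by `effect` (0 = ablation).
#'
#' @param n_genes Number of genes (>= 2).
#' @param density Edge probability per ordered pair, in `[0, 1]`.
#' @param n_perturb Number of perturbed edges (must not exceed the sampled
#'   edge count).
#' @param effect Multiplier applied to perturbed edge functions in the case
#'   group (>= 0; 1 = no perturbation).
#' @param seed Seed (expanded via [stage_seed()]).
#' @param max_parents Parent cap per gene.
#' @param amplitude Response spread of each edge function on the latent
#'   (standardized log-expression) scale.
#' @param noise_sd Latent Gaussian noise standard deviation per gene.
#' @param intercept_range Range of per-gene baseline log2 expression.
#' @param lib_range Range of per-sample library sizes (expected total reads).
#' @param n_background Number of additional independent background genes
#'   included in the count matrix (but not in the network). They emulate
#'   the bulk of a transcriptome, so that per-sample TPM denominators are
#'   buffered as they are in real data rather than dominated by the
#'   network genes.
#' @details Edge functions take the parent's *standardized* latent
#'   deviation as input (each node's deviation scale `tau` is propagated
#'   analytically at generation time), which keeps latent variance bounded
#'   along the graph and inputs within the spline grid.
#' @return Object of class `synthetic_truth`.
#' @export
generate_truth <- function(n_genes = 100L, density = 0.008, n_perturb = 5L,
                           effect = 0, seed = 1L, max_parents = 3L,
                           amplitude = 0.8, noise_sd = 0.35,
                           intercept_range = c(5, 8),
                           lib_range = c(1e5, 3e5),
                           n_background = 5L * n_genes) {
  stopifnot(n_genes >= 2, density >= 0, density <= 1, n_perturb >= 0, effect >= 0)
  set.seed(stage_seed(seed, "truth"))
  genes <- sprintf("ENSGSYN%05d", seq_len(n_genes))
  ord <- sample(genes)
  edges_p <- character(0); edges_c <- character(0)
  for (j in seq_len(n_genes)[-1]) {
    pot <- ord[seq_len(j - 1)]
    take <- which(stats::runif(length(pot)) < density)
    if (length(take) > max_parents) take <- sort(sample(take, max_parents))
    if (length(take) > 0) {
      edges_p <- c(edges_p, pot[take])
      edges_c <- c(edges_c, rep(ord[j], length(take)))
    }
  }
  edges <- data.frame(parent = edges_p, child = edges_c, stringsAsFactors = FALSE)
  if (n_perturb > nrow(edges)) {
    stop(sprintf("requested %d perturbed edges but only %d edges sampled",
                 n_perturb, nrow(edges)), call. = FALSE)
  }
  functions <- lapply(seq_len(nrow(edges)),
                      function(i) .draw_edge_function(amplitude))
  names(functions) <- if (nrow(edges) > 0) {
    edge_key(edges$parent, edges$child)
  } else {
    character(0)
  }

  # Each edge function takes the parent's STANDARDIZED deviation as input
  # (regulators act relative to their own dynamic range); the deviation
  # scale tau of every node is propagated analytically so that latent
  # variance stays bounded along the graph. Var(f(U)) for U ~ N(0,1) is
  # evaluated by quadrature.
  noise_sd_vec <- stats::setNames(rep_len(noise_sd, n_genes), genes)
  grid <- seq(-4, 4, length.out = 201)
  wq <- stats::dnorm(grid); wq <- wq / sum(wq)
  fn_var <- vapply(functions, function(cf) {
    v <- truth_eval(cf, grid)
    m <- sum(wq * v)
    sum(wq * (v - m)^2)
  }, 0)
  tau <- stats::setNames(rep(NA_real_, n_genes), genes)
  for (g in ord) {
    idx <- which(edges$child == g)
    tau[[g]] <- sqrt(sum(fn_var[idx]) + noise_sd_vec[[g]]^2)
  }
  perturbed_idx <- if (n_perturb > 0) sort(sample(nrow(edges), n_perturb)) else integer(0)
  perturbed <- edges[perturbed_idx, , drop = FALSE]
  rownames(perturbed) <- NULL
  if (nrow(perturbed) > 0) perturbed$multiplier <- effect
  else perturbed$multiplier <- numeric(0)
  bg_genes <- if (n_background > 0) {
    sprintf("BGSYN%05d", seq_len(n_background))
  } else {
    character(0)
  }
  all_genes <- c(genes, bg_genes)
  structure(list(
    genes = genes, background_genes = bg_genes,
    order = ord, edges = edges, functions = functions,
    perturbed = perturbed,
    intercepts = stats::setNames(stats::runif(length(all_genes),
                                              intercept_range[1],
                                              intercept_range[2]), all_genes),
    noise_sd = noise_sd_vec, tau = tau,
    background_sd = stats::setNames(rep(1, n_background), bg_genes),
    gene_lengths = stats::setNames(sample(500:3000, length(all_genes),
                                          replace = TRUE), all_genes),
    lib_range = lib_range, max_parents = max_parents, amplitude = amplitude,
    density = density, seed = seed
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d genes, %d edges, %d perturbed (multiplier %s)\n",
              length(x$genes), nrow(x$edges), nrow(x$perturbed),
              if (nrow(x$perturbed) > 0) format(x$perturbed$multiplier[1]) else "-"))
  invisible(x)
}

.edge_multipliers <- function(truth) {
  mult <- stats::setNames(rep(1, nrow(truth$edges)),
                          edge_key(truth$edges$parent, truth$edges$child))
  if (nrow(truth$perturbed) > 0) {
    mult[edge_key(truth$perturbed$parent, truth$perturbed$child)] <-
      truth$perturbed$multiplier
  }
  mult
}

#' Simulate read counts from a ground-truth network
#'
#' Latent log-expression is generated in topological order: each gene's
#' latent deviation is the sum of its incoming edge functions evaluated at
#' the parents' deviations (multiplied by the perturbation multiplier for
#' case samples on perturbed edges) plus Gaussian noise; log2 expression is
#' the gene intercept plus this deviation. Expected transcript abundance
#' `2^log2expr` is then converted to integer counts with per-sample library
#' sizes and per-gene length weighting via a Poisson draw (negative
#' binomial when `overdispersion` is set).
#'
#' @param truth A [generate_truth()] object.
#' @param n_case,n_control Positive group sizes (the study shape is 11 vs 9).
#' @param seed Seed (expanded via [stage_seed()]).
#' @param overdispersion Optional negative-binomial overdispersion
#'   (`NULL` = Poisson).
#' @return List with `counts` (a [count_matrix()]), `labels`
#'   (a [sample_labels()] factor, cases first), and `latent` (the
#'   genes-by-samples matrix of latent deviations, for oracle checks).
#' @export
simulate_counts <- function(truth, n_case = 11L, n_control = 9L, seed = 1L,
                            overdispersion = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), n_case >= 1, n_control >= 1)
  set.seed(stage_seed(seed, "counts"))
  n <- n_case + n_control
  sample_ids <- c(sprintf("case_%02d", seq_len(n_case)),
                  sprintf("control_%02d", seq_len(n_control)))
  is_case <- c(rep(TRUE, n_case), rep(FALSE, n_control))
  mult <- .edge_multipliers(truth)
  all_genes <- c(truth$genes, truth$background_genes)

  latent <- matrix(0, length(all_genes), n,
                   dimnames = list(all_genes, sample_ids))
  parents_of <- split(truth$edges$parent, factor(truth$edges$child,
                                                 levels = truth$genes))
  for (g in truth$order) {
    s <- rep(0, n)
    for (p in parents_of[[g]]) {
      key <- edge_key(p, g)
      f <- truth_eval(truth$functions[[key]], latent[p, ] / truth$tau[[p]])
      m <- ifelse(is_case, mult[[key]], 1)
      s <- s + m * f
    }
    latent[g, ] <- s + stats::rnorm(n, 0, truth$noise_sd[[g]])
  }
  for (g in truth$background_genes) {
    latent[g, ] <- stats::rnorm(n, 0, truth$background_sd[[g]])
  }
  log2expr <- truth$intercepts[all_genes] + latent
  abundance <- 2^log2expr
  w <- abundance * truth$gene_lengths
  lib <- stats::runif(n, truth$lib_range[1], truth$lib_range[2])
  lambda <- sweep(w, 2, colSums(w), "/") * rep(lib, each = nrow(w))
  counts <- if (is.null(overdispersion)) {
    matrix(stats::rpois(length(lambda), lambda), nrow(lambda))
  } else {
    matrix(stats::rnbinom(length(lambda), mu = lambda,
                          size = 1 / overdispersion), nrow(lambda))
  }
  dimnames(counts) <- dimnames(lambda)
  list(counts = count_matrix(counts, truth$gene_lengths),
       labels = sample_labels(sample_ids, ifelse(is_case, "case", "control")),
       latent = latent[truth$genes, , drop = FALSE])
}

#' Brute-force oracle for an edge's true contribution
#'
#' Evaluates the TRUE edge function of a ground-truth network at one
#' sample's latent parent value by direct basis expansion (the hand-coded
#' de Boor recursion), applying the case-group multiplier when requested.
#' Independent of the fitting/ECv code path; used to cross-check
#' [compute_ecv()]-style evaluations at the truth level.
#'
#' @param truth A [generate_truth()] object.
#' @param latent Named latent deviation vector of one sample (a column of
#'   `simulate_counts()$latent`).
#' @param parent,child Edge to evaluate (must exist in the truth).
#' @param case Evaluate under the case-group multiplier.
#' @return The true contribution value (scalar).
#' @export
oracle_ecv <- function(truth, latent, parent, child, case = FALSE) {
  key <- edge_key(parent, child)
  if (!key %in% names(truth$functions)) {
    stop("unknown edge: ", key, call. = FALSE)
  }
  v <- truth_eval(truth$functions[[key]], latent[[parent]] / truth$tau[[parent]])
  if (case) {
    m <- .edge_multipliers(truth)[[key]]
    v <- m * v
  }
  v
}
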