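# Fit a tiny network on data where v is an exact linear function of u so
# the edge smoother is effectively linear.
linear_net <- function(n = 80, slope = 2, seed = 1) {
  set.seed(seed)
  u <- rnorm(n)
  x <- rbind(u = u, v = slope * u)
  colnames(x) <- sprintf("s%03d", seq_len(n))
  # no standardization so the closed form stays transparent
  cfg <- pipeline_config(candidate_parents_k = 1, restarts = 1,
                         standardize = FALSE)
  net <- ecv_network(x, cfg, seed = 1)
  list(net = net, x = x, u = u)
}

test_that("ECv of a linear edge equals slope times the centered parent value", {
  L <- linear_net()
  net <- L$net
  expect_identical(nrow(net$edges), 1L)
  ecv <- compute_ecv(net)
  key <- rownames(ecv)[1]
  parent <- net$edges$parent[1]
  slope_sign <- if (parent == "u") 2 else 0.5
  centered <- L$x[parent, ] - mean(L$x[parent, ])
  expect_equal(unname(ecv[1, ]), unname(slope_sign * centered), tolerance = 1e-6)

  # a sample sitting at the training mean of the parent has ECv ~ 0
  probe <- L$x[, 1:2, drop = FALSE]
  probe[parent, 1] <- mean(L$x[parent, ])
  ecv2 <- compute_ecv(net, probe)
  expect_lt(abs(ecv2[1, 1]), 1e-9)

  expect_error(compute_ecv(net, L$x[setdiff(rownames(L$x), parent), , drop = FALSE]),
               "missing")
})

test_that("ECv matches an independent de Boor basis expansion", {
  tr <- generate_truth(n_genes = 12, density = 0.2, n_perturb = 0, seed = 21)
  sim <- simulate_counts(tr, 30, 30, seed = 21)
  lg <- log_transform(compute_tpm(sim$counts))[tr$genes, ]
  net <- ecv_network(lg, pipeline_config(restarts = 2), seed = 1)
  expect_gt(nrow(net$edges), 0)
  ecv <- compute_ecv(net)
  set.seed(22)
  for (rep in 1:1000) {
    i <- sample(nrow(net$edges), 1)
    s <- sample(ncol(ecv), 1)
    e <- net$edges[i, ]
    sm <- net$smoothers[[paste0(e$parent, "~", e$child)]]
    xval <- net$data[e$parent, s]
    indep <- drop(ecvnet:::deboor_basis(sm$knots, xval)[, -1, drop = FALSE] %*%
                    sm$coef) - sm$center
    expect_equal(unname(ecv[i, s]), unname(indep), tolerance = 1e-9)
  }
})

test_that("differential edges are ranked and selected as specified", {
  # hand-built ECv matrix: 5 edges with group deltas 0..4
  edges <- data.frame(parent = sprintf("p%d", 1:5), child = sprintf("c%d", 1:5),
                      stringsAsFactors = FALSE)
  vals <- rbind(rep(0, 8),
                c(rep(1, 4), rep(0, 4)),
                c(rep(2, 4), rep(0, 4)),
                c(rep(3, 4), rep(0, 4)),
                c(rep(4, 4), rep(0, 4)))
  dimnames(vals) <- list(paste0(edges$parent, "~", edges$child),
                         sprintf("s%d", 1:8))
  ecv <- structure(vals, edges = edges, class = c("ecv_matrix", "matrix", "array"))
  lab <- sample_labels(colnames(vals), rep(c("case", "control"), each = 4))
  de <- differential_edges(ecv, lab, q = 3 / 5, floor_n = 1)
  expect_identical(de$n_selected, 3L)
  expect_equal(de$selected$delta, c(4, 3, 2))
  expect_identical(de$selected$parent, c("p5", "p4", "p3"))

  # identical groups: all deltas zero, floor 1 keeps the lexically first edge
  lab2 <- sample_labels(colnames(vals), rep(c("case", "control"), 4))
  vals0 <- vals; vals0[] <- rep(vals[, 1], 8)
  ecv0 <- structure(vals0, edges = edges, class = class(ecv))
  de0 <- differential_edges(ecv0, lab2, q = 1e-5, floor_n = 1)
  expect_identical(de0$n_selected, 1L)
  expect_identical(de0$selected$parent, "p1")
  expect_equal(de0$selected$delta, 0)
})

test_that("the selection-count arithmetic holds", {
  # top 0.001% of one million edges is ten edges
  expect_identical(ecvnet:::selection_count(1e-5, 1e6, 1L), 10L)
  expect_identical(ecvnet:::selection_count(1e-5, 100, 1L), 1L)   # floor
  expect_identical(ecvnet:::selection_count(1, 42, 1L), 42L)      # cap
})

test_that("selection is monotone in the fraction q", {
  set.seed(23)
  edges <- data.frame(parent = sprintf("p%02d", 1:20),
                      child = sprintf("c%02d", 1:20), stringsAsFactors = FALSE)
  vals <- matrix(rnorm(20 * 10), 20, 10,
                 dimnames = list(paste0(edges$parent, "~", edges$child),
                                 sprintf("s%d", 1:10)))
  ecv <- structure(vals, edges = edges, class = c("ecv_matrix", "matrix", "array"))
  lab <- sample_labels(colnames(vals), rep(c("case", "control"), each = 5))
  sel_prev <- character(0)
  for (q in c(0.1, 0.3, 0.5, 1)) {
    de <- differential_edges(ecv, lab, q = q, floor_n = 1)
    sel <- paste(de$selected$parent, de$selected$child)
    expect_true(all(sel_prev %in% sel))
    sel_prev <- sel
  }
})

test_that("subnetworks are the weakly connected components of the selection", {
  e1 <- data.frame(parent = c("a", "c"), child = c("b", "d"), delta = c(1, 2))
  s1 <- extract_subnetworks(e1)
  expect_length(s1, 2)
  expect_identical(lapply(s1, `[[`, "genes"), list(c("a", "b"), c("c", "d")))

  e2 <- data.frame(parent = c("a", "b", "d"), child = c("b", "c", "e"),
                   delta = c(1, 2, 3))
  s2 <- extract_subnetworks(e2)
  expect_identical(s2[[1]]$genes, c("a", "b", "c"))   # larger component first
  expect_identical(s2[[2]]$genes, c("d", "e"))

  # partition invariant: each edge in exactly one component, gene sets disjoint
  all_edges <- do.call(rbind, lapply(s2, `[[`, "edges"))
  expect_identical(nrow(all_edges), nrow(e2))
  expect_identical(anyDuplicated(unlist(lapply(s2, `[[`, "genes"))), 0L)
  expect_error(extract_subnetworks(e1[0, ]), "empty")
})

test_that("subnetwork statistics pick the best-AUC representative", {
  fix <- marker_tpm(seed = 31, k = 4, n = 30)
  tpm <- unclass(fix$tpm)
  # make G02 an exact scalar multiple of G01 -> |r| = 1, and give G03 a
  # strong group effect so it wins the AUC in its own subnetwork
  tpm["G02", ] <- 3 * tpm["G01", ]
  tpm["G03", fix$labels == "case"] <- tpm["G03", fix$labels == "case"] * 10
  tpm["FILLER", ] <- 1e6 - colSums(tpm[c("G01", "G02", "G03", "G04"), ])
  tpm <- tpm_matrix(tpm)
  subnets <- list(
    list(id = 1, genes = c("G01", "G02"),
         edges = data.frame(parent = "G01", child = "G02", delta = 1)),
    list(id = 2, genes = c("G03", "G04"),
         edges = data.frame(parent = "G03", child = "G04", delta = 1)))
  out <- subnetwork_stats(subnets, tpm, fix$labels)
  expect_equal(out[[1]]$min_abs_cor, 1, tolerance = 1e-12)
  expect_identical(out[[2]]$representative, "G03")
  expect_gte(out[[2]]$representative_auc, out[[2]]$auc[["G04"]])
  for (s in out) expect_true(all(s$auc >= 0.5 & s$auc <= 1))
  expect_error(subnetwork_stats(list(list(id = 1, genes = "nope",
                                          edges = e1 <- data.frame(parent = "nope", child = "x", delta = 1))),
                                tpm, fix$labels), "missing")
})
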