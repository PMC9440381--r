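test_that("smoothers interpolate linear signals and stay centered", {
  set.seed(1)
  x <- rnorm(60)
  sm <- fit_smoother(x, x, spline_df = 6)
  expect_lt(max(abs(evaluate_smoother(sm, x) - (x - mean(x)))), 1e-6)
  expect_lt(abs(mean(attr(sm, "contribution"))), 1e-9)

  # pure-noise child: fitted contribution explains almost nothing
  set.seed(2)
  xp <- rnorm(200); y <- rnorm(200)
  smn <- fit_smoother(xp, y, spline_df = 4)
  expect_lt(stats::var(attr(smn, "contribution")), 0.2 * stats::var(y))
  expect_lt(abs(mean(attr(smn, "contribution"))), 1e-9)

  expect_error(fit_smoother(rep(1, 50), rnorm(50)), "constant")
  expect_error(fit_smoother(rnorm(4), rnorm(4)), "samples")
})

test_that("a sine signal is recovered within the expected error", {
  set.seed(3)
  x <- seq(-pi, pi, length.out = 200)
  y <- sin(x) + rnorm(200, 0, 0.1)
  sm <- fit_smoother(x, y, spline_df = 6)
  fitted <- evaluate_smoother(sm, x) + mean(y)
  expect_lt(sqrt(mean((fitted - sin(x))^2)), 0.15)
})

test_that("smoother evaluation extrapolates linearly beyond the data range", {
  set.seed(4)
  x <- runif(100, -1, 1)
  sm <- fit_smoother(x, 2 * x, spline_df = 4)
  # second differences vanish on a straight line: f(-3) is the midpoint of
  # f(-2.5) and f(-3.5) outside the boundary knots
  out <- evaluate_smoother(sm, c(-3, 3))
  mid <- evaluate_smoother(sm, c(-2.5, 2.5))
  far <- evaluate_smoother(sm, c(-3.5, 3.5))
  expect_equal(2 * out, mid + far, tolerance = 1e-6)
})

test_that("the empty-parent local score matches a hand-computed likelihood", {
  y <- c(1, 2, 4)
  x <- rbind(child = y, other = c(0, 1, 0))
  colnames(x) <- c("a", "b", "c")
  s2 <- mean((y - mean(y))^2)
  hand <- 3 * (log(2 * pi * s2) + 1) + log(3) * 2
  expect_equal(local_score("child", character(0), x), hand, tolerance = 1e-12)
  expect_error(local_score("child", "child", x), "own parent")
})

test_that("an independent-noise parent worsens the score nearly always", {
  worse <- 0
  for (s in 1:100) {
    set.seed(s)
    x <- rbind(child = rnorm(300), noise = rnorm(300))
    colnames(x) <- sprintf("s%03d", 1:300)
    s0 <- local_score("child", character(0), x)
    s1 <- local_score("child", "noise", x)
    worse <- worse + (s1 > s0)
  }
  expect_gte(worse, 95)
})

test_that("candidate parents rank by absolute rank correlation", {
  set.seed(5)
  base <- rnorm(50)
  x <- rbind(a = base, b = base, c = rnorm(50), d = rnorm(50))
  colnames(x) <- sprintf("s%02d", 1:50)
  cand <- candidate_parents(x, k = 2)
  expect_identical(cand$a[1], "b")   # duplicated pair lists each other first
  expect_identical(cand$b[1], "a")
  cand_all <- candidate_parents(x, k = 10)
  expect_identical(sort(cand_all$a), c("b", "c", "d"))  # k >= n-1: complete

  # on a chain, the true parent is among the candidates
  hits <- 0
  for (s in 1:30) {
    xd <- chain_data(100, seed = s)
    cd <- candidate_parents(xd, k = 2)
    hits <- hits + (("u" %in% cd$v) && ("v" %in% cd$w))
  }
  expect_gte(hits, 28)
})

test_that("structure learning recovers a smooth chain and stays acyclic", {
  x <- chain_data(200, seed = 1)
  cfg <- pipeline_config(candidate_parents_k = 2, restarts = 2)
  net <- ecv_network(x, cfg, seed = 1)
  skel <- sort(paste(pmin(net$edges$parent, net$edges$child),
                     pmax(net$edges$parent, net$edges$child)))
  expect_identical(skel, c("u v", "v w"))

  for (s in 1:5) {
    xs <- chain_data(120, seed = s + 10)
    nets <- ecv_network(xs, cfg, seed = s)
    expect_silent(topological_order(nets$genes, nets$edges))
  }
})

test_that("mutually independent genes yield an empty network", {
  set.seed(6)
  x <- matrix(rnorm(10 * 100), 10, 100,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%03d", 1:100)))
  net <- ecv_network(x, pipeline_config(restarts = 2), seed = 1)
  expect_identical(nrow(net$edges), 0L)
})

test_that("the network score decomposes into node local scores", {
  tr <- generate_truth(n_genes = 10, density = 0.15, n_perturb = 0, seed = 8)
  sim <- simulate_counts(tr, 40, 40, seed = 8)
  lg <- log_transform(compute_tpm(sim$counts))[tr$genes, ]
  cfg <- pipeline_config(restarts = 2)
  net <- ecv_network(lg, cfg, seed = 1)
  total <- sum(vapply(net$genes, function(g) {
    local_score(g, net$parents[[g]], net$data, cfg)
  }, 0))
  expect_equal(net$score, total, tolerance = 1e-6)
})

test_that("learning is deterministic given data, config and seed", {
  tr <- generate_truth(n_genes = 8, density = 0.2, n_perturb = 0, seed = 9)
  sim <- simulate_counts(tr, 30, 30, seed = 9)
  lg <- log_transform(compute_tpm(sim$counts))[tr$genes, ]
  cfg <- pipeline_config(restarts = 2)
  n1 <- ecv_network(lg, cfg, seed = 3)
  n2 <- ecv_network(lg, cfg, seed = 3)
  expect_identical(n1$edges, n2$edges)
  expect_equal(coef(n1), coef(n2), tolerance = 0)
  expect_identical(n1$score, n2$score)
})

test_that("constant genes are dropped with a warning before the search", {
  set.seed(10)
  x <- rbind(a = rnorm(40), b = rnorm(40), flat = rep(2, 40))
  colnames(x) <- sprintf("s%02d", 1:40)
  expect_warning(net <- ecv_network(x, pipeline_config(restarts = 1), seed = 1),
                 "constant")
  expect_false("flat" %in% net$genes)
})

test_that("reproducibility checking reports identity and Jaccard gracefully", {
  # identical seeds: identical by construction
  tr <- generate_truth(n_genes = 8, density = 0.15, n_perturb = 0, seed = 11)
  sim <- simulate_counts(tr, 30, 30, seed = 11)
  lg <- log_transform(compute_tpm(sim$counts))[tr$genes, ]
  cfg <- pipeline_config(restarts = 2)
  rep_same <- check_reproducibility(lg, cfg, seeds = c(5, 5, 5))
  expect_true(rep_same$identical)
  expect_equal(min(rep_same$jaccard), 1)

  # weak signal: must return a report, identical or not
  set.seed(12)
  noisy <- matrix(rnorm(6 * 30), 6, 30,
                  dimnames = list(sprintf("g%d", 1:6), sprintf("s%02d", 1:30)))
  rep_weak <- check_reproducibility(noisy, cfg, seeds = c(1, 2, 3))
  expect_true(is.logical(rep_weak$identical))
  expect_true(all(rep_weak$jaccard >= 0 & rep_weak$jaccard <= 1))
})

test_that("network model methods are coherent", {
  x <- chain_data(150, seed = 13)
  net <- ecv_network(x, pipeline_config(candidate_parents_k = 2, restarts = 2),
                     seed = 1)
  fitted <- predict(net, type = "response")
  res <- residuals(net)
  expect_equal(net$data[net$genes, ] - fitted, res, tolerance = 1e-12)
  # residual variance matches the stored sigma2 (MLE, denominator n)
  for (g in net$genes) {
    expect_equal(mean(res[g, ]^2), unname(net$sigma2[[g]]), tolerance = 1e-8)
  }
  sims <- simulate(net, nsim = 50, seed = 99)
  expect_identical(dim(sims), c(3L, 50L))
  expect_output(print(net), "ecv_network")
  expect_output(print(summary(net)), "parents per gene")
})
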