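test_that("read_newick parses, validates and normalizes trees", {
  t2 <- read_newick(nwk_cherry, normalize_depth = FALSE)
  expect_s3_class(t2, "phylo_tree")
  expect_setequal(t2$tip.label, c("A", "B"))
  expect_equal(tree_depth(t2), 1)

  t3 <- read_newick(nwk_3tip, normalize_depth = FALSE)
  expect_equal(tree_depth(t3), 2)
  t3n <- read_newick(nwk_3tip, normalize_depth = TRUE)
  expect_equal(tree_depth(t3n), 1)
  # internal edge 1 scaled by depth 2 -> 0.5
  internal <- t3n$edge.length[t3n$edge[, 2] > length(t3n$tip.label)]
  expect_equal(internal, 0.5)

  expect_error(read_newick("((A:1,B:2):1,C:2);"), "not ultrametric.*A.*B|not ultrametric.*B.*A")
  expect_error(read_newick("((A:1,B:1):1,A:2);"), "duplicate")
  expect_error(read_newick("((A,B),C);"), "branch lengths")
  expect_error(read_newick("not a newick"), "parse")
})

test_that("shared_path_times matches topology and a patristic-distance oracle", {
  t2 <- read_newick(nwk_cherry, normalize_depth = FALSE)
  tm <- shared_path_times(t2)
  expect_equal(tm["A", "B"], 0)
  expect_equal(unname(diag(tm)), c(1, 1))

  t3 <- read_newick(nwk_3tip, normalize_depth = FALSE)
  tm3 <- shared_path_times(t3)
  expect_equal(tm3["A", "B"], 1)
  expect_equal(tm3["A", "C"], 0)
  expect_equal(tm3["B", "C"], 0)

  # random Yule trees: t_ij = depth - d_ij / 2 with d_ij patristic (cophenetic)
  for (seed in 1:3) {
    tr <- simulate_yule_tree(10, seed = seed)
    tm <- shared_path_times(tr)
    d <- ape::cophenetic.phylo(tr)[rownames(tm), colnames(tm)]
    oracle <- tree_depth(tr) - d / 2
    diag(oracle) <- diag(tm)
    expect_equal(tm, oracle, tolerance = 1e-8)
  }
})

test_that("ou_correlation obeys closed-form limits and the stated formula", {
  tr <- read_newick(nwk_3tip_half, normalize_depth = FALSE)
  # alpha -> 0 limit is the BM correlation t_ij / T
  expect_equal(ou_correlation(tr, 0)$matrix, bm_correlation(tr)$matrix,
               tolerance = 1e-10)
  # alpha large: effectively identity
  big <- ou_correlation(tr, 50)$matrix
  expect_equal(unname(diag(big)), rep(1, 3))
  expect_lt(max(abs(big[upper.tri(big)])), 1e-6)
  # direct scalar evaluation of the covariance formula at alpha = 1
  a <- 1; T <- 1; tAB <- 0.5
  vab <- (1 / (2 * a)) * exp(-2 * a * (T - tAB)) * (1 - exp(-2 * a * tAB))
  vii <- (1 / (2 * a)) * (1 - exp(-2 * a * T))
  R <- ou_correlation(tr, 1)$matrix
  expect_equal(R["A", "B"], vab / vii, tolerance = 1e-12)
  expect_equal(R["A", "C"], 0, tolerance = 1e-12)
  expect_error(ou_correlation(tr, -1), "alpha")
})

test_that("OU correlations satisfy invariants and decrease in alpha (property)", {
  alphas <- c(0, 0.1, 0.5, 1, 2, 5, 10, 50)
  for (seed in 1:4) {
    tr <- simulate_yule_tree(sample(5:25, 1), seed = seed)
    prev <- NULL
    for (a in alphas) {
      cs <- ou_correlation(tr, a)
      expect_correlation_invariants(cs)
      off <- cs$matrix[upper.tri(cs$matrix)]
      if (!is.null(prev)) expect_true(all(off <= prev + 1e-10))
      prev <- off
    }
  }
})

test_that("lambda_correlation boundary and hand-evaluated cases", {
  tr <- read_newick(nwk_3tip_half, normalize_depth = FALSE)
  expect_equal(unname(lambda_correlation(tr, 0)$matrix), diag(3))
  expect_equal(lambda_correlation(tr, 1)$matrix, bm_correlation(tr)$matrix)
  R <- lambda_correlation(tr, 0.5)$matrix
  expect_equal(R["A", "B"], 0.25)
  expect_equal(R["A", "C"], 0)
  expect_error(lambda_correlation(tr, 1.2), "lambda")
  expect_error(lambda_correlation(tr, -0.1), "lambda")
  # lambda = 1 equals the OU alpha -> 0 limit
  tr2 <- simulate_yule_tree(20, seed = 9)
  expect_equal(lambda_correlation(tr2, 1)$matrix, ou_correlation(tr2, 0)$matrix,
               tolerance = 1e-8)
})

test_that("nearest_pd_jitter inflates minimally and errors when hopeless", {
  id <- diag(4)
  out <- nearest_pd_jitter(id)
  expect_equal(attr(out, "jitter"), 0)
  expect_equal(unname(out), id, ignore_attr = TRUE)

  tr <- simulate_yule_tree(20, seed = 3)
  R <- ou_correlation(tr, 2)$matrix
  expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
  out2 <- nearest_pd_jitter(R)
  expect_equal(attr(out2, "jitter"), 0)

  ones <- matrix(1, 3, 3)
  out3 <- nearest_pd_jitter(ones)
  expect_lte(attr(out3, "jitter"), 1e-6)
  expect_gt(attr(out3, "jitter"), 0)

  expect_error(nearest_pd_jitter(matrix(c(1, 2, 3, 4), 2)), "symmetric")
  neg <- diag(c(1, -5))
  expect_error(nearest_pd_jitter(neg), "not positive definite")
})

test_that("correlation CSV export round-trips labels", {
  tr <- simulate_yule_tree(6, seed = 2)
  cs <- ou_correlation(tr, 1)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_correlation_csv(cs, f)
  back <- read.csv(f)
  expect_equal(back$species, cs$labels)
  expect_equal(as.matrix(back[, -1]), unname(cs$matrix), ignore_attr = TRUE,
               tolerance = 1e-12)
})
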