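make_panel <- function(scores_by_panelist, samples = c("s1", "s2"),
                       attrs = c("sweet", "starchy")) {
  do.call(rbind, lapply(names(scores_by_panelist), function(p) {
    data.frame(panelist = p,
               expand.grid(sample = samples, attribute = attrs,
                           stringsAsFactors = FALSE),
               score = scores_by_panelist[[p]])
  }))
}

test_that("QDA aggregation averages panelists and enforces the grid", {
  one <- make_panel(list(P1 = c(4, 5, 6, 7)))
  m1 <- aggregate_qda(one)
  expect_equal(unname(m1["s1", "sweet"]), 4)
  expect_equal(unname(m1["s2", "starchy"]), 7)

  two <- make_panel(list(P1 = c(4, 4, 4, 4), P2 = c(5, 5, 5, 5)))
  expect_true(all(aggregate_qda(two) == 4.5))

  bad <- make_panel(list(P1 = c(9.25, 5, 6, 7)))
  expect_error(aggregate_qda(bad), "half-point grid")
  neg <- make_panel(list(P1 = c(-0.5, 5, 6, 7)))
  expect_error(aggregate_qda(neg), "half-point grid")
})

test_that("Ward clustering boundary cuts give the definitional WCSS", {
  set.seed(10)
  X <- matrix(rnorm(8 * 4), 8, dimnames = list(paste0("s", 1:8), NULL))
  expect_equal(ward_cluster(X, k = 8)$wcss, 0)
  expect_equal(ward_cluster(X, k = 1)$wcss,
               sum(sweep(X, 2, colMeans(X))^2))
  expect_error(ward_cluster(X, k = 0), "between")
  expect_error(ward_cluster(X, k = 9), "between")
})

test_that("Ward recovers well-separated archetype groups", {
  arch <- load_archetypes()
  panel <- simulate_sensory(arch, study_design(seed = 77), 10,
                            noise_sd = 0.3)
  prof <- aggregate_qda(panel)
  cl <- ward_cluster(prof, k = 3)
  expect_equal(mclust::adjustedRandIndex(cl$assignments,
                                         attr(prof, "groups")), 1)
  # labels are ordered by first sample appearance
  expect_identical(unname(cl$assignments[1]), 1L)
})

test_that("Ward matches the exhaustive minimum-variance optimum on
           separated data and never beats it", {
  set.seed(12)
  agree <- 0
  for (i in 1:100) {
    k <- sample(2:3, 1)
    sizes <- if (k == 2) c(3, 4) else c(2, 2, 3)
    centers <- matrix(rnorm(k * 2, sd = 6), k)
    X <- centers[rep(seq_len(k), sizes), ] +
      matrix(rnorm(sum(sizes) * 2), sum(sizes))
    rownames(X) <- paste0("s", seq_len(nrow(X)))
    w <- ward_cluster(X, k)$wcss
    b <- brute_min_wcss(X, k)
    expect_gte(w, b - 1e-9)  # greedy can never undercut the optimum
    if (abs(w - b) < 1e-9) agree <- agree + 1
  }
  expect_gte(agree, 95)
})

test_that("the WCSS curve is non-increasing with the right endpoints", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:12, 1)
    X <- matrix(rnorm(n * 3), n, dimnames = list(paste0("s", 1:n), NULL))
    cu <- wcss_curve(X, k_max = n)
    expect_true(all(diff(cu) <= 1e-9))
    expect_equal(unname(cu[as.character(n)]), 0)
    expect_equal(unname(cu["1"]), sum(sweep(X, 2, colMeans(X))^2))
  }
})

test_that("the elbow is the maximum second difference, ties to smallest k", {
  expect_identical(elbow_k(c(`1` = 100, `2` = 60, `3` = 15, `4` = 12,
                             `5` = 10)), 3L)
  expect_identical(elbow_k(c(`1` = 100, `2` = 30, `3` = 10, `4` = 8,
                             `5` = 7)), 2L)
  linear <- stats::setNames(seq(100, 20, by = -20), 1:5)
  expect_identical(elbow_k(linear), 2L)
  expect_error(elbow_k(c(`1` = 2, `2` = 1)), "at least 3")
  expect_error(elbow_k(c(`1` = 3, `3` = 2, `4` = 1)), "consecutive")
})

test_that("synthetic aroma profiles elbow at three clusters and the curve
           drops sharply there", {
  arch <- load_archetypes()
  panel <- simulate_sensory(arch, study_design(seed = 42), 10,
                            noise_sd = 0.5)
  cu <- wcss_curve(aggregate_qda(panel), 6)
  expect_identical(elbow_k(cu), 3L)
  expect_gt(cu[["2"]] - cu[["3"]], 5 * (cu[["3"]] - cu[["4"]]))
})

test_that("cluster profiles are per-cluster attribute means", {
  X <- matrix(c(1, 2, 3, 5, 5, 8), 3, 2,
              dimnames = list(c("a", "b", "c"), c("x", "y")))
  grand <- cluster_profiles(X, c(a = 1, b = 1, c = 1))
  expect_equal(unname(grand[1, ]), colMeans(X), ignore_attr = TRUE)
  two <- cluster_profiles(X, c(a = 1, b = 1, c = 2))
  expect_equal(unname(two["1", "x"]), 1.5)
  expect_equal(unname(two["2", "y"]), 8)
  expect_error(cluster_profiles(X, c(a = 1, b = 1)), "cover")
  expect_error(cluster_profiles(X, c(a = 1, b = NA, c = 2)), "empty")

  # archetype recovery: cluster means sit close to the generating means
  arch <- load_archetypes()
  d <- study_design(seed = 55)
  prof <- aggregate_qda(simulate_sensory(arch, d, 10, noise_sd = 0.5))
  truth <- attr(prof, "groups")
  means <- cluster_profiles(prof, truth)
  for (g in c("A", "B", "C")) {
    n_eff <- sum(truth == g) * 10
    bound <- 4 * 0.5 / sqrt(n_eff) + 0.25  # CLT + half-point snapping bias
    expect_true(all(abs(means[g, ] - arch$means[g, ]) < bound))
  }
})
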