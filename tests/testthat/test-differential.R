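test_that("one-way ANOVA handles identical and degenerate groups", {
  x <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  res <- anova_oneway(x, g)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  deg <- anova_oneway(c(1, 1, 2, 2), rep(c("a", "b"), each = 2))
  expect_true(is.infinite(deg$F))
  expect_equal(deg$p, 0)
  expect_true(deg$degenerate)
  same <- anova_oneway(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(same$p, 1)
  expect_error(anova_oneway(1:3, c("a", "a", "a")), "2 groups")
})

test_that("two-group ANOVA F equals the squared pooled t (property)", {
  for (seed in 1:50) {
    set.seed(seed)
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), mean = 0.5)
    a <- anova_oneway(c(x, y), rep(c("x", "y"), c(length(x), length(y))))
    t <- student_ttest(x, y)
    expect_equal(a$F, t$t^2, tolerance = 1e-10)
    expect_equal(a$p, t$p, tolerance = 1e-10)
  }
})

test_that("summary-statistic ANOVA is exactly the raw-data ANOVA", {
  for (seed in 1:100) {
    set.seed(seed)
    g <- sample(2:4, 1)
    ns <- sample(2:6, g, replace = TRUE)
    vals <- rnorm(sum(ns), mean = rep(rnorm(g, sd = 2), ns))
    grp <- rep(letters[1:g], ns)
    raw <- anova_oneway(vals, grp)
    summ <- anova_from_summary(tapply(vals, grp, mean),
                               tapply(vals, grp, sd),
                               as.integer(table(grp)))
    expect_equal(summ$F, raw$F, tolerance = 1e-10)
    expect_equal(summ$p, raw$p, tolerance = 1e-10)
  }
})

test_that("summary ANOVA reproduces hand computations from group tables", {
  # 6-Undecanone group summaries, n = 3/4/4
  r1 <- anova_from_summary(c(0.51, 0.09, 0.29), c(0.10, 0.18, 0.37),
                           c(3, 4, 4))
  expect_equal(r1$F, 2.2986, tolerance = 1e-3)
  # (E)-2-Octenal with the ND group entering as exact zeros
  r2 <- anova_from_summary(c(0.56, 0.40, 0), c(0.07, 0.09, 0), c(3, 4, 4))
  expect_equal(r2$F, 70.70, tolerance = 1e-2)
  expect_equal(anova_from_summary(c(1, 1), c(0.3, 0.4), c(3, 3))$F, 0)
  expect_error(anova_from_summary(c(1, 2), c(0.1, 0.1), c(1, 1)), ">= 2")
})

test_that("pooled t-test matches the textbook formula and its limits", {
  x <- c(1, 2, 3); y <- c(2, 4, 6, 8)
  res <- student_ttest(x, y)
  sp2 <- (sum((x - 2)^2) + sum((y - 5)^2)) / 5
  t_hand <- (2 - 5) / sqrt(sp2 * (1 / 3 + 1 / 4))
  expect_equal(res$t, t_hand)
  expect_equal(res$p, 2 * pt(abs(t_hand), 5, lower.tail = FALSE))

  expect_equal(student_ttest(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_lt(student_ttest(c(0, 0, 0), c(1, 1, 1.0001))$p, 1e-6)
  expect_equal(student_ttest(c(2, 2), c(2, 2))$p, 1)
  expect_error(student_ttest(1, c(1, 2)), ">= 2")
})

test_that("log2 fold changes use the pseudo-content for non-detects", {
  expect_equal(log2_fold_change(3, 3, 0.01), 0)
  expect_equal(log2_fold_change(2, 1, 0), 1)
  expect_equal(log2_fold_change(0.22, 0, 0.01), log2(0.23 / 0.01))
  expect_equal(log2_fold_change(0, 0, 0.01), 0)
  expect_error(log2_fold_change(-1, 1, 0.1), ">= 0")
  expect_equal(default_epsilon(c(0, 0.4, 2)), 0.2)
  expect_error(default_epsilon(c(0, 0)), "nonzero")
})

test_that("the differential verdict needs both p and VIP strictly past
           their thresholds", {
  p <- c(a = 0.01, b = 0.01, c = 0.2, d = 0.05, e = 0.04)
  vip <- c(a = 1.5, b = 0.8, c = 1.5, d = 1.5, e = 1.0)
  fc <- c(a = 2, b = 2, c = 2, d = -2, e = 1)
  out <- screen_differential(p, vip, fc)
  expect_identical(out$verdict,
                   c("up", "not significant", "not significant",
                     "not significant", "not significant"))
  down <- screen_differential(c(x = 0.01), c(x = 2), c(x = -1.5))
  expect_identical(down$verdict, "down")
  empty <- screen_differential(numeric(0), numeric(0), numeric(0))
  expect_identical(nrow(empty), 0L)
})

test_that("Venn region counts match direct set algebra and sum to the
           union", {
  two <- venn_counts(list(X = c("a", "b"), Y = c("b", "c")))
  expect_identical(two$count[two$region == "X"], 1L)
  expect_identical(two$count[two$region == "Y"], 1L)
  expect_identical(two$count[two$region == "X&Y"], 1L)

  same <- venn_counts(list(X = c("a", "b"), Y = c("a", "b")))
  expect_identical(same$count[same$region == "X&Y"], 2L)
  expect_identical(sum(same$count), 2L)

  set.seed(42)
  for (i in 1:20) {
    sets <- list(P = sample(letters, 8), Q = sample(letters, 10),
                 R = sample(letters, 5))
    got <- venn_counts(sets)
    want <- brute_venn(sets)
    for (r in got$region) {
      expect_identical(got$count[got$region == r], as.integer(want[[r]]))
    }
    expect_identical(sum(got$count), length(unique(unlist(sets))))
  }
  expect_error(venn_counts(list(A = "a")), "2 sets")
})

test_that("PCA Hotelling ellipse flags gross outliers only", {
  lib <- load_gcms_table()
  inall <- 0
  for (i in 1:100) {
    conc <- simulate_concentrations(lib, study_design(seed = 3000 + i))
    keep <- apply(conc$values, 2, sd) > 0
    ph <- pca_hotelling(conc$values[, keep])
    if (all(ph$inside)) inall <- inall + 1
  }
  expect_gte(inall, 90)

  set.seed(9)
  X <- matrix(rnorm(20 * 5), 20)
  X[1, ] <- X[1, ] + 10
  ph <- pca_hotelling(X, autoscale = FALSE)
  expect_false(ph$inside[1])
  expect_equal(unname(colMeans(ph$scores)), rep(0, ncol(ph$scores)),
               tolerance = 1e-10)
  expect_error(pca_hotelling(matrix(rnorm(6), 3, 2)), "n samples")
})

test_that("complete-linkage ordering keeps obvious blocks contiguous", {
  base <- matrix(rnorm(6 * 4, sd = 0.2), 6, 4)
  base[1:3, ] <- base[1:3, ] + 3
  base[4:6, ] <- base[4:6, ] - 3
  rownames(base) <- paste0("r", 1:6)
  hm <- hclust_heatmap(base, row_scale = "none")
  pos <- sort(match(1:3, hm$row_order))
  expect_equal(pos, pos[1] + 0:2)  # the high block stays contiguous

  # identical rows merge at height zero and sit adjacent
  dup <- rbind(a = c(1, 2, 3), b = c(9, 9, 9), a2 = c(1, 2, 3))
  hm2 <- hclust_heatmap(dup, row_scale = "none")
  pos <- match(c(1, 3), hm2$row_order)
  expect_equal(abs(diff(pos)), 1)
  expect_equal(min(hm2$row_tree$height), 0)

  # permutation invariance of the merge heights
  perm <- base[sample(6), ]
  expect_equal(sort(hclust_heatmap(perm, "none")$row_tree$height),
               sort(hm$row_tree$height))

  # zero-variance rows are flagged and scaled to zeros
  flat <- rbind(x = c(1, 1, 1), y = c(1, 2, 3), z = c(4, 0, 2))
  hm3 <- hclust_heatmap(flat, row_scale = "zscore")
  expect_identical(hm3$flat_rows, "x")
  expect_true(all(hm3$scaled["x", ] == 0))
})

test_that("the ANOVA screen ranks the strongly separated compounds high
           on synthetic per-sample data", {
  lib <- load_gcms_table()
  hits <- 0
  for (i in 1:100) {
    conc <- simulate_concentrations(lib, study_design(seed = 2000 + i))
    sc <- anova_screen(conc)
    med <- stats::median(sc$p)
    if (sc$p[sc$compound == "(E)-2-Octenal"] < med &&
        sc$p[sc$compound == "2-Acetyl-1h-pyrrole"] < med) hits <- hits + 1
  }
  expect_gte(hits, 95)
})
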