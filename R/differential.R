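# Differential screening of volatiles across and between aroma types:
# one-way ANOVA, pairwise pooled-variance Student t tests gated on
# OPLS-DA VIP, fold changes, Venn region counts, PCA with Hotelling T2
# ellipse, and complete-linkage heatmap ordering.

#' One-way fixed-effects ANOVA
#'
#' Classical pooled-variance one-way ANOVA; the p-value comes from the F
#' distribution with (g - 1, n - g) degrees of freedom. Degenerate inputs
#' (zero within-group variance everywhere) collapse to the limits F = 0,
#' p = 1 when the group means agree and F = Inf, p = 0 (flagged) when
#' they do not.
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation (>= 2 groups, at least one
#'   with >= 2 observations).
#' @return List with \code{F}, \code{p}, \code{df} and a
#'   \code{degenerate} flag.
#' @export
anova_oneway <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  ns <- table(groups)
  if (!any(ns >= 2)) stop("need at least one group with >= 2 observations")
  g <- nlevels(droplevels(groups))
  n <- length(values)
  df <- c(g - 1, n - g)
  ssw <- sum(tapply(values, groups, function(x) sum((x - mean(x))^2)))
  if (ssw == 0) {
    means <- tapply(values, groups, mean)
    if (max(means) - min(means) == 0) {
      return(list(F = 0, p = 1, df = df, degenerate = TRUE))
    }
    return(list(F = Inf, p = 0, df = df, degenerate = TRUE))
  }
  fit <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value), df = df,
       degenerate = FALSE)
}

#' One-way ANOVA from group summary statistics
#'
#' Exact reconstruction of the pooled one-way ANOVA from per-group means,
#' SDs and sizes: feeding it the summaries of any raw matrix reproduces
#' \code{\link{anova_oneway}} identically. Lets published mean +/- SD
#' tables be analyzed when the raw per-sample data are unavailable.
#'
#' @param means,sds,ns aligned per-group summaries (SDs are sample SDs,
#'   denominator n - 1).
#' @return As \code{\link{anova_oneway}}.
#' @export
anova_from_summary <- function(means, sds, ns) {
  if (length(unique(c(length(means), length(sds), length(ns)))) != 1) {
    stop("means, sds, ns must have equal length")
  }
  if (length(means) < 2) stop("need at least 2 groups")
  if (any(ns < 1)) stop("all group sizes must be >= 1")
  if (!any(ns >= 2)) stop("need at least one group with >= 2 observations")
  if (any(sds < 0)) stop("sds must be >= 0")
  g <- length(means)
  n <- sum(ns)
  df <- c(g - 1, n - g)
  grand <- sum(ns * means) / n
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, p = 1, df = df, degenerate = TRUE))
    return(list(F = Inf, p = 0, df = df, degenerate = TRUE))
  }
  F <- (ssb / df[1]) / (ssw / df[2])
  list(F = F, p = stats::pf(F, df[1], df[2], lower.tail = FALSE), df = df,
       degenerate = FALSE)
}

#' Per-compound ANOVA screen over a concentration matrix
#'
#' @param conc a \code{concentration_matrix}.
#' @param alpha significance threshold (strict).
#' @return Data frame: compound, F, p, significant.
#' @export
anova_screen <- function(conc, alpha = 0.05) {
  stopifnot(inherits(conc, "concentration_matrix"))
  res <- lapply(colnames(conc$values), function(cmp) {
    a <- anova_oneway(conc$values[, cmp], conc$groups)
    data.frame(compound = cmp, F = a$F, p = a$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p < alpha
  out
}

#' Pooled-variance Student t test (two-sided)
#'
#' @param x,y numeric group samples, each of size >= 2.
#' @return List with \code{t}, \code{p}, \code{df}, \code{degenerate}.
#' @export
student_ttest <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  pooled_ss <- sum((x - mean(x))^2) + sum((y - mean(y))^2)
  if (pooled_ss == 0) {
    df <- length(x) + length(y) - 2
    if (mean(x) == mean(y)) {
      return(list(t = 0, p = 1, df = df, degenerate = TRUE))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0, df = df,
                degenerate = TRUE))
  }
  fit <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(fit$statistic), p = unname(fit$p.value),
       df = unname(fit$parameter), degenerate = FALSE)
}

#' Log2 fold change with a pseudo-content for non-detects
#'
#' \eqn{\log_2((m_1 + \epsilon)/(m_2 + \epsilon))}. The default epsilon,
#' half the smallest nonzero content in the matrix under study, keeps
#' fold changes over not-detected (zero) groups finite. Two zero means
#' give 0.
#'
#' @param mean_num,mean_den non-negative group means (vectorized).
#' @param epsilon pseudo-content.
#' @return Numeric log2 fold change(s).
#' @export
log2_fold_change <- function(mean_num, mean_den, epsilon) {
  if (any(mean_num < 0) || any(mean_den < 0)) stop("means must be >= 0")
  if (epsilon < 0) stop("epsilon must be >= 0")
  out <- ifelse(mean_num == 0 & mean_den == 0, 0,
                log2((mean_num + epsilon) / (mean_den + epsilon)))
  out
}

#' Default fold-change pseudo-content
#'
#' Half the smallest nonzero value of the matrix.
#'
#' @param values numeric matrix or vector of contents.
#' @return Scalar epsilon.
#' @export
default_epsilon <- function(values) {
  nz <- values[values > 0]
  if (length(nz) == 0) stop("no nonzero contents")
  min(nz) / 2
}

#' Differential-compound verdicts
#'
#' A compound is differential iff p < alpha and VIP > vip_min (both
#' strict); the direction comes from the sign of the log2 fold change.
#'
#' @param p_values,vips,fold_changes aligned named numeric vectors.
#' @param alpha p-value threshold (strict).
#' @param vip_min VIP threshold (strict).
#' @return Data frame: compound, p, vip, log2fc, verdict (up / down /
#'   not significant).
#' @export
screen_differential <- function(p_values, vips, fold_changes,
                                alpha = 0.05, vip_min = 1) {
  if (length(p_values) == 0) {
    return(data.frame(compound = character(0), p = numeric(0),
                      vip = numeric(0), log2fc = numeric(0),
                      verdict = character(0), stringsAsFactors = FALSE))
  }
  cmp <- names(p_values)
  if (is.null(cmp)) cmp <- as.character(seq_along(p_values))
  vips <- vips[cmp]
  fold_changes <- fold_changes[cmp]
  hit <- p_values < alpha & vips > vip_min
  verdict <- ifelse(!hit, "not significant",
                    ifelse(fold_changes >= 0, "up", "down"))
  data.frame(compound = cmp, p = unname(p_values), vip = unname(vips),
             log2fc = unname(fold_changes), verdict = verdict,
             stringsAsFactors = FALSE)
}

#' Venn region counts
#'
#' Counts every membership region of a Venn diagram over named sets:
#' each element of the union is assigned the pattern of sets containing
#' it, and all 2^n - 1 patterns are reported (zeros included).
#'
#' @param sets named list (>= 2) of character vectors.
#' @return Data frame: region (set names joined by "&"), count.
#' @export
venn_counts <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets")
  if (is.null(names(sets))) stop("sets must be named")
  universe <- unique(unlist(sets))
  patterns <- vapply(universe, function(e) {
    inset <- vapply(sets, function(s) e %in% s, logical(1))
    paste(names(sets)[inset], collapse = "&")
  }, character(1))
  n <- length(sets)
  all_regions <- unlist(lapply(seq_len(n), function(k) {
    utils::combn(names(sets), k, paste, collapse = "&")
  }))
  counts <- vapply(all_regions, function(r) sum(patterns == r), integer(1))
  data.frame(region = all_regions, count = unname(counts),
             stringsAsFactors = FALSE)
}

#' PCA scores with Hotelling's T2 confidence ellipse
#'
#' PCA on autoscaled data; the per-sample T2 statistic over the first
#' \code{n_components} scores is compared with the limit
#' \eqn{a(n-1)/(n-a) F_{1-\alpha}(a, n-a)} (a = number of components).
#'
#' @param X samples x variables matrix.
#' @param n_components number of score dimensions for the ellipse.
#' @param confidence ellipse coverage.
#' @param autoscale scale variables to unit variance (constant variables
#'   are dropped with a message).
#' @return List with \code{scores}, \code{t2}, \code{t2_limit},
#'   \code{inside} flags and explained variance.
#' @export
pca_hotelling <- function(X, n_components = 2, confidence = 0.95,
                          autoscale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= n_components + 1) stop("need n samples > n_components + 1")
  if (autoscale) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      message("dropping ", sum(sds == 0), " constant variable(s) for PCA")
      X <- X[, sds > 0, drop = FALSE]
    }
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = autoscale)
  if (ncol(pc$x) < n_components) stop("matrix rank below n_components")
  a <- n_components
  scores <- pc$x[, seq_len(a), drop = FALSE]
  lam <- pc$sdev[seq_len(a)]^2
  t2 <- rowSums(sweep(scores^2, 2, lam, "/"))
  lim <- a * (n - 1) / (n - a) *
    stats::qf(confidence, a, n - a)
  list(scores = pc$x, t2 = t2, t2_limit = lim, inside = t2 <= lim,
       explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Complete-linkage heatmap ordering
#'
#' Orders rows and columns by complete-linkage agglomeration on Euclidean
#' distances, optionally after z-scoring the rows (zero-variance rows are
#' flagged and scaled to zeros).
#'
#' @param mat numeric matrix (>= 2 rows and columns).
#' @param row_scale \code{"zscore"} or \code{"none"}.
#' @return List with \code{row_order}, \code{col_order}, \code{scaled}
#'   matrix, the two \code{hclust} trees and \code{flat_rows} (names of
#'   zero-variance rows).
#' @export
hclust_heatmap <- function(mat, row_scale = c("zscore", "none")) {
  row_scale <- match.arg(row_scale)
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2) stop("need >= 2 rows and columns")
  flat <- character(0)
  scaled <- mat
  if (row_scale == "zscore") {
    sds <- apply(mat, 1, stats::sd)
    flat <- rownames(mat)[sds == 0]
    scaled <- t(apply(mat, 1, function(r) {
      s <- stats::sd(r)
      if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
    }))
    dimnames(scaled) <- dimnames(mat)
  }
  rtree <- stats::hclust(stats::dist(scaled), method = "complete")
  ctree <- stats::hclust(stats::dist(t(scaled)), method = "complete")
  list(row_order = rtree$order, col_order = ctree$order,
       scaled = scaled, row_tree = rtree, col_tree = ctree,
       flat_rows = flat)
}
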