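# QDA sensory aggregation and aroma-type clustering: Ward linkage on
# Euclidean distances between sample aroma profiles, with the cluster
# count chosen at the WCSS elbow.

#' Average QDA panel scores per sample and attribute
#'
#' Validates that every score sits on the 0-9 half-point grid, then takes
#' the arithmetic mean over panelists.
#'
#' @param panel a long data frame with columns panelist, sample,
#'   attribute, score (e.g. from \code{\link{simulate_sensory}}).
#' @return Numeric matrix, samples x attributes, of mean scores. Sample
#'   group labels (if present in the panel) are attached as attribute
#'   \code{"groups"}.
#' @export
aggregate_qda <- function(panel) {
  need <- c("panelist", "sample", "attribute", "score")
  if (!all(need %in% names(panel))) {
    stop("panel must have columns ", paste(need, collapse = ", "))
  }
  s <- panel$score
  off <- is.na(s) | s < 0 | s > 9 | abs(s * 2 - round(s * 2)) > 1e-8
  if (any(off)) {
    stop(sprintf("%d score(s) off the 0-9 half-point grid (first: %s)",
                 sum(off), s[which(off)[1]]))
  }
  samples <- unique(panel$sample)
  attrs <- unique(panel$attribute)
  m <- tapply(panel$score, list(factor(panel$sample, samples),
                                factor(panel$attribute, attrs)),
              mean)
  m <- matrix(as.numeric(m), nrow = length(samples),
              dimnames = list(samples, attrs))
  if ("group" %in% names(panel)) {
    attr(m, "groups") <- stats::setNames(
      panel$group[match(samples, panel$sample)], samples)
  }
  m
}

# Within-cluster sum of squares of a labelled partition: total squared
# Euclidean deviation of rows from their cluster centroid.
wcss_of <- function(profiles, assignments) {
  assignments <- assignments[rownames(profiles)]
  sum(vapply(unique(assignments), function(cl) {
    x <- profiles[assignments == cl, , drop = FALSE]
    ctr <- colMeans(x)
    sum(sweep(x, 2, ctr)^2)
  }, numeric(1)))
}

# Relabel cluster ids 1..k in order of first appearance over the rows.
relabel_by_appearance <- function(assignments) {
  first <- unique(assignments)
  stats::setNames(match(assignments, first), names(assignments))
}

#' Ward clustering of sample aroma profiles
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances (the \code{ward.D2} linkage of
#' \code{\link[stats]{hclust}}), cut at \code{k} clusters. Attributes all
#' share the 0-9 QDA scale, so profiles are not standardized by default.
#'
#' @param profiles samples x attributes numeric matrix.
#' @param k number of clusters, between 1 and the number of samples.
#' @param standardize z-score the attribute columns first.
#' @return A \code{cluster_result}: list with \code{k},
#'   \code{assignments} (named integer vector, labels ordered by first
#'   sample appearance), \code{wcss}, and the \code{hclust} \code{tree}.
#' @export
ward_cluster <- function(profiles, k, standardize = FALSE) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (k < 1 || k > n) stop("k must be between 1 and the number of samples")
  if (ncol(profiles) < 1) stop("need at least one attribute")
  if (standardize) profiles <- scale(profiles)
  tree <- stats::hclust(stats::dist(profiles), method = "ward.D2")
  assignments <- relabel_by_appearance(stats::cutree(tree, k = k))
  structure(list(k = k, assignments = assignments,
                 wcss = wcss_of(profiles, assignments), tree = tree),
            class = "cluster_result")
}

#' WCSS curve over Ward tree cuts
#'
#' Within-cluster sum of squares for cuts k = 1..k_max of the Ward tree.
#' Because the cuts are nested, the curve is non-increasing in k, with
#' WCSS(1) the total sum of squares and WCSS(n) = 0.
#'
#' @param profiles samples x attributes numeric matrix.
#' @param k_max largest cut to evaluate (<= number of samples).
#' @param standardize z-score the attribute columns first.
#' @return Named numeric vector, names "1".."k_max".
#' @export
wcss_curve <- function(profiles, k_max, standardize = FALSE) {
  profiles <- as.matrix(profiles)
  if (k_max > nrow(profiles)) stop("k_max exceeds number of samples")
  if (standardize) profiles <- scale(profiles)
  tree <- stats::hclust(stats::dist(profiles), method = "ward.D2")
  vapply(seq_len(k_max), function(k) {
    wcss_of(profiles, stats::cutree(tree, k = k))
  }, numeric(1)) |> stats::setNames(as.character(seq_len(k_max)))
}

#' Elbow of a WCSS curve
#'
#' The elbow is the interior k maximizing the second difference
#' \eqn{(WCSS_{k-1} - WCSS_k) - (WCSS_k - WCSS_{k+1})}: the point where a
#' rapid decrease turns flat. Ties go to the smallest k.
#'
#' @param curve named numeric vector over consecutive k (>= 3 points).
#' @return Integer k*.
#' @export
elbow_k <- function(curve) {
  if (length(curve) < 3) stop("need at least 3 consecutive k values")
  ks <- as.integer(names(curve))
  if (is.null(names(curve)) || any(is.na(ks))) ks <- seq_along(curve)
  if (any(diff(ks) != 1)) stop("curve must be on consecutive k")
  w <- as.numeric(curve)
  second <- (w[seq_len(length(w) - 2)] - w[seq(2, length(w) - 1)]) -
    (w[seq(2, length(w) - 1)] - w[seq(3, length(w))])
  ks[which.max(second) + 1]
}

#' Per-cluster mean aroma profiles (spider-plot data)
#'
#' @param profiles samples x attributes matrix.
#' @param assignments named cluster labels covering every sample; empty or
#'   missing labels are an error.
#' @return clusters x attributes matrix of mean scores.
#' @export
cluster_profiles <- function(profiles, assignments) {
  profiles <- as.matrix(profiles)
  if (!all(rownames(profiles) %in% names(assignments))) {
    stop("assignments must cover all samples")
  }
  a <- assignments[rownames(profiles)]
  if (any(is.na(a)) || any(!nzchar(as.character(a)))) {
    stop("empty cluster label in assignments")
  }
  labels <- sort(unique(a))
  out <- t(vapply(labels, function(cl) {
    colMeans(profiles[a == cl, , drop = FALSE])
  }, numeric(ncol(profiles))))
  rownames(out) <- as.character(labels)
  out
}
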