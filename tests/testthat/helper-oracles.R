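# Independent oracles used to cross-check package implementations.
# These deliberately share no code with the package.

# Classical NIPALS single-component PLS on autoscaled X / centered y.
nipals_pls1 <- function(X, y, tol = 1e-12, maxit = 500) {
  Xs <- scale(as.matrix(X))
  yc <- y - mean(y)
  u <- yc
  w_old <- rep(0, ncol(Xs))
  for (it in seq_len(maxit)) {
    w <- unname(drop(crossprod(Xs, u)))
    w <- w / sqrt(sum(w^2))
    t <- drop(Xs %*% w)
    q <- sum(yc * t) / sum(t^2)
    u <- yc * q / q^2
    if (sum((w - w_old)^2) < tol) break
    w_old <- w
  }
  list(w = w, scores = t)
}

# Exhaustive minimum-WCSS partition of the rows of X into exactly k
# non-empty clusters (feasible for small n only).
brute_min_wcss <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  best <- Inf
  rec <- function(i, labs) {
    if (i > n) {
      if (length(unique(labs)) == k) {
        w <- sum(vapply(unique(labs), function(cl) {
          x <- X[labs == cl, , drop = FALSE]
          sum(sweep(x, 2, colMeans(x))^2)
        }, numeric(1)))
        if (w < best) best <<- w
      }
      return(invisible())
    }
    for (l in seq_len(min(k, max(labs, 0L) + 1L))) rec(i + 1L, c(labs, l))
  }
  rec(1L, integer(0))
  best
}

# Direct set-algebra region counts, independent of venn_counts().
brute_venn <- function(sets) {
  universe <- unique(unlist(sets))
  out <- list()
  n <- length(sets)
  for (k in seq_len(n)) {
    for (idx in utils::combn(n, k, simplify = FALSE)) {
      members <- Filter(function(e) {
        all(vapply(idx, function(j) e %in% sets[[j]], logical(1))) &&
          !any(vapply(setdiff(seq_len(n), idx), function(j) {
            e %in% sets[[j]]
          }, logical(1)))
      }, universe)
      out[[paste(names(sets)[idx], collapse = "&")]] <- length(members)
    }
  }
  out
}

# A tiny three-compound GC-MS library written to a temp file and loaded
# through the standard reader, for tests that need a small library.
tiny_library <- function() {
  path <- tempfile(fileext = ".tsv")
  lines <- c(
    "no\tname\tri\tformula\tcas\tcategory\todor_description\todor_threshold_ug_l\tcontent_A\tcontent_B\tcontent_C",
    "1\tAlpha\t1000\tC1\t1-1-1\tKetones\tSweet, Fruity\t2.0\t4.00 ± 1.00\t2.00 ± 0.50\tND",
    "2\tBeta\t1100\tC2\t2-2-2\tAlcohols\t——\tn.f.\t1.00 ± 0.10\t1.00 ± 0.10\t1.00 ± 0.10",
    "3\tGamma\t1200\tC3\t3-3-3\tAldehydes\tGreen\t0.5\t1.00 ± 0.20\tND\t3.00 ± 0.30"
  )
  writeLines(lines, path, useBytes = FALSE)
  load_gcms_table(path)
}
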