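# Orthogonal PLS discriminant analysis (single response), following the
# orthogonal signal correction scheme: class-orthogonal variation is
# stripped from X component by component, then one predictive PLS
# component is fit on the filtered matrix. With zero orthogonal
# components the model reduces exactly to 1-component PLS-DA.

#' Fit an OPLS-DA model
#'
#' The binary class vector is centered; X is centered and (by default)
#' autoscaled to unit variance. The predictive weight is
#' \eqn{w \propto X'y}. For each orthogonal component, the loading of the
#' current predictive direction is deflected against \eqn{w}
#' (\eqn{w_o \propto p - (w'p) w}), normalized, and the corresponding
#' orthogonal score/loading pair is deflated from X. The final predictive
#' component (scores \eqn{t}, loadings \eqn{p}, y-loading \eqn{q}) is
#' computed on the filtered matrix. Orthogonal scores are uncorrelated
#' with the class by construction.
#'
#' @param X samples x variables numeric matrix.
#' @param y class membership: a factor/character with two levels or a
#'   numeric two-valued vector. Encoding does not affect VIP ranking.
#' @param n_ortho number of orthogonal components (>= 0; default 1).
#' @param scaling \code{"autoscale"} (unit variance, the metabolomics
#'   default) or \code{"center"}.
#' @return An \code{oplsda} object: list with predictive \code{weights},
#'   \code{scores}, \code{loadings}, y-loading \code{q}, an \code{ortho}
#'   list (weight/score/loading matrices), \code{n_ortho},
#'   \code{scaling}, and the centering/scaling vectors.
#' @export
fit_oplsda <- function(X, y, n_ortho = 1,
                       scaling = c("autoscale", "center")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  if (n_ortho < 0) stop("n_ortho must be >= 0")
  yv <- if (is.numeric(y)) y else as.numeric(factor(y))
  if (length(unique(yv)) != 2) stop("y must contain exactly two classes")
  if (length(yv) != nrow(X)) stop("length(y) must match nrow(X)")

  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (scaling == "autoscale" && any(sds == 0)) {
    stop("constant variable(s) under autoscaling: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  sc <- if (scaling == "autoscale") sds else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2, mu), 2, sc, "/")
  yc <- yv - mean(yv)

  w <- drop(crossprod(Xs, yc))
  w <- w / sqrt(sum(w^2))

  Xf <- Xs
  W_o <- T_o <- P_o <- NULL
  if (n_ortho > 0) {
    W_o <- matrix(0, ncol(X), n_ortho)
    T_o <- matrix(0, nrow(X), n_ortho)
    P_o <- matrix(0, ncol(X), n_ortho)
    for (a in seq_len(n_ortho)) {
      t_p <- drop(Xf %*% w)
      p <- drop(crossprod(Xf, t_p)) / sum(t_p^2)
      w_o <- p - drop(crossprod(w, p)) * w
      nrm <- sqrt(sum(w_o^2))
      if (nrm < 1e-12) break  # no orthogonal variation left
      w_o <- w_o / nrm
      t_o <- drop(Xf %*% w_o)
      p_o <- drop(crossprod(Xf, t_o)) / sum(t_o^2)
      Xf <- Xf - tcrossprod(t_o, p_o)
      W_o[, a] <- w_o; T_o[, a] <- t_o; P_o[, a] <- p_o
    }
  }

  # predictive component on the filtered matrix
  w_p <- drop(crossprod(Xf, yc))
  w_p <- w_p / sqrt(sum(w_p^2))
  t_p <- drop(Xf %*% w_p)
  p_p <- drop(crossprod(Xf, t_p)) / sum(t_p^2)
  q <- sum(yc * t_p) / sum(t_p^2)

  structure(list(weights = stats::setNames(w_p, colnames(X)),
                 scores = t_p, loadings = p_p, q = q,
                 ortho = list(weights = W_o, scores = T_o, loadings = P_o),
                 n_ortho = n_ortho, scaling = scaling,
                 center = mu, scale = sc, y = yc),
            class = "oplsda")
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf("OPLS-DA: 1 predictive + %d orthogonal component(s), %s\n",
              x$n_ortho, x$scaling))
  cat(sprintf("score-class correlation: %.4f\n",
              stats::cor(x$scores, x$y)))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' VIP over the predictive component(s) only (the VIP_pred convention):
#' \eqn{VIP_j = \sqrt{p \sum_a SSY_a w_{aj}^2 / \sum_a SSY_a}} with p the
#' number of variables. For the single predictive component this reduces
#' to \eqn{\sqrt{p}\,|w_j|}, so mean(VIP^2) = 1 identically and VIP > 1
#' flags variables contributing more than an average share to the class
#' separation.
#'
#' @param model a fitted \code{\link{fit_oplsda}} model.
#' @return Named numeric VIP vector.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "oplsda"))
  p <- length(model$weights)
  sqrt(p * model$weights^2)
}
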