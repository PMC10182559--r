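#' Log transform and auto-scale a sample-by-feature matrix
#'
#' Metabolomics-style normalization: `log10(x + pseudo)` with the
#' pseudo-count equal to half the smallest nonzero matrix value, then
#' per-feature centering to mean 0 and scaling to unit variance.
#' Features with zero variance after the log are dropped with a warning.
#' Re-applying to an already scaled matrix is rejected.
#'
#' @param X Non-negative numeric matrix, samples in rows.
#' @return Scaled matrix with attribute `autoscaled = TRUE` (dropped
#'   features, if any, in `attr(, "dropped")`).
#' @export
log_autoscale <- function(X) {
  stopifnot(is.matrix(X))
  if (isTRUE(attr(X, "autoscaled")))
    stop("matrix is already log-autoscaled")
  if (any(X < 0)) stop("negative values; expected raw intensities")
  nz <- X[X > 0]
  pc <- if (length(nz)) min(nz) / 2 else 1
  L <- log10(X + pc)
  v <- apply(L, 2, stats::var)
  dropped <- colnames(L)[v == 0]
  if (length(dropped)) {
    warning("dropping zero-variance feature(s): ",
            paste(dropped, collapse = ", "))
    L <- L[, v > 0, drop = FALSE]
  }
  out <- scale(L)
  attributes(out)$`scaled:center` <- NULL
  attributes(out)$`scaled:scale` <- NULL
  attr(out, "autoscaled") <- TRUE
  attr(out, "dropped") <- dropped
  out
}

#' PLS-DA with VIP scores
#'
#' Two-class partial least squares discriminant analysis by NIPALS PLS1
#' against a +/-1-coded response. Variable importance in projection (VIP)
#' follows the standard definition from the component weights and the
#' y-variance explained per component; the mean of squared VIPs equals 1
#' by construction. 95% score ellipses per class are derived from the 2-D
#' score covariance at the chi-squared (2 df) quantile.
#'
#' @param X Normalized matrix ([log_autoscale()]), samples in rows.
#' @param y Binary labels (2 levels; first level is coded -1).
#' @param n_components Number of latent components (default 2).
#' @param vip_threshold Selection threshold on VIP (default 1.5).
#' @return A `biomarker_plsda`: `scores`, `loadings`, `weights`, `vip`,
#'   `selected`, `explained_y`, `ellipses`, `levels`.
#' @export
plsda <- function(X, y, n_components = 2L, vip_threshold = 1.5) {
  stopifnot(is.matrix(X))
  y <- factor(y)
  if (nlevels(y) != 2L) stop("plsda requires exactly two classes")
  if (n_components >= min(dim(X))) stop("n_components too large for X")
  yy <- ifelse(y == levels(y)[1], -1, 1)
  yy <- yy - mean(yy)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  n <- nrow(Xc); p <- ncol(Xc); A <- n_components
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A); ssy <- numeric(A)
  Xa <- Xc; ya <- yy
  for (a in seq_len(A)) {
    w <- crossprod(Xa, ya)
    w <- w / sqrt(sum(w^2))
    t <- Xa %*% w
    tt <- sum(t^2)
    pl <- crossprod(Xa, t) / tt
    qa <- sum(ya * t) / tt
    Xa <- Xa - t %*% t(pl)
    ya <- ya - qa * t
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t
    q[a] <- qa; ssy[a] <- qa^2 * tt
  }
  vip <- sqrt(p * (W^2 %*% ssy) / sum(ssy))[, 1]
  names(vip) <- colnames(X)
  rownames(W) <- rownames(P) <- colnames(X)
  dimnames(Tm) <- list(rownames(X), paste0("comp", seq_len(A)))

  ellipses <- NULL
  if (A >= 2L) {
    r2 <- stats::qchisq(0.95, df = 2)
    ellipses <- lapply(levels(y), function(lv) {
      S <- Tm[y == lv, 1:2, drop = FALSE]
      if (nrow(S) < 3L) return(NULL)
      list(center = colMeans(S), cov = stats::cov(S), radius2 = r2)
    })
    names(ellipses) <- levels(y)
  }
  structure(list(scores = Tm, loadings = P, weights = W, vip = vip,
                 selected = names(vip)[vip > vip_threshold],
                 explained_y = ssy / sum(yy^2), q = q,
                 ellipses = ellipses, levels = levels(y)),
            class = "biomarker_plsda")
}

#' @export
print.biomarker_plsda <- function(x, ...) {
  cat(sprintf("<plsda> %d components, %d features, %d with VIP > 1.5\n",
              ncol(x$scores), length(x$vip), length(x$selected)))
  invisible(x)
}

#' Univariate ROC curve and AUC
#'
#' AUC equals the normalized Mann-Whitney U statistic (probability that a
#' random positive scores above a random negative, ties counted half);
#' the ROC is the step function over score thresholds with tie midpoints.
#'
#' @param values Numeric scores (higher = more positive-like).
#' @param y Binary labels; second factor level is the positive class.
#' @return List with `auc` and `roc` (`data.frame` of `fpr`, `tpr`).
#' @export
roc_univariate <- function(values, y) {
  y <- factor(y)
  if (nlevels(y) != 2L) stop("need exactly two classes")
  pos <- y == levels(y)[2]
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0L || n2 == 0L) stop("one class is empty")
  r <- rank(values)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  thr <- sort(unique(values), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(values[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(values[!pos] >= t), numeric(1))
  list(auc = auc,
       roc = data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)))
}

# L2-regularized linear (ridge) margin classifier on +/-1 labels.
ridge_weights <- function(X, yy, lambda = 1) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ctr <- attr(Xc, "scaled:center")
  w <- solve(crossprod(Xc) + lambda * diag(ncol(X)), crossprod(Xc, yy))
  list(w = w[, 1], center = ctr, b = mean(yy))
}

#' Cross-validated multivariate ROC
#'
#' Repeated Monte-Carlo cross-validation (default 50 repeats with a
#' stratified 1/3 holdout): on each training split an L2-regularized
#' linear margin classifier is fit on all features, features are ranked by
#' absolute weight, the classifier is refit on the `top_k` features, and
#' held-out samples are scored. AUC is summarised over repeats by its
#' mean and a percentile confidence interval.
#'
#' @param X Normalized matrix, samples in rows (n >= 8).
#' @param y Binary labels; every class needs >= 2 samples.
#' @param top_k Features kept after ranking (default
#'   `min(5, ncol(X))`).
#' @param n_repeats Monte-Carlo repeats.
#' @param holdout_fraction Fraction held out per repeat.
#' @param seed Integer seed (results are deterministic given it).
#' @param lambda Ridge penalty.
#' @return List with `auc` (mean), `ci` (2.5/97.5 percentiles),
#'   `auc_repeats`, `top_k`, `n_repeats`.
#' @export
roc_multivariate <- function(X, y, top_k = min(5L, ncol(X)),
                             n_repeats = 50L, holdout_fraction = 1 / 3,
                             seed = 1L, lambda = 1) {
  stopifnot(is.matrix(X))
  y <- factor(y)
  if (nlevels(y) != 2L) stop("need exactly two classes")
  if (any(table(y) < 2L)) stop("each class needs at least 2 samples")
  n <- nrow(X)
  if (n < 8L) stop("need at least 8 samples")
  yy <- ifelse(y == levels(y)[1], -1, 1)

  aucs <- with_seed(seed, vapply(seq_len(n_repeats), function(rep) {
    test <- unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      k <- max(1L, round(length(idx) * holdout_fraction))
      k <- min(k, length(idx) - 2L)   # keep >= 2 per class in training
      sample(idx, k)
    }))
    train <- setdiff(seq_len(n), test)
    fit_all <- ridge_weights(X[train, , drop = FALSE], yy[train], lambda)
    keep <- order(-abs(fit_all$w))[seq_len(top_k)]
    fit <- ridge_weights(X[train, keep, drop = FALSE], yy[train], lambda)
    score <- sweep(X[test, keep, drop = FALSE], 2, fit$center) %*% fit$w +
      fit$b
    roc_univariate(as.vector(score), y[test])$auc
  }, numeric(1)))
  list(auc = mean(aucs),
       ci = stats::quantile(aucs, c(0.025, 0.975), names = FALSE),
       auc_repeats = aucs, top_k = top_k, n_repeats = n_repeats)
}
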