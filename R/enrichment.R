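#' Two-sided Wilcoxon rank-sum test
#'
#' Mann-Whitney U with the exact null distribution when both groups have
#' no ties and at most 50 observations, otherwise the tie-corrected normal
#' approximation with continuity correction. A feature constant across
#' both groups yields p = 1.
#'
#' @param x,y Numeric samples.
#' @return List with `U` (statistic for the first sample) and `p`.
#' @export
wilcox_rank_sum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 <= 50 && n2 <= 50) {
    p <- if (U > n1 * n2 / 2)
      2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    else
      2 * stats::pwilcox(U, n1, n2)
    p <- min(1, p)
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(list(U = U, p = 1))
    z <- U - mu
    z <- sign(z) * max(0, abs(z) - 0.5)   # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z) / sqrt(sig2)))
  }
  list(U = U, p = p)
}

#' Cluster-wise differential features (one-vs-rest)
#'
#' For every cluster and panel feature, a two-sided Wilcoxon rank-sum test
#' of the cluster's pixels against all other pixels, with
#' Benjamini-Hochberg correction across features within each cluster.
#' Fold-changes are computed on means with a pseudo-count of half the
#' smallest nonzero matrix value.
#'
#' @param fm A `feature_matrix` (normalized values are the usual input).
#' @param labels Integer/character cluster label per pixel.
#' @return An `enrichment_table` `data.frame` with columns `cluster`,
#'   `feature`, `U`, `p`, `q`, `log2fc`, `mean_in`, `mean_out`, sorted by
#'   cluster, then `q`, then decreasing `|log2fc|`.
#' @export
rank_features <- function(fm, labels) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- fm$values
  if (length(labels) != nrow(X))
    stop("one label per pixel required")
  ids <- sort(unique(labels))
  if (length(ids) < 2L) stop("need at least 2 clusters")
  sizes <- table(labels)
  if (any(sizes < 2L)) stop("every cluster needs at least 2 pixels")
  nz <- X[X > 0]
  pc <- if (length(nz)) min(nz) / 2 else .Machine$double.eps

  out <- do.call(rbind, lapply(ids, function(cl) {
    inn <- labels == cl
    res <- lapply(seq_len(ncol(X)), function(j)
      wilcox_rank_sum(X[inn, j], X[!inn, j]))
    p <- vapply(res, `[[`, numeric(1), "p")
    mi <- colMeans(X[inn, , drop = FALSE])
    mo <- colMeans(X[!inn, , drop = FALSE])
    data.frame(cluster = cl, feature = colnames(X),
               U = vapply(res, `[[`, numeric(1), "U"),
               p = p, q = stats::p.adjust(p, "BH"),
               log2fc = log2((mi + pc) / (mo + pc)),
               mean_in = mi, mean_out = mo, row.names = NULL)
  }))
  out <- out[order(out$cluster, out$q, -abs(out$log2fc)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Glycogen chain-length profile and total glycogen
#'
#' Per-group mean and standard error of each DP-ladder feature, plus the
#' per-pixel total glycogen, defined as the sum over all `glycogen_dp`
#' panel features.
#'
#' @param fm A `feature_matrix`.
#' @param grouping Factor/character per pixel (e.g. region or cluster).
#' @param panel The panel; defaults to the one stored in `fm`.
#' @return List with `profile` (`data.frame`: `group`, `dp`, `label`,
#'   `mean`, `sem`, `n`) and `total_glycogen` (`data.frame`: per pixel
#'   `pixel_id`, `group`, `total`).
#' @export
chain_profile <- function(fm, grouping, panel = fm$panel) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(grouping) != nrow(fm$values))
    stop("one group per pixel required")
  is_dp <- panel$class == "glycogen_dp"
  if (!any(is_dp)) stop("panel has no glycogen_dp features")
  dp_lab <- panel$label[is_dp]
  dp_num <- round((panel$target_mz[is_dp] - mass_constants[["water"]] -
                   mass_constants[["na_cation"]]) / mass_constants[["hex"]])
  V <- fm$values[, dp_lab, drop = FALSE]
  groups <- unique(as.character(grouping))
  if (any(vapply(groups, function(g) sum(grouping == g), integer(1)) == 0L))
    stop("empty group")
  profile <- do.call(rbind, lapply(groups, function(g) {
    sub <- V[grouping == g, , drop = FALSE]
    data.frame(group = g, dp = as.integer(dp_num), label = dp_lab,
               mean = colMeans(sub),
               sem = apply(sub, 2, stats::sd) / sqrt(nrow(sub)),
               n = nrow(sub), row.names = NULL)
  }))
  list(profile = profile,
       total_glycogen = data.frame(pixel_id = fm$pixels$pixel_id,
                                   group = as.character(grouping),
                                   total = rowSums(V)))
}

# Holm-Sidak step-down adjustment of a p-value vector.
holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Group comparison statistics
#'
#' `two_sample_t`: two-tailed Welch t-test. `one_way`: one-way ANOVA F
#' test with Holm-Sidak-adjusted pairwise Welch post-hoc comparisons.
#' `two_way`: two-way ANOVA with interaction (factors `groups` and
#' `factor2`, e.g. treatment x DP) and, per level of `factor2`,
#' Holm-Sidak-adjusted pairwise group comparisons.
#'
#' @param values Numeric response vector.
#' @param groups Factor/character group per observation.
#' @param design One of `"two_sample_t"`, `"one_way"`, `"two_way"`.
#' @param factor2 Second factor for the two-way layout.
#' @return List with `design`, `table` (main test) and, for ANOVA
#'   designs, `posthoc` (`data.frame` of pairwise comparisons with
#'   adjusted p).
#' @export
compare_groups <- function(values, groups,
                           design = c("two_sample_t", "one_way", "two_way"),
                           factor2 = NULL) {
  design <- match.arg(design)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("fewer than 2 observations in a group")

  if (design == "two_sample_t") {
    if (nlevels(groups) != 2L) stop("two_sample_t requires exactly 2 groups")
    tt <- stats::t.test(values ~ groups)
    return(list(design = design,
                table = data.frame(statistic = unname(tt$statistic),
                                   df = unname(tt$parameter),
                                   p = tt$p.value)))
  }

  pairwise <- function(sub_values, sub_groups) {
    lv <- levels(droplevels(sub_groups))
    prs <- utils::combn(lv, 2, simplify = FALSE)
    p <- vapply(prs, function(pr) {
      stats::t.test(sub_values[sub_groups == pr[1]],
                    sub_values[sub_groups == pr[2]])$p.value
    }, numeric(1))
    data.frame(group1 = vapply(prs, `[`, character(1), 1),
               group2 = vapply(prs, `[`, character(1), 2),
               p = p, p_adj = holm_sidak(p))
  }

  if (design == "one_way") {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    return(list(design = design,
                table = data.frame(F = an$`F value`[1], df1 = an$Df[1],
                                   df2 = an$Df[2], p = an$`Pr(>F)`[1]),
                posthoc = pairwise(values, groups)))
  }

  if (is.null(factor2)) stop("two_way design requires factor2")
  f2 <- factor(factor2)
  if (any(table(groups, f2) < 2L))
    stop("fewer than 2 observations in a cell of the two-way layout")
  fit <- stats::lm(values ~ groups * f2)
  an <- stats::anova(fit)
  ph <- do.call(rbind, lapply(levels(f2), function(lv) {
    sub <- f2 == lv
    cbind(level = lv, pairwise(values[sub], droplevels(groups[sub])))
  }))
  ph$p_adj <- holm_sidak(ph$p)   # adjust across all levels jointly
  list(design = design,
       table = data.frame(term = rownames(an), F = an$`F value`,
                          df = an$Df, p = an$`Pr(>F)`, row.names = NULL),
       posthoc = ph)
}

#' Hierarchically ordered heatmap layout
#'
#' Selects the `top_k` rows with the largest variance (or all rows of a
#' pre-ranked matrix), then orders rows and columns by agglomerative
#' clustering with the Euclidean distance and Ward linkage. The ordering
#' is deterministic; exact ties fall back to label order.
#'
#' @param mat Numeric matrix, features in rows.
#' @param top_k Number of top-variance rows to keep (default
#'   `min(50, nrow)`).
#' @return List with `rows` (selected row names in display order),
#'   `cols`, and the two `hclust` objects.
#' @export
ordered_heatmap <- function(mat, top_k = min(50L, nrow(mat))) {
  stopifnot(is.matrix(mat))
  if (anyNA(mat)) stop("matrix contains missing values")
  if (top_k > nrow(mat)) stop("top_k exceeds the number of features")
  if (is.null(rownames(mat))) rownames(mat) <- seq_len(nrow(mat))
  if (is.null(colnames(mat))) colnames(mat) <- seq_len(ncol(mat))
  v <- apply(mat, 1, stats::var)
  keep <- order(-v, rownames(mat))[seq_len(top_k)]
  sub <- mat[sort(keep), , drop = FALSE]
  rh <- stats::hclust(stats::dist(sub, "euclidean"), method = "ward.D2")
  ch <- stats::hclust(stats::dist(t(sub), "euclidean"), method = "ward.D2")
  list(rows = rownames(sub)[rh$order], cols = colnames(sub)[ch$order],
       row_hclust = rh, col_hclust = ch)
}
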