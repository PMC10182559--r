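#' Unsupervised pixel clustering on carbohydrate features
#'
#' Spatially agnostic clustering of pixels: Euclidean k-nearest-neighbor
#' graph on log1p-transformed TIC-normalized feature rows, then Leiden
#' community detection under modularity at the given resolution. Because
#' modularity optimization tends to split large homogeneous kNN-graph
#' components, communities whose centroids are statistically
#' indistinguishable (centroid separation not exceeding `merge_factor`
#' times the pooled within-community RMS spread) are merged afterwards;
#' with `merge_factor = 0` the raw Leiden partition is returned. Labels
#' are dense-coded `0..C-1` by decreasing cluster size (ties broken by
#' smallest member pixel id).
#'
#' @param fm A TIC-normalized `feature_matrix`.
#' @param k_neighbors Neighbors in the kNN graph (default 15).
#' @param resolution Leiden resolution parameter (default 1.0).
#' @param seed Integer seed (Leiden refinement is stochastic).
#' @param merge_factor Post-hoc merge threshold described above; default 2
#'   because bisecting a single Gaussian cluster separates the half-centroids
#'   by at most ~1.6 within-RMS, while genuinely distinct clusters in this
#'   feature space sit well above 2.
#' @return A `cluster_result`: `labels` (integer per pixel), `pixels`
#'   frame, `params`, empty `matrix_cluster_ids`, `retained_pixels` = all.
#' @export
cluster_pixels <- function(fm, k_neighbors = 15L, resolution = 1.0,
                           seed = 1L, merge_factor = 2.0) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!fm$normalized) stop("cluster_pixels expects a TIC-normalized matrix")
  n <- nrow(fm$values)
  if (n < 2L) stop("need at least 2 pixels")
  if (k_neighbors >= n) stop("k_neighbors must be < number of pixels")

  X <- log1p(fm$values)
  nn <- FNN::get.knn(X, k = k_neighbors)
  edges <- cbind(rep(seq_len(n), k_neighbors), as.vector(nn$nn.index))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  memb <- with_seed(seed, igraph::membership(igraph::cluster_leiden(
    g, objective_function = "modularity",
    resolution = resolution, n_iterations = 5)))
  memb <- merge_indistinguishable(X, as.integer(memb), merge_factor)
  labels <- dense_code_labels(memb, fm$pixels$pixel_id)

  structure(list(labels = labels,
                 pixels = fm$pixels,
                 embedding = NULL,
                 matrix_cluster_ids = integer(0),
                 retained_pixels = fm$pixels$pixel_id,
                 params = list(k_neighbors = k_neighbors,
                               resolution = resolution, seed = seed,
                               merge_factor = merge_factor)),
            class = "cluster_result")
}

# Merge communities whose centroids are closer than `factor` times the
# pooled within-community RMS distance-to-centroid. Zero-spread clusters
# merge only at exactly zero separation.
merge_indistinguishable <- function(X, memb, factor) {
  if (factor < 0) return(memb)
  repeat {
    ids <- sort(unique(memb))
    if (length(ids) < 2L) return(memb)
    cent <- t(vapply(ids, function(c)
      colMeans(X[memb == c, , drop = FALSE]), numeric(ncol(X))))
    size <- vapply(ids, function(c) sum(memb == c), numeric(1))
    ssw <- vapply(seq_along(ids), function(k) {
      d <- X[memb == ids[k], , drop = FALSE] -
        matrix(cent[k, ], nrow = size[k], ncol = ncol(X), byrow = TRUE)
      sum(d * d)
    }, numeric(1))
    best <- NULL; best_score <- Inf
    for (a in seq_along(ids)[-length(ids)]) for (b in (a + 1):length(ids)) {
      d <- sqrt(sum((cent[a, ] - cent[b, ])^2))
      s <- sqrt((ssw[a] + ssw[b]) / (size[a] + size[b]))
      qualifies <- if (s == 0) d == 0 else d <= factor * s
      score <- if (s == 0) d else d / s
      if (qualifies && score < best_score) { best <- c(a, b); best_score <- score }
    }
    if (is.null(best)) return(memb)
    memb[memb == ids[best[2]]] <- ids[best[1]]
  }
}

# Dense labels 0..C-1 by (size desc, smallest pixel_id asc).
dense_code_labels <- function(memb, pixel_ids) {
  ids <- unique(memb)
  size <- vapply(ids, function(c) sum(memb == c), numeric(1))
  first <- vapply(ids, function(c) min(pixel_ids[memb == c]), numeric(1))
  o <- order(-size, first)
  code <- integer(max(ids))
  new_of <- stats::setNames(seq_along(ids) - 1L, ids[o])
  as.integer(new_of[as.character(memb)])
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d pixels, %d clusters%s\n",
              length(x$labels), length(unique(x$labels)),
              if (length(x$matrix_cluster_ids))
                paste0(" (matrix: ",
                       paste(x$matrix_cluster_ids, collapse = ","), ")")
              else ""))
  invisible(x)
}

#' 2-D UMAP embedding of pixel feature vectors
#'
#' Visualization-only embedding of the log1p-transformed normalized
#' feature rows; no downstream stage consumes it. Deterministic for a
#' fixed seed (single-threaded SGD).
#'
#' @param fm A TIC-normalized `feature_matrix`.
#' @param seed Integer seed.
#' @param n_neighbors UMAP neighborhood size.
#' @return Numeric matrix, pixels by 2.
#' @export
embed_2d <- function(fm, seed = 1L, n_neighbors = 15L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!fm$normalized) stop("embed_2d expects a TIC-normalized matrix")
  n <- nrow(fm$values)
  if (n < 4L) stop("need at least 4 pixels to embed")
  X <- log1p(fm$values)
  emb <- with_seed(seed, uwot::umap(
    X, n_neighbors = min(n_neighbors, n - 1L), init = "spca",
    n_threads = 1, n_sgd_threads = 0, verbose = FALSE))
  dimnames(emb) <- list(fm$pixels$pixel_id, c("umap1", "umap2"))
  emb
}

#' Flag CHCA matrix clusters
#'
#' For each cluster, the matrix fraction is the mean over member pixels of
#' (sum of matrix-class feature values / sum of all panel feature values);
#' clusters at or above `matrix_fraction_threshold` are flagged as
#' off-tissue matrix clusters to be omitted from further analysis.
#' Flagging is monotone in the threshold.
#'
#' @param cr A `cluster_result`.
#' @param fm The `feature_matrix` the clustering was computed on.
#' @param panel A [peak_panel()] with at least one matrix-class entry.
#' @param matrix_fraction_threshold Flagging threshold in \[0, 1\].
#' @return Integer vector of flagged cluster ids (possibly empty, with a
#'   warning when no cluster qualifies).
#' @export
flag_matrix_clusters <- function(cr, fm, panel = fm$panel,
                                 matrix_fraction_threshold = 0.5) {
  stopifnot(inherits(cr, "cluster_result"), inherits(fm, "feature_matrix"))
  is_mat <- panel$class == "matrix"
  if (!any(is_mat)) stop("panel has no matrix-class entries")
  tot <- rowSums(fm$values)
  frac <- ifelse(tot > 0, rowSums(fm$values[, is_mat, drop = FALSE]) / tot, 0)
  ids <- sort(unique(cr$labels))
  cl_frac <- vapply(ids, function(c) mean(frac[cr$labels == c]), numeric(1))
  flagged <- ids[cl_frac >= matrix_fraction_threshold]
  if (!length(flagged))
    warning("no cluster reaches matrix fraction ",
            matrix_fraction_threshold)
  flagged
}

#' Remove matrix clusters and finalize the clustering
#'
#' Removes pixels belonging to the flagged matrix clusters. With
#' `mode = "recluster"` (default) the remaining pixels are re-clustered
#' from scratch, matching the practice of re-plotting the partition after
#' matrix removal; `mode = "keep_labels"` keeps the existing labels.
#'
#' @param cr A `cluster_result` with `matrix_cluster_ids` set (pass the
#'   output of [flag_matrix_clusters()] via `matrix_ids`).
#' @param fm The `feature_matrix` used for clustering.
#' @param matrix_ids Cluster ids to remove; defaults to
#'   `cr$matrix_cluster_ids`.
#' @param mode `"recluster"` or `"keep_labels"`.
#' @return A new `cluster_result` on the retained pixels; the removed
#'   pixel ids are recorded in `removed_pixels`.
#' @export
remove_and_finalize <- function(cr, fm, matrix_ids = cr$matrix_cluster_ids,
                                mode = c("recluster", "keep_labels")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cr, "cluster_result"), inherits(fm, "feature_matrix"))
  drop <- cr$labels %in% matrix_ids
  if (all(drop)) stop("matrix removal would empty the dataset")
  keep_ids <- fm$pixels$pixel_id[!drop]
  fm2 <- subset_pixels(fm, keep_ids)
  if (mode == "recluster" && length(matrix_ids)) {
    out <- cluster_pixels(fm2,
                          k_neighbors = min(cr$params$k_neighbors,
                                            nrow(fm2$values) - 1L),
                          resolution = cr$params$resolution,
                          seed = cr$params$seed,
                          merge_factor = cr$params$merge_factor)
  } else {
    out <- cr
    out$labels <- cr$labels[!drop]
    out$pixels <- fm2$pixels
    out$retained_pixels <- keep_ids
  }
  out$matrix_cluster_ids <- integer(0)
  out$removed_pixels <- fm$pixels$pixel_id[drop]
  out
}

#' Subset a feature matrix to a set of pixels
#'
#' @param fm A `feature_matrix`.
#' @param pixel_ids Pixel ids to retain.
#' @return The subset `feature_matrix`.
#' @export
subset_pixels <- function(fm, pixel_ids) {
  stopifnot(inherits(fm, "feature_matrix"))
  keep <- fm$pixels$pixel_id %in% pixel_ids
  out <- fm
  out$values <- fm$values[keep, , drop = FALSE]
  out$tic <- fm$tic[keep]
  out$pixels <- fm$pixels[keep, , drop = FALSE]
  out
}

#' Spatial cluster map
#'
#' Renders cluster labels back onto the acquisition grid (removed pixels
#' as background) via [write_label_map()].
#'
#' @param cr A `cluster_result`.
#' @param ds The source [msi_dataset()] (must share the pixel frame).
#' @param path Output stem for `<path>.csv` / `<path>.png`.
#' @return File paths, invisibly.
#' @export
spatial_map <- function(cr, ds, path) {
  stopifnot(inherits(cr, "cluster_result"), inherits(ds, "msi_dataset"))
  if (!all(cr$pixels$pixel_id %in% ds$pixels$pixel_id))
    stop("cluster result and dataset do not share a pixel frame")
  write_label_map(as.integer(cr$labels),
                  cr$pixels[, c("x", "y")], path, continuous = FALSE)
}
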