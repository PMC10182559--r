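test_that("noiseless regions are recovered exactly; degenerate inputs handled", {
  res <- phantom_fm(small_phantom_config(noise_cv = 0, drift_amplitude = 0))
  cr <- cluster_pixels(res$fm, seed = 3)
  expect_identical(length(unique(cr$labels)), 3L)
  expect_equal(adjusted_rand_index(cr$labels,
                                   res$ph$truth$label_map$region_id), 1.0)
  # labels are dense-coded by decreasing size
  sz <- table(cr$labels)
  expect_identical(names(sz), as.character(0:2))
  expect_true(all(diff(as.vector(sz)) <= 0))

  # all pixels identical -> single cluster
  uni <- res$fm
  uni$values <- matrix(rep(uni$values[1, ], each = nrow(uni$values)),
                       nrow = nrow(uni$values),
                       dimnames = dimnames(uni$values))
  expect_identical(unique(cluster_pixels(uni, seed = 1)$labels), 0L)

  expect_error(cluster_pixels(res$fm, k_neighbors = nrow(res$fm$values)),
               "k_neighbors")
  raw <- phantom_fm(small_phantom_config(), normalized = FALSE)$fm
  expect_error(cluster_pixels(raw), "normalized")
})

test_that("clustering is invariant to pixel order and deterministic by seed", {
  res <- phantom_fm(small_phantom_config(noise_cv = 0.2, seed = 5))
  cr1 <- cluster_pixels(res$fm, seed = 11)
  cr2 <- cluster_pixels(res$fm, seed = 11)
  expect_identical(cr1$labels, cr2$labels)

  perm <- sample(nrow(res$fm$values))
  fmp <- res$fm
  fmp$values <- fmp$values[perm, , drop = FALSE]
  fmp$tic <- fmp$tic[perm]
  fmp$pixels <- fmp$pixels[perm, , drop = FALSE]
  crp <- cluster_pixels(fmp, seed = 11)
  expect_equal(adjusted_rand_index(crp$labels[order(perm)], cr1$labels), 1.0)
})

test_that("UMAP embedding is deterministic and separates phantom regions", {
  res <- phantom_fm(small_phantom_config(noise_cv = 0.1, seed = 2))
  e1 <- embed_2d(res$fm, seed = 4)
  e2 <- embed_2d(res$fm, seed = 4)
  expect_identical(e1, e2)
  expect_identical(dim(e1), c(nrow(res$fm$values), 2L))

  # mean silhouette of truth labels in the embedding
  region <- res$ph$truth$label_map$region_id
  D <- as.matrix(dist(e1))
  sil <- vapply(seq_len(nrow(D)), function(i) {
    a <- mean(D[i, setdiff(which(region == region[i]), i)])
    b <- min(vapply(setdiff(unique(region), region[i]),
                    function(g) mean(D[i, region == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)

  small <- res$fm
  small$values <- small$values[1:3, , drop = FALSE]
  small$pixels <- small$pixels[1:3, , drop = FALSE]
  small$tic <- small$tic[1:3]
  expect_error(embed_2d(small), "at least 4")
})

test_that("matrix clusters are flagged by signal fraction, monotonically", {
  res <- phantom_fm(small_phantom_config(noise_cv = 0.2, seed = 7))
  cr <- cluster_pixels(res$fm, seed = 1)
  flagged <- flag_matrix_clusters(cr, res$fm)
  region <- res$ph$truth$label_map$region_id
  # the flagged cluster is the off-tissue border
  expect_identical(length(flagged), 1L)
  expect_gt(mean(region[cr$labels == flagged] == "matrix"), 0.99)
  # boundary threshold 1.0 flags nothing (with a warning)
  expect_warning(none <- flag_matrix_clusters(cr, res$fm,
                                              matrix_fraction_threshold = 1),
                 "no cluster")
  expect_identical(none, integer(0))
  # monotone: higher threshold never flags more
  ths <- c(0.2, 0.5, 0.8, 1.0)
  ns <- vapply(ths, function(t) length(suppressWarnings(
    flag_matrix_clusters(cr, res$fm, matrix_fraction_threshold = t))),
    integer(1))
  expect_true(all(diff(ns) <= 0))
  pan_nomat <- res$fm$panel[res$fm$panel$class != "matrix", ]
  class(pan_nomat) <- c("peak_panel", "data.frame")
  expect_error(flag_matrix_clusters(cr, res$fm, panel = pan_nomat),
               "matrix-class")
})

test_that("matrix removal modes behave per contract", {
  res <- phantom_fm(small_phantom_config(noise_cv = 0.2, seed = 9))
  cr <- cluster_pixels(res$fm, seed = 2)
  cr$matrix_cluster_ids <- flag_matrix_clusters(cr, res$fm)

  # keep_labels with nothing flagged is the identity
  ident <- remove_and_finalize(cr, res$fm, matrix_ids = integer(0),
                               mode = "keep_labels")
  expect_identical(ident$labels, cr$labels)
  expect_identical(ident$retained_pixels, cr$retained_pixels)

  fin1 <- remove_and_finalize(cr, res$fm, mode = "recluster")
  fin2 <- remove_and_finalize(cr, res$fm, mode = "recluster")
  expect_identical(fin1$labels, fin2$labels)

  region <- res$ph$truth$label_map$region_id
  removed <- res$fm$pixels$pixel_id %in% fin1$removed_pixels
  expect_gte(mean(region[removed] == "matrix"), 0.99)   # precision
  expect_gte(mean(removed[region == "matrix"]), 0.99)   # recall

  expect_error(remove_and_finalize(cr, res$fm,
                                   matrix_ids = unique(cr$labels)),
               "empty")
})

test_that("spatial maps reproduce the truth geometry", {
  res <- phantom_fm(small_phantom_config(noise_cv = 0, drift_amplitude = 0))
  cr <- cluster_pixels(res$fm, seed = 3)
  stem <- tempfile()
  spatial_map(cr, res$ph$dataset, stem)
  img <- utils::read.csv(paste0(stem, ".csv"))
  expect_identical(nrow(img), nrow(res$fm$pixels))
  expect_equal(adjusted_rand_index(img$value,
                                   res$ph$truth$label_map$region_id), 1.0)
  cr_bad <- cr
  cr_bad$pixels$pixel_id <- cr_bad$pixels$pixel_id + 10000L
  expect_error(spatial_map(cr_bad, res$ph$dataset, stem), "pixel frame")
})
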