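#' Aggregate pixels into tile (pseudo-ROI) samples
#'
#' Splits the pixel grid into square tiles and keeps tiles whose pixels
#' are at least `purity` pure in one group; each kept tile becomes one
#' sample whose feature vector is the mean over its pixels. This mirrors
#' summarising regions of interest into per-sample observations for
#' supervised analysis.
#'
#' @param fm A `feature_matrix`.
#' @param grouping Group per pixel (cluster label or region id).
#' @param tile Tile side length in pixels.
#' @param purity Minimum within-tile majority fraction.
#' @return List with `X` (samples x features), `y` (majority group), and
#'   `tiles` (`data.frame` of tile origins).
#' @export
tile_samples <- function(fm, grouping, tile = 5L, purity = 0.8) {
  stopifnot(inherits(fm, "feature_matrix"))
  tx <- fm$pixels$x %/% tile
  ty <- fm$pixels$y %/% tile
  key <- paste(tx, ty)
  rows <- list(); ys <- character(0); origins <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    tab <- sort(table(as.character(grouping[idx])), decreasing = TRUE)
    if (tab[1] / length(idx) < purity) next
    if (length(idx) < max(2L, tile)) next
    rows[[length(rows) + 1L]] <- colMeans(fm$values[idx, , drop = FALSE])
    ys <- c(ys, names(tab)[1])
    origins[[length(origins) + 1L]] <-
      c(tx = tx[idx[1]] * tile, ty = ty[idx[1]] * tile)
  }
  if (!length(rows)) stop("no pure tiles at this size/purity")
  X <- do.call(rbind, rows)
  list(X = X, y = ys,
       tiles = as.data.frame(do.call(rbind, origins)))
}

#' Pipeline run configuration
#'
#' @param out_dir Output directory for run artifacts.
#' @param seed Global seed; per-stage seeds are derived deterministically
#'   from it, so stages are independently reproducible.
#' @param stages Character vector of stages to execute, in fixed order
#'   from `"phantom"`, `"preprocess"`, `"cluster"`, `"enrich"`,
#'   `"quantify"`, `"biomarker"`.
#' @param phantom List of overrides passed to [phantom_config()].
#' @param preprocess List of overrides for [recalibration_config()].
#' @param cluster List: `k_neighbors`, `resolution`, `matrix_threshold`.
#' @param quantify List of overrides for [make_standard_spots()]
#'   (`amounts`, `response_slope`, `noise_cv`).
#' @param biomarker List: `tile`, `top_k`, `n_repeats`.
#' @return A `pipeline_config`; unknown keys in any override list are
#'   rejected.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            stages = c("phantom", "preprocess", "cluster",
                                       "enrich", "quantify", "biomarker"),
                            phantom = list(),
                            preprocess = list(),
                            cluster = list(),
                            quantify = list(),
                            biomarker = list()) {
  all_stages <- c("phantom", "preprocess", "cluster", "enrich", "quantify",
                  "biomarker")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  check_keys <- function(lst, allowed, what) {
    extra <- setdiff(names(lst), allowed)
    if (length(extra))
      stop("unknown ", what, " key(s): ", paste(extra, collapse = ", "))
    lst
  }
  check_keys(phantom, names(formals(phantom_config)), "phantom")
  check_keys(preprocess, names(formals(recalibration_config)), "preprocess")
  check_keys(cluster, c("k_neighbors", "resolution", "matrix_threshold",
                        "merge_factor"), "cluster")
  check_keys(quantify, c("amounts", "response_slope", "noise_cv"), "quantify")
  check_keys(biomarker, c("tile", "top_k", "n_repeats"), "biomarker")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = intersect(all_stages, stages),
                 phantom = phantom, preprocess = preprocess,
                 cluster = cluster, quantify = quantify,
                 biomarker = biomarker),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order, each consuming only prior-stage
#' artifacts, and writes a manifest (`manifest.json`) with the package
#' version, config hash, seed and per-stage wall time. All numeric
#' artifacts are deterministic for a fixed config and seed; only the
#' manifest's timing fields vary between runs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of in-memory stage results plus
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list(out_dir = config$out_dir)
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  stages <- config$stages
  p <- function(...) file.path(config$out_dir, ...)

  if ("phantom" %in% stages) {
    state$phantom <- tick("phantom", {
      cfg <- do.call(phantom_config,
                     utils::modifyList(list(seed = derive_seed(config$seed,
                                                               "phantom")),
                                       config$phantom))
      ph <- make_phantom(cfg)
      write_imzml(ph$dataset, p("phantom.imzML"))
      utils::write.csv(ph$truth$label_map, p("truth_labels.csv"),
                       row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(signatures = ph$truth$signatures,
             drift = ph$truth$drift_offsets$offset_da),
        p("truth_record.json"), digits = NA, auto_unbox = TRUE)
      ph
    })
  }

  if ("preprocess" %in% stages) {
    if (is.null(state$phantom))
      stop("preprocess: missing upstream artifact (phantom stage disabled)")
    state$preprocess <- tick("preprocess", {
      rcfg <- do.call(recalibration_config, config$preprocess)
      rc <- recalibrate(state$phantom$dataset, rcfg)
      fm_raw <- integrate_panel(rc$dataset, state$phantom$truth$config$panel)
      fm <- tic_normalize(fm_raw)
      utils::write.csv(rc$shifts, p("shift_table.csv"), row.names = FALSE,
                       quote = FALSE)
      write_pixel_table(fm$pixels, fm$values, p("fm_normalized.csv"))
      write_pixel_table(fm_raw$pixels, fm_raw$values, p("fm_raw.csv"))
      list(fm = fm, fm_raw = fm_raw, shifts = rc$shifts)
    })
  }

  if ("cluster" %in% stages) {
    if (is.null(state$preprocess))
      stop("cluster: missing upstream artifact (preprocess stage disabled)")
    state$cluster <- tick("cluster", {
      cc <- utils::modifyList(list(k_neighbors = 15L, resolution = 1.0,
                                   matrix_threshold = 0.5,
                                   merge_factor = 2.0), config$cluster)
      fm <- state$preprocess$fm
      cr <- cluster_pixels(fm, cc$k_neighbors, cc$resolution,
                           seed = derive_seed(config$seed, "cluster"),
                           merge_factor = cc$merge_factor)
      cr$matrix_cluster_ids <- flag_matrix_clusters(
        cr, fm, matrix_fraction_threshold = cc$matrix_threshold)
      final <- remove_and_finalize(cr, fm, mode = "recluster")
      fm_kept <- subset_pixels(fm, final$retained_pixels)
      emb <- embed_2d(fm_kept, seed = derive_seed(config$seed, "embed"))
      utils::write.csv(
        data.frame(pixel_id = final$pixels$pixel_id, x = final$pixels$x,
                   y = final$pixels$y, label = final$labels),
        p("labels.csv"), row.names = FALSE, quote = FALSE)
      utils::write.csv(
        data.frame(pixel_id = fm_kept$pixels$pixel_id, emb),
        p("embedding.csv"), row.names = FALSE, quote = FALSE)
      spatial_map(final, state$phantom$dataset, p("spatial_clusters"))
      jsonlite::write_json(final$params, p("cluster_params.json"),
                           auto_unbox = TRUE, digits = NA)
      list(result = final, fm = fm_kept, embedding = emb)
    })
  }

  if ("enrich" %in% stages) {
    if (is.null(state$cluster))
      stop("enrich: labels missing (cluster stage disabled)")
    state$enrich <- tick("enrich", {
      et <- rank_features(state$cluster$fm, state$cluster$result$labels)
      cp <- chain_profile(state$cluster$fm, state$cluster$result$labels)
      utils::write.csv(et, p("enrichment.csv"), row.names = FALSE,
                       quote = FALSE)
      utils::write.csv(cp$profile, p("chain_profile.csv"), row.names = FALSE,
                       quote = FALSE)
      list(table = et, chains = cp)
    })
  }

  if ("quantify" %in% stages) {
    if (is.null(state$preprocess))
      stop("quantify: missing upstream artifact (preprocess stage disabled)")
    state$quantify <- tick("quantify", {
      qc <- utils::modifyList(list(amounts = c(1, 10, 20, 40, 100, 1000),
                                   response_slope = 50, noise_cv = 0.05),
                              config$quantify)
      sp <- make_standard_spots(qc$amounts, qc$response_slope, qc$noise_cv,
                                seed = derive_seed(config$seed, "spots"),
                                panel = state$phantom$truth$config$panel)
      rc <- recalibrate(sp$dataset,
                        do.call(recalibration_config, config$preprocess))
      fm_sp <- integrate_panel(rc$dataset, state$phantom$truth$config$panel)
      curve <- fit_standard_curve(spot_signals(fm_sp, sp$truth$spot_of),
                                  qc$amounts)
      grouping <- state$phantom$truth$label_map$region_id
      qt <- quantify(state$preprocess$fm_raw, curve, grouping = grouping)
      utils::write.csv(qt$ng_per_pixel, p("ng_per_pixel.csv"),
                       row.names = FALSE, quote = FALSE)
      if (!is.null(qt$region_means))
        utils::write.csv(qt$region_means, p("ng_region_means.csv"),
                         row.names = FALSE, quote = FALSE)
      jsonlite::write_json(curve[c("slope", "intercept", "r_squared",
                                   "linear_range")],
                           p("standard_curve.json"), auto_unbox = TRUE,
                           digits = NA)
      write_label_map(qt$ng_per_pixel$ng,
                      qt$ng_per_pixel[, c("x", "y")], p("ng_map"),
                      continuous = TRUE)
      list(curve = curve, quant = qt)
    })
  }

  if ("biomarker" %in% stages) {
    if (is.null(state$cluster))
      stop("biomarker: labels missing (cluster stage disabled)")
    state$biomarker <- tick("biomarker", {
      bc <- utils::modifyList(list(tile = 5L, top_k = 5L, n_repeats = 50L),
                              config$biomarker)
      labs <- state$cluster$result$labels
      top2 <- names(sort(table(labs), decreasing = TRUE))[1:2]
      keep <- labs %in% top2
      fm_b <- subset_pixels(state$cluster$fm,
                            state$cluster$fm$pixels$pixel_id[keep])
      ts <- tile_samples(fm_b, labs[keep], tile = bc$tile)
      Xn <- log_autoscale(ts$X)
      pl <- plsda(Xn, ts$y)
      rocm <- roc_multivariate(Xn, ts$y, top_k = min(bc$top_k, ncol(Xn)),
                               n_repeats = bc$n_repeats,
                               seed = derive_seed(config$seed, "biomarker"))
      best <- names(which.max(pl$vip))
      rocu <- roc_univariate(ts$X[, best], ts$y)
      utils::write.csv(data.frame(feature = names(pl$vip), vip = pl$vip,
                                  selected = names(pl$vip) %in% pl$selected),
                       p("vip.csv"), row.names = FALSE, quote = FALSE)
      utils::write.csv(rocu$roc, p("roc_points.csv"), row.names = FALSE,
                       quote = FALSE)
      jsonlite::write_json(list(auc_multivariate = rocm$auc,
                                auc_ci = rocm$ci,
                                auc_univariate_top_vip = rocu$auc,
                                top_vip_feature = best),
                           p("auc.json"), auto_unbox = TRUE, digits = NA)
      list(plsda = pl, roc_multivariate = rocm, roc_univariate = rocu,
           samples = ts)
    })
  }

  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                               auto_unbox = TRUE, digits = NA, force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(package = "glycoscape",
                   version = as.character(utils::packageVersion("glycoscape")),
                   seed = config$seed,
                   config_hash = unname(tools::md5sum(tf)),
                   stages = stages,
                   wall_time_s = timings)
  unlink(tf)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(state)
}
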