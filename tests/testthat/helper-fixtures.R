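# Shared fixtures, built in code at test time.

# Small panel: keeps integration and clustering fast in unit tests.
small_panel <- function() {
  build_default_panel(dp_min = 5L, dp_max = 10L,
                      nglycans = c("Hex5HexNAc4dHex1", "Hex8HexNAc2",
                                   "Hex3HexNAc4dHex1"),
                      matrix_mz = chca_matrix_mz(3:5))
}

# 24x24 three-region phantom config (matrix border / normal / fibrotic).
small_phantom_config <- function(noise_cv = 0.2, drift_amplitude = 0.2,
                                 seed = 1L, panel = small_panel(),
                                 signatures = default_signatures(panel),
                                 ...) {
  phantom_config(grid_width = 24L, grid_height = 24L,
                 matrix_border_width = 3L,
                 regions = list(list(region_id = "fibrotic",
                                     shape = "ellipse", cx = 15, cy = 12,
                                     rx = 5, ry = 4,
                                     signature = "fibrotic")),
                 signatures = signatures,
                 noise_cv = noise_cv, drift_amplitude = drift_amplitude,
                 seed = seed, panel = panel, ...)
}

# Phantom -> recalibrated, integrated, TIC-normalized feature matrix.
phantom_fm <- function(cfg, normalized = TRUE) {
  ph <- make_phantom(cfg)
  rc <- recalibrate(ph$dataset)
  fm <- integrate_panel(rc$dataset, cfg$panel)
  list(ph = ph, fm = if (normalized) tic_normalize(fm) else fm)
}

# Tiny hand-built dataset: n pixels on one row, given spectra.
toy_dataset <- function(spectra) {
  n <- length(spectra)
  msi_dataset(data.frame(pixel_id = seq_len(n), x = seq_len(n) - 1L, y = 0L,
                         scan_index = seq_len(n) - 1L),
              spectra)
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration (oracle).
wilcox_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v <- c(x, y)
  r <- rank(v)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Brute-force AUC by pair counting (oracle).
auc_pairs <- function(values, y) {
  y <- factor(y)
  pos <- values[y == levels(y)[2]]
  neg <- values[y == levels(y)[1]]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
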