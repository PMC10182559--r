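test_that("wilcox_rank_sum matches the exact-enumeration oracle (n <= 8)", {
  set.seed(31)
  for (i in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = sample(c(0, 1.5), 1))
    got <- wilcox_rank_sum(x, y)
    expect_equal(got$p, wilcox_enum_p(x, y), tolerance = 1e-12)
  }
  # constant feature: all ties -> p = 1
  expect_identical(wilcox_rank_sum(rep(1, 5), rep(1, 7))$p, 1)
  # tie-corrected normal approximation agrees with stats::wilcox.test
  x <- c(1, 2, 2, 3, 5, 5, 8); y <- c(2, 4, 4, 6, 6, 9, 9, 11)
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                             exact = FALSE))
  expect_equal(wilcox_rank_sum(x, y)$p, ref$p.value, tolerance = 1e-9)
})

test_that("rank_features finds a spiked feature and validates input", {
  res <- phantom_fm(small_phantom_config(noise_cv = 0.2, seed = 13))
  region <- res$ph$truth$label_map$region_id
  fm <- res$fm
  spike <- "1809"
  fm$values[region == "fibrotic", spike] <-
    fm$values[region == "fibrotic", spike] * 10
  et <- rank_features(fm, region)
  fib <- et[et$cluster == "fibrotic", ]
  expect_identical(fib$feature[1], spike)
  expect_lt(fib$q[1], 0.05)
  expect_true(all(et$q >= et$p))
  expect_true(all(et$p >= 0 & et$p <= 1))
  expect_error(rank_features(fm, rep("one", nrow(fm$values))), "2 clusters")
})

test_that("chain profiles: additivity, trivial totals, null difference", {
  res <- phantom_fm(small_phantom_config(noise_cv = 0.15, seed = 21),
                    normalized = FALSE)
  region <- res$ph$truth$label_map$region_id
  cp <- chain_profile(res$fm, region)
  expect_true(all(cp$total_glycogen$total >= 0))
  pan <- res$fm$panel
  dp_labs <- pan$label[pan$class == "glycogen_dp"]
  expect_identical(length(unique(cp$profile$dp)), length(dp_labs))
  # additivity: summing two halves of the ladder equals the full total
  half <- dp_labs[1:3]
  tot2 <- rowSums(res$fm$values[, half, drop = FALSE]) +
    rowSums(res$fm$values[, setdiff(dp_labs, half), drop = FALSE])
  expect_equal(unname(tot2), cp$total_glycogen$total, tolerance = 1e-12)
  # identical signatures -> profile difference ~ 0
  arbitrary <- rep(c("g1", "g2"), length.out = sum(region == "normal"))
  cpn <- chain_profile(subset_pixels(res$fm,
                                     res$fm$pixels$pixel_id[region == "normal"]),
                       arbitrary)
  d <- with(cpn$profile, mean[group == "g1"] - mean[group == "g2"])
  s <- with(cpn$profile, sqrt(sem[group == "g1"]^2 + sem[group == "g2"]^2))
  expect_true(all(abs(d) < 4 * s))
  expect_error(chain_profile(res$fm, region, panel = {
    p <- pan[pan$class != "glycogen_dp", ]; class(p) <- class(pan); p
  }), "glycogen_dp")
})

test_that("compare_groups designs: trivial nulls, power, printed-size toy", {
  set.seed(5)
  a <- rnorm(30); b <- a  # identical groups
  same <- compare_groups(c(a, b), rep(c("x", "y"), each = 30))
  expect_gt(same$table$p, 0.99)
  f0 <- compare_groups(c(a, b, a), rep(c("x", "y", "z"), each = 30),
                       design = "one_way")
  expect_lt(f0$table$F, 1e-20)

  # two-sample power at delta = 2 sigma, n = 50 (500 sims)
  rej <- mean(replicate(500, {
    compare_groups(c(rnorm(50), rnorm(50, 2)),
                   rep(c("a", "b"), each = 50))$table$p < 0.05
  }))
  expect_gte(rej, 0.99)

  # group sizes mirroring a 7 vs 26 cohort run and return finite p
  toy <- compare_groups(c(rnorm(7), rnorm(26, 1)),
                        rep(c("n", "f"), c(7, 26)))
  expect_true(is.finite(toy$table$p))

  # two-way with interaction and Holm-Sidak post-hoc
  dd <- expand.grid(rep = 1:6, grp = c("ctl", "trt"), dp = paste0("dp", 3:6))
  val <- rnorm(nrow(dd)) + (dd$grp == "trt") * (dd$dp == "dp5") * 3
  tw <- compare_groups(val, dd$grp, design = "two_way", factor2 = dd$dp)
  expect_identical(nrow(tw$table), 4L)  # grp, dp, interaction, residuals
  ph <- tw$posthoc
  expect_lt(ph$p_adj[ph$level == "dp5"], 0.05)
  expect_true(all(ph$p_adj >= ph$p - 1e-12))
  expect_error(compare_groups(1:3, c("a", "a", "b")), "fewer than 2")
})

test_that("ordered_heatmap is deterministic with contiguous blocks", {
  set.seed(9)
  blockA <- matrix(rnorm(5 * 8, 10), 5, 8)
  blockB <- matrix(rnorm(5 * 8, -10), 5, 8)
  m <- rbind(blockA, blockB) + rnorm(80, sd = 0.1)
  rownames(m) <- paste0("f", 1:10)
  oh <- ordered_heatmap(m, top_k = 10)
  posA <- match(paste0("f", 1:5), oh$rows)
  expect_identical(diff(range(posA)), 4L)  # block A contiguous
  # identical rows end up adjacent
  m2 <- m; m2[2, ] <- m2[1, ]
  oh2 <- ordered_heatmap(m2, top_k = 10)
  expect_identical(abs(diff(match(c("f1", "f2"), oh2$rows))), 1L)
  expect_error(ordered_heatmap(m, top_k = 99), "top_k")
  m[1, 1] <- NA
  expect_error(ordered_heatmap(m), "missing")
})
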