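test_that("bias map has the right shape and exact zero lines", {
  m <- build_bias_map(bias_grid_spec())
  expect_equal(length(m$mean_axis), 21)   # -4.5 .. 0.5 by 0.25
  expect_equal(length(m$sd_axis), 13)     # 0.8 .. 2.0 by 0.1
  expect_equal(dim(m$bias), c(21, 13))
  # zero along the reference-SD column
  ref_col <- which(abs(m$sd_axis - 1) < 1e-9)
  expect_equal(unname(m$bias[, ref_col]), rep(0, 21))
  # zero along the mean == threshold row
  thr_row <- which(abs(m$mean_axis - (-2)) < 1e-9)
  expect_equal(unname(m$bias[thr_row, ]), rep(0, 13), tolerance = 1e-12)
  d <- as.data.frame(m)
  expect_equal(nrow(d), 21 * 13)
  expect_named(d, c("mean", "sd", "prevalence", "bias"))
})

test_that("point bias estimate matches CDF differences", {
  expect_equal(estimate_bias(-2, 2.0), 0)
  expect_equal(estimate_bias(-1, sqrt(2)),
               pnorm(-1 / sqrt(2)) - pnorm(-1), tolerance = 1e-12)
  expect_lt(abs(estimate_bias(-1, sqrt(2)) - 0.081), 5e-4)
  # antisymmetry about a mean at the threshold
  expect_equal(estimate_bias(-3, sqrt(2)), -estimate_bias(-1, sqrt(2)),
               tolerance = 1e-12)
  # the worked example: mean -1, SD inflated 1.0 -> 1.4 shifts the
  # prevalence from about 16% to about 24%, i.e. +8 points
  expect_equal(round(100 * estimate_bias(-1, 1.4)), 8)
  expect_error(estimate_bias(-1, 0), "positive")
})

test_that("bias surface is antisymmetric, sd-monotone and decays in |mean + 2|", {
  m <- build_bias_map(bias_grid_spec())
  b <- m$bias
  n <- length(m$mean_axis)
  # antisymmetry: the mean axis is symmetric about -2
  expect_equal(unname(b), unname(-b[n:1, ]), tolerance = 1e-12)
  # monotone in sd for fixed mean on either side of the threshold
  for (i in seq_len(n)) {
    if (m$mean_axis[i] > -2) expect_true(all(diff(b[i, ]) > 0))
    if (m$mean_axis[i] < -2) expect_true(all(diff(b[i, ]) < 0))
  }
  # |bias| shrinks moving away from mean -2 beyond the extremum
  far <- abs(estimate_bias(c(-8, -6, 4, 2), 2))
  near <- abs(estimate_bias(c(-3.25, -0.75), 2))
  expect_true(all(far < min(near)))
})

test_that("realistic bias range brackets the point estimate", {
  r <- realistic_bias_range(-1, 1.6)
  expect_equal(r$interval,
               sort(c(pnorm(-0.625) - pnorm(-1 / 0.8),
                      pnorm(-0.625) - pnorm(-1 / 1.2))))
  point <- estimate_bias(-1, 1.6)
  expect_gte(point, r$interval[1])
  expect_lte(point, r$interval[2])
  # degenerate cases
  expect_equal(realistic_bias_range(-2, 1.7)$interval, c(0, 0))
  expect_equal(realistic_bias_range(-1, 0.8)$bias_vs_low_ref, 0)
})

test_that("bias extrema sit at -0.75 / -3.25 on the upper SD boundary", {
  ex <- locate_bias_extrema(bias_grid_spec())
  expect_equal(ex$overestimate$mean, -0.75)
  expect_equal(ex$underestimate$mean, -3.25)
  expect_equal(ex$overestimate$sd, 2.0)
  expect_equal(ex$underestimate$sd, 2.0)
  # symmetric about -2 with opposite biases
  expect_equal(ex$overestimate$mean + ex$underestimate$mean, -4)
  expect_equal(ex$overestimate$bias, -ex$underestimate$bias,
               tolerance = 1e-12)
  # per-sd slices are also symmetric (the reference-SD slice is
  # identically zero, so its argmax/argmin are arbitrary)
  slices <- abs(ex$by_sd$sd - 1) > 1e-9
  expect_equal(ex$by_sd$mean_at_max[slices] + ex$by_sd$mean_at_min[slices],
               rep(-4, sum(slices)))
})

test_that("Monte Carlo map agrees with the closed form cellwise", {
  spec_mc <- bias_grid_spec(mean_step = 1, sd_step = 0.4,
                            engine = "monte_carlo", n_samples = 20000,
                            seed = 17)
  spec_cf <- bias_grid_spec(mean_step = 1, sd_step = 0.4)
  mc <- build_bias_map(spec_mc)
  cf <- build_bias_map(spec_cf)
  expect_equal(dim(mc$prevalence), dim(cf$prevalence))
  se <- pmax(mc$mc_standard_error, 1e-6)
  expect_true(all(abs(mc$prevalence - cf$prevalence) < 4 * se))
  # MC bias is exactly zero on the reference column too (column reuse)
  ref_col <- which(abs(mc$sd_axis - 1) < 1e-9)
  if (length(ref_col) == 1L) {
    expect_equal(unname(mc$bias[, ref_col]),
                 rep(0, length(mc$mean_axis)))
  }
})

test_that("map serialization round-trips values and metadata", {
  path <- tempfile(fileext = ".csv")
  m <- build_bias_map(bias_grid_spec(mean_step = 0.5, sd_step = 0.3))
  write_bias_map(m, path)
  back <- read.csv(path)
  expect_equal(back$bias, as.data.frame(m)$bias)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$reference_sd, 1)
  expect_equal(meta$engine, "closed_form")
})

test_that("degenerate grids and engines are rejected", {
  expect_error(bias_grid_spec(mean_step = 0), "positive")
  expect_error(bias_grid_spec(sd_min = -0.5), "positive")
  expect_error(bias_grid_spec(mean_min = 1, mean_max = 0), "min <= max")
  expect_error(bias_grid_spec(engine = "monte_carlo"), "seed")
  mc_map <- build_bias_map(bias_grid_spec(mean_step = 2.5, sd_step = 1.2,
                                          engine = "monte_carlo",
                                          n_samples = 1000, seed = 3))
  expect_error(locate_bias_extrema(mc_map), "closed_form")
})
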