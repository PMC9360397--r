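# Generator: study design, serum Hb arithmetic, forward models, noise
# calibration and patch rendering.

test_that("design cardinality is animals x fractions and inputs are checked", {
  cases <- list(list(n = 10, f = haemolysis_fractions(), expected = 70),
                list(n = 1, f = 0, expected = 1),
                list(n = 3, f = c(0, 0.1), expected = 6))
  for (cs in cases) {
    d <- generate_design(cs$n, cs$f, seed = 1)
    expect_equal(d$n_samples, cs$expected)
    expect_equal(nrow(simulate_samples(d)), cs$expected)
  }
  expect_error(generate_design(0), "positive")
  expect_error(generate_design(5, fractions = c(0, 0.2)), "0.2")
  expect_error(generate_design(5, fractions = numeric(0)), "non-empty")
})

test_that("design is deterministic per seed and blood Hb respects bounds", {
  d1 <- generate_design(10, seed = 7)
  d2 <- generate_design(10, seed = 7)
  expect_identical(d1$blood_hb, d2$blood_hb)
  d3 <- generate_design(200, seed = 8)
  expect_true(all(d3$blood_hb >= 80 & d3$blood_hb <= 140))
})

test_that("serum_hb follows fraction x blood Hb with a clipped baseline", {
  expect_equal(serum_hb(100, 0.10), 10)
  expect_equal(serum_hb(100, 0), 0)
  expect_equal(serum_hb(120, 0.01), 1.2)
  expect_error(serum_hb(-5, 0.1), "positive")
  expect_error(serum_hb(100, 0.2), "0, 0.1")
  # blanks with a baseline vary and never go negative
  set.seed(1)
  blanks <- serum_hb(rep(100, 500), 0, baseline_sd = 0.02)
  expect_gt(sd(blanks), 0)
  expect_true(all(blanks >= 0))
})

test_that("absorbance forward model evaluates the published line", {
  expect_equal(absorbance_forward(0), 0.1051)
  expect_equal(absorbance_forward(10), 0.9781)
  expect_equal(absorbance_forward(1), 0.1924)
  expect_error(absorbance_forward(-1), ">= 0")
})

test_that("noise_sd_for_target_r has the closed form and correct limits", {
  # slope 1, sd(x) 1, r = 0.5 -> sigma = sqrt(3)
  expect_equal(noise_sd_for_target_r(1, c(0, 1, 2), 0.5), sqrt(3))
  # r -> 1 drives sigma -> 0
  expect_lt(noise_sd_for_target_r(1, c(0, 1, 2), 0.999999), 1e-2)
  expect_error(noise_sd_for_target_r(1, rep(2, 5), 0.9), "variance")
  expect_error(noise_sd_for_target_r(1, c(0, 1), 1.5), "target_r")
})

test_that("calibrated noise reproduces the target correlation (Monte Carlo)", {
  # expectation over many replicate designs at the seven-level design
  set.seed(123)
  hb <- as.vector(outer(rep(110, 7), haemolysis_fractions()))
  sd_n <- noise_sd_for_target_r(0.0873, hb, 0.991)
  rs <- replicate(1e4, {
    y <- 0.1051 + 0.0873 * hb + rnorm(length(hb), 0, sd_n)
    cor(hb, y)
  })
  expect_lt(abs(mean(rs) - 0.991), 0.005)
})

test_that("rgb forward model inverts the Redbance line and is monotone", {
  noisefree <- function(hb) rgb_forward(hb, g_noise_sd = 0, b_noise_sd = 0)
  expect_equal(noisefree(0)[, "r"], 256 * 10^-0.0929, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(round(noisefree(0)[, "r"], 1), 206.7, ignore_attr = TRUE)
  expect_equal(round(noisefree(10)[, "r"], 1), 134.4, ignore_attr = TRUE)
  hb_grid <- seq(0, 12, by = 0.5)
  r_vals <- noisefree(hb_grid)[, "r"]
  expect_true(all(diff(r_vals) < 0))
  expect_true(all(noisefree(hb_grid) >= 1 & noisefree(hb_grid) <= 255))
})

test_that("sample table has the study structure and is byte-reproducible", {
  s <- make_sample_table(seed = 42)
  expect_equal(nrow(s), 70)
  expect_named(s, c("sample_id", "animal_id", "fraction", "hb_ref",
                    "absorbance540", "r_mean", "g_mean", "b_mean",
                    "intensity"))
  expect_true(all(s$hb_ref >= 0))
  expect_true(all(s$r_mean >= 1 & s$r_mean <= 255))
  # blanks vary (nonzero SD feeds a nonzero LOD downstream)
  expect_gt(sd(s$hb_ref[s$fraction == 0]), 0)
  # G, B only weakly related to Hb; R strongly
  expect_lt(abs(cor(s$g_mean, s$hb_ref)), 0.5)
  expect_lt(abs(cor(s$b_mean, s$hb_ref)), 0.5)
  expect_gt(abs(cor(s$r_mean, s$hb_ref)), 0.9)
  # identical seeds give byte-identical CSV artifacts
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_sample_table(make_sample_table(seed = 9), f1)
  write_sample_table(make_sample_table(seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(read_sample_table(f1)$hb_ref, make_sample_table(seed = 9)$hb_ref)
})

test_that("rendered patches round-trip through ROI extraction", {
  # noiseless integer colour: exact recovery
  p <- tempfile(fileext = ".png")
  render_patch(c(200, 180, 120), size = 16, pixel_noise_sd = 0, path = p)
  s <- roi_mean(read_image(p), roi(0, 0, 16, 16))
  expect_equal(c(s$r_mean, s$g_mean, s$b_mean), c(200, 180, 120))
  # noisy 64x64 patch: ROI mean within the standard-error bound
  render_patch(c(200, 180, 120), size = 64, pixel_noise_sd = 2, seed = 11,
               path = p)
  s <- roi_mean(read_image(p), roi(0, 0, 64, 64))
  expect_lt(abs(s$r_mean - 200), 0.2)
  expect_lt(abs(s$g_mean - 180), 0.2)
  expect_lt(abs(s$b_mean - 120), 0.2)
  # single pixel, noiseless: the rounded input
  render_patch(c(10.4, 20.6, 30), size = 1, pixel_noise_sd = 0, path = p)
  s <- roi_mean(read_image(p), roi(0, 0, 1, 1))
  expect_equal(c(s$r_mean, s$g_mean, s$b_mean), c(10, 21, 30))
  expect_error(render_patch(c(300, 0, 0), size = 4, path = p), "255")
})
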