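# coordinate-level bead pairs for one channel: reference positions plus a
# known displacement field and optional jitter
make_pairs <- function(n, field, channel, jitter_px = 0, seed = 1,
                       extent = c(90, 90, 20)) {
  set.seed(seed)
  ref <- data.frame(x = runif(n, 5, extent[1]), y = runif(n, 5, extent[2]),
                    z = runif(n, 3, extent[3]))
  ab <- eval_aberration(field, channel, ref$x, ref$y)
  data.frame(x_ref = ref$x, y_ref = ref$y, z_ref = ref$z,
             x = ref$x + ab$dx + rnorm(n, 0, jitter_px),
             y = ref$y + ab$dy + rnorm(n, 0, jitter_px),
             z = ref$z + ab$dz + rnorm(n, 0, jitter_px))
}

quad_field <- function() {
  aberration_field(
    channels = c("cy5", "a594"),
    dx = list(a594 = c(0.8, 4e-3, -2e-3, 2e-5, -1e-5, 3e-5)),
    dy = list(a594 = c(-0.5, -3e-3, 2e-3, -2e-5, 3e-5, 1e-5)),
    dz = c(a594 = 1))
}

test_that("bead matching is mutual-nearest-neighbor within a radius", {
  set.seed(2)
  ref <- data.frame(x = runif(30, 5, 80), y = runif(30, 5, 80),
                    z = runif(30, 3, 18))
  pairs <- match_beads(ref, ref, max_radius_px = 5)
  expect_equal(nrow(pairs), 30)
  expect_true(all(pairs$dist_px == 0))

  other <- ref
  other$x[1] <- other$x[1] + 50 # displaced beyond the radius
  pairs2 <- match_beads(ref, other, max_radius_px = 5)
  expect_equal(nrow(pairs2), 29)
})

test_that("zero displacement fits to the identity model", {
  f0 <- aberration_field(channels = c("cy5", "a488"))
  pairs <- make_pairs(40, f0, "a488")
  model <- fit_aberration(list(a488 = pairs))
  expect_equal(model$channels$a488$dx, rep(0, 6), tolerance = 1e-10)
  expect_equal(model$channels$a488$dy, rep(0, 6), tolerance = 1e-10)
  expect_equal(model$channels$a488$dz, 0, tolerance = 1e-12)
  expect_equal(model$channels$a488$mse_px, 0, tolerance = 1e-12)
  # reference channel is the identity by construction
  expect_equal(model$channels$cy5$dx, rep(0, 6))
})

test_that("an injected quadratic field is recovered within 3 s.e.", {
  field <- quad_field()
  # 10 nm jitter = 10/130 lateral px
  pairs <- make_pairs(100, field, "a594", jitter_px = 10 / 130, seed = 5)
  model <- fit_aberration(list(a594 = pairs))
  m <- model$channels$a594
  expect_true(all(abs(m$dx - field$a594$dx) <= 3 * m$se_dx))
  expect_true(all(abs(m$dy - field$a594$dy) <= 3 * m$se_dy))
  expect_equal(m$dz, 1, tolerance = 0.05)

  mse <- correction_mse(pairs, model, "a594")
  expect_lt(mse["mse_3d_after"], mse["mse_3d_before"])
  expect_lt(mse["mse_2d_after"], 0.05)
})

test_that("exactly 6 well-spread beads interpolate a quadratic exactly", {
  field <- quad_field()
  set.seed(8)
  ref <- data.frame(x = c(10, 80, 14, 76, 40, 25), y = c(10, 12, 78, 74, 30, 60),
                    z = runif(6, 3, 18))
  ab <- eval_aberration(field, "a594", ref$x, ref$y)
  pairs <- data.frame(x_ref = ref$x, y_ref = ref$y, z_ref = ref$z,
                      x = ref$x + ab$dx, y = ref$y + ab$dy, z = ref$z + ab$dz)
  model <- fit_aberration(list(a594 = pairs))
  expect_lt(model$channels$a594$mse_px, 1e-16)
  expect_error(fit_aberration(list(a594 = pairs[1:5, ])), "at least 6")
})

test_that("coordinate correction inverts the model's own field", {
  field <- quad_field()
  pairs <- make_pairs(50, field, "a594", seed = 9)
  model <- fit_aberration(list(a594 = pairs))
  dots <- data.frame(x = pairs$x, y = pairs$y, z = pairs$z, channel = "a594")
  corr <- apply_correction(dots, model)
  expect_equal(corr$x, pairs$x_ref, tolerance = 1e-5)
  expect_equal(corr$y, pairs$y_ref, tolerance = 1e-5)
  expect_equal(corr$z, pairs$z_ref, tolerance = 1e-6)

  # reference-channel dots pass through unchanged
  refdots <- data.frame(x = 1:3, y = 4:6, z = c(2, 3, 4), channel = "cy5")
  expect_equal(apply_correction(refdots, model), refdots)
  expect_error(apply_correction(
    data.frame(x = 1, y = 1, z = 1, channel = "tmr"), model), "not in model")
})

test_that("pure-noise displacements are not 'corrected' away", {
  f0 <- aberration_field(channels = c("cy5", "a700"))
  pairs <- make_pairs(120, f0, "a700", jitter_px = 0.3, seed = 11)
  model <- fit_aberration(list(a700 = pairs))
  mse <- correction_mse(pairs, model, "a700")
  expect_lte(mse["mse_3d_after"], mse["mse_3d_before"])
  expect_gt(mse["mse_3d_after"] / mse["mse_3d_before"], 0.8)
})

test_that("models serialize to text and back", {
  field <- quad_field()
  pairs <- make_pairs(40, field, "a594", seed = 12)
  model <- fit_aberration(list(a594 = pairs))
  path <- tempfile(fileext = ".yaml")
  write_aberration_model(model, path)
  back <- read_aberration_model(path)
  expect_equal(back$reference_channel, "cy5")
  expect_equal(back$channels$a594$dx, model$channels$a594$dx, tolerance = 1e-8)
  expect_equal(back$channels$a594$dz, model$channels$a594$dz, tolerance = 1e-8)
})

test_that("bead fields rendered with a pure axial shift recover 200 nm", {
  field <- aberration_field(channels = c("cy5", "a594"),
                            dz = c(a594 = 1)) # one axial voxel = 200 nm
  bf <- render_bead_field(12, field, channels = c("cy5", "a594"),
                          stack_dim = c(70, 70, 20), seed = 4)
  expect_equal(nrow(bf$truth), 12)
  expect_equal(nrow(bf$displaced), 24) # per channel
  ref_dots <- do.call(rbind, lapply(seq_len(12), function(i) {
    fit_dot_3d(bf$stacks$cy5,
               round(c(bf$truth$y[i], bf$truth$x[i], bf$truth$z[i])))
  }))
  oth_dots <- do.call(rbind, lapply(seq_len(12), function(i) {
    fit_dot_3d(bf$stacks$a594,
               round(c(bf$truth$y[i], bf$truth$x[i], bf$truth$z[i] + 1)))
  }))
  ok <- ref_dots$converged & oth_dots$converged
  expect_gt(sum(ok), 8)
  dz_px <- mean(oth_dots$z[ok] - ref_dots$z[ok])
  expect_equal(dz_px * 200, 200, tolerance = 0.15)
})
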