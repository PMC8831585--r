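# allocation-like table from bare coordinates for the chr2 scheme
coords_allocation <- function(scheme, xyz) {
  data.frame(probe_id = scheme$probes$probe_id[seq_len(nrow(xyz))],
             x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
             status = "assigned", stringsAsFactors = FALSE)
}

test_that("splines interpolate the input points exactly", {
  scheme <- build_chr2_scheme()
  set.seed(1)
  xyz <- matrix(runif(16 * 3, 0, 5), ncol = 3)
  st <- interpolate_structure(coords_allocation(scheme, xyz), scheme)
  expect_equal(st$fx(st$t), xyz[, 1], tolerance = 1e-10)
  expect_equal(st$fy(st$t), xyz[, 2], tolerance = 1e-10)
  expect_equal(st$fz(st$t), xyz[, 3], tolerance = 1e-10)
  # 15 segments, 50 samples per segment
  expect_equal(nrow(st$samples), 15 * 50 + 1)
  expect_error(interpolate_structure(
    coords_allocation(scheme, xyz[1:2, ]), scheme), "3 present")
})

test_that("collinear points give a straight line with zero curvature", {
  scheme <- build_chr2_scheme()
  t <- seq(0, 1, length.out = 16)
  xyz <- cbind(1 + 2 * t, 3 - t, 0.5 + 4 * t)
  st <- interpolate_structure(coords_allocation(scheme, xyz), scheme)
  prof <- curvature_profile(st)
  expect_lt(max(prof$k), 1e-8)
  # the curve stays on the line
  mid <- st$samples
  expect_equal(mid$y, 3 - (mid$x - 1) / 2, tolerance = 1e-9)
})

test_that("curvature matches closed forms for circle and helix", {
  # a dense single-color design gives enough spline knots for the
  # interpolation error to drop below the closed-form tolerance
  n <- 60
  scheme <- build_chr2_scheme(write_probe_fixture(sprintf(
    "chr2\t%d\t%d\td%02d\tcy5", (1:n) * 100000, (1:n) * 100000 + 1000, 1:n)))
  th <- seq(0, 1.8 * pi, length.out = n)
  r <- 2
  circle <- cbind(r * cos(th), r * sin(th), rep(1, n))
  st <- interpolate_structure(coords_allocation(scheme, circle), scheme)
  prof <- curvature_profile(st)
  # avoid the natural-spline end segments where the fit leaves the circle
  inner <- prof[prof$t > quantile(prof$t, 0.1) &
                  prof$t < quantile(prof$t, 0.9), ]
  expect_equal(median(inner$k), 1 / r, tolerance = 1e-3)

  # helix x = a cos t, y = a sin t, z = c t: k = a / (a^2 + c^2)
  a <- 1.5; cc <- 0.6
  helix <- cbind(a * cos(th), a * sin(th), cc * th)
  sth <- interpolate_structure(coords_allocation(scheme, helix), scheme)
  profh <- curvature_profile(sth)
  innerh <- profh[profh$t > quantile(profh$t, 0.1) &
                    profh$t < quantile(profh$t, 0.9), ]
  expect_equal(median(innerh$k), a / (a^2 + cc^2), tolerance = 1e-3)
})

test_that("curvature is invariant under rigid motions and scaling of peaks", {
  scheme <- build_chr2_scheme()
  set.seed(7)
  xyz <- matrix(cumsum(rnorm(48, 0, 0.8)), ncol = 3)
  st1 <- interpolate_structure(coords_allocation(scheme, xyz), scheme)
  k1 <- curvature_profile(st1)

  # random rotation (QR of a random matrix) + translation
  qr_r <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_r) < 0) qr_r[, 1] <- -qr_r[, 1]
  xyz2 <- sweep(xyz %*% qr_r, 2, c(5, -3, 2), `+`)
  st2 <- interpolate_structure(coords_allocation(scheme, xyz2), scheme)
  k2 <- curvature_profile(st2)
  expect_equal(k2$k, k1$k, tolerance = 1e-6)

  # uniform rescaling preserves the peak count (curvature scales by 1/s)
  st3 <- interpolate_structure(coords_allocation(scheme, xyz * 3), scheme)
  k3 <- curvature_profile(st3)
  p1 <- curvature_peaks(k1)
  p3 <- curvature_peaks(k3)
  expect_equal(nrow(p1), nrow(p3))
  expect_equal(k3$k * 3, k1$k, tolerance = 1e-6)
})

test_that("normalized peaks lie in (0.1, 1] and plateaus are flagged", {
  scheme <- build_chr2_scheme()
  set.seed(9)
  xyz <- matrix(cumsum(rnorm(48, 0, 0.8)), ncol = 3)
  prof <- curvature_profile(
    interpolate_structure(coords_allocation(scheme, xyz), scheme))
  peaks <- curvature_peaks(prof)
  expect_true(all(peaks$k_norm > 0.1 & peaks$k_norm <= 1))
  expect_equal(max(peaks$k_norm), 1) # the global maximum is always reported

  # a secondary bump below the 0.1 threshold is excluded
  fake <- data.frame(t = 1:9, k = c(0.01, 1, 0.01, 0.005, 0.04, 0.005, 0,
                                    0.002, 0))
  pk <- curvature_peaks(fake)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$t, 2)

  const <- data.frame(t = 1:50, k = rep(0.5, 50))
  pc <- curvature_peaks(const)
  expect_equal(nrow(pc), 0)
  expect_true(attr(pc, "plateau"))
})

test_that("pairwise distance matrix aggregates present pairs only", {
  scheme <- build_chr2_scheme()
  set.seed(3)
  al1 <- coords_allocation(scheme, matrix(runif(48, 0, 8), ncol = 3))
  al2 <- al1
  al2$status[al2$probe_id == "chr2_p05"] <- "missing"
  res <- pairwise_distance_matrix(list(al1, al2), scheme)
  expect_equal(nrow(res$summary), 120)
  # pairs with p05 have exactly one sample (from al1)
  p05 <- res$summary$probe_i == "chr2_p05" | res$summary$probe_j == "chr2_p05"
  expect_true(all(res$summary$n[p05] == 1))
  expect_true(all(res$summary$n[!p05] == 2))
  # medians match direct computation for one pair
  i <- which(al1$probe_id == "chr2_p01")
  j <- which(al1$probe_id == "chr2_p02")
  d <- sqrt(sum((al1[i, c("x_um", "y_um", "z_um")] -
                   al1[j, c("x_um", "y_um", "z_um")])^2))
  row <- res$summary$probe_i == "chr2_p01" & res$summary$probe_j == "chr2_p02"
  expect_equal(res$summary$median_um[row], d, tolerance = 1e-10)
})

test_that("chain-model distances grow with genomic distance", {
  scheme <- build_chr2_scheme()
  # gentle steps and a roomy territory keep the chain in its power-law
  # regime (no saturation at the confinement scale)
  scenes <- simulate_structures(scheme, 120, step_scale_nm = 200,
                                territory_radius_nm = 6000, seed = 13)
  # direct truth positions (per probe, allele)
  allocs <- unlist(lapply(scenes, function(sc) {
    lapply(1:2, function(k) {
      tr <- sc$truth[sc$truth$allele == k, ]
      agg <- aggregate(tr[, c("x_nm", "y_nm", "z_nm")],
                       by = list(probe_id = tr$probe_id), FUN = mean)
      data.frame(probe_id = agg$probe_id, x_um = agg$x_nm / 1000,
                 y_um = agg$y_nm / 1000, z_um = agg$z_nm / 1000,
                 status = "assigned")
    })
  }), recursive = FALSE)
  res <- pairwise_distance_matrix(allocs, scheme)
  sm <- res$summary
  # 20-Mb pairs are physically farther than 3-Mb pairs
  expect_gt(median(sm$median_um[sm$genomic_distance == 2e7]),
            median(sm$median_um[sm$genomic_distance == 3e6]))
  # log-log monotone association across all 120 pairs
  expect_gt(cor(log(sm$genomic_distance), log(sm$median_um),
                method = "spearman"), 0.9)
})
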