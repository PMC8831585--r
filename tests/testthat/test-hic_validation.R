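test_that("compartment calls respect sign and the uncertainty band", {
  track <- eigenvector_track(data.frame(
    chrom = "chr2", start = c(0, 1e5, 2e5, 3e5),
    end = c(1e5, 2e5, 3e5, 4e5),
    value = c(0.5, -0.005, 0, -0.3)))
  out <- ab_compartments(track)
  expect_equal(out$compartment, c("A", "unassigned", "unassigned", "B"))
  flipped <- eigenvector_track(track, sign_convention = "negative_A")
  expect_equal(ab_compartments(flipped)$compartment,
               c("B", "unassigned", "unassigned", "A"))
})

test_that("probe-pair contact lookup matches the matrix by construction", {
  scheme <- build_chr2_scheme()
  mids <- probe_midpoints(scheme)
  n_bins <- floor(max(mids) / 1e5) + 1
  idx <- outer(seq_len(n_bins), seq_len(n_bins),
               function(i, j) 1 / (1 + abs(i - j)))
  cm <- contact_matrix("chr2", 1e5, idx)
  pairs <- probe_pair_contact_freq(cm, scheme)
  expect_equal(nrow(pairs), 120)
  b <- floor(mids / 1e5) + 1
  expect_equal(pairs$hic_freq,
               unname(1 / (1 + abs(b[pairs$probe_i] - b[pairs$probe_j]))))
  # off-chromosome probes are refused
  cm_wrong <- contact_matrix("chr7", 1e5, idx)
  expect_error(probe_pair_contact_freq(cm_wrong, scheme), "chromosome")
})

test_that("contact matrices round-trip through the pairs text format", {
  set.seed(2)
  m <- matrix(0, 8, 8)
  m[upper.tri(m, diag = TRUE)] <- rpois(36, 4)
  m <- m + t(m) - diag(diag(m))
  cm <- contact_matrix("chr2", 1e5, m)
  path <- tempfile(fileext = ".tsv")
  write_contact_matrix(cm, path)
  back <- read_contact_matrix(path, bin_size = 1e5)
  expect_equal(back$mat[seq_len(8), seq_len(8)], m)
  expect_equal(back$chrom, "chr2")
  expect_error(contact_matrix("chr2", 1e5, matrix(c(0, 1, 2, 0), 2)),
               "symmetric")
})

test_that("FISH contact frequency is inclusive at the threshold", {
  samples <- data.frame(
    cluster = 1:3, probe_i = "p1", probe_j = "p2",
    dist_um = c(0.5, 1.0, 1.5))
  f <- fish_contact_frequency(samples)
  expect_equal(f$contact_freq, 2 / 3)
  expect_equal(f$n, 3)
  expect_equal(fish_contact_frequency(transform(samples, dist_um = 0.5))$contact_freq, 1)
  expect_equal(fish_contact_frequency(transform(samples, dist_um = 2))$contact_freq, 0)
  # monotone non-decreasing in the threshold
  ths <- c(0.3, 0.6, 1, 1.4, 2)
  fr <- vapply(ths, function(t) fish_contact_frequency(samples, t)$contact_freq,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("correlations match the closed-form and degrade under permutation", {
  set.seed(6)
  x <- runif(120, 0.3, 4)
  y <- exp(-x)
  r <- correlate_fish_hic(x, y)
  expect_equal(r$spearman, -1)
  expect_lt(r$pearson, 0)
  expect_equal(r$n, 120)
  # brute-force product-moment formula
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r$pearson, brute, tolerance = 1e-12)

  perm_r <- vapply(1:10, function(i) {
    set.seed(i)
    abs(correlate_fish_hic(sample(x), y)$pearson)
  }, numeric(1))
  expect_gte(mean(perm_r < 0.3), 0.9)

  expect_error(correlate_fish_hic(rep(1, 10), runif(10)), "constant")
  expect_error(correlate_fish_hic(c(1, 2), c(3, 4)), "3 complete")
})

test_that("lamina-by-compartment summarises medians per probe", {
  set.seed(3)
  dots <- data.frame(
    probe_id = rep(c("pa", "pb"), each = 50),
    lamina_norm = c(runif(50, 0.4, 1), runif(50, 0, 0.6)))
  labels <- c(pa = "A", pb = "B")
  res <- lamina_by_compartment(dots, labels)
  expect_true(res$comparison_defined)
  expect_gt(res$summary, 0)
  # identical distributions give a near-zero summary
  same <- transform(dots, lamina_norm = rep(runif(50), 2))
  expect_equal(lamina_by_compartment(same, labels)$summary, 0,
               tolerance = 1e-9)
  # one-compartment input has no defined comparison
  res1 <- lamina_by_compartment(dots, c(pa = "A", pb = "A"))
  expect_false(res1$comparison_defined)
  expect_true(is.na(res1$summary))
})

test_that("a matched synthetic contact matrix reproduces the sign structure", {
  scheme <- build_chr2_scheme()
  truth_allocs <- function(scenes) {
    unlist(lapply(scenes, function(sc) lapply(1:2, function(k) {
      tr <- sc$truth[sc$truth$allele == k, ]
      agg <- aggregate(tr[, c("x_nm", "y_nm", "z_nm")],
                       by = list(probe_id = tr$probe_id), FUN = mean)
      data.frame(probe_id = agg$probe_id, x_um = agg$x_nm / 1000,
                 y_um = agg$y_nm / 1000, z_um = agg$z_nm / 1000,
                 status = "assigned")
    })), recursive = FALSE)
  }
  d_a <- pairwise_distance_matrix(
    truth_allocs(simulate_structures(scheme, 80, seed = 41)), scheme)
  d_b <- pairwise_distance_matrix(
    truth_allocs(simulate_structures(scheme, 80, seed = 42)), scheme)
  cm <- contact_matrix_from_distances(d_b, scheme)
  hic <- probe_pair_contact_freq(cm, scheme)
  # median distance anti-correlates with contacts; FISH contacts correlate
  r_dist <- correlate_fish_hic(d_a$summary$median_um, hic$hic_freq)
  expect_lt(r_dist$pearson, -0.5)
  fc <- fish_contact_frequency(d_a)
  key <- paste(fc$probe_i, fc$probe_j)
  r_freq <- correlate_fish_hic(
    fc$contact_freq, hic$hic_freq[match(key, paste(hic$probe_i, hic$probe_j))])
  expect_gt(r_freq$pearson, 0.5)
})
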