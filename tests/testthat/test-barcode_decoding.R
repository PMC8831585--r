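test_that("co-localization thresholds follow the dichroic layout", {
  expect_equal(colocalization_threshold("tmr", "cy5"), 0.25)
  expect_equal(colocalization_threshold("a488", "a594"), 0.55)
  expect_equal(colocalization_threshold("a594", "a700"), 0.25)
  expect_equal(colocalization_threshold("a488", "cy5"), 0.55)
  expect_error(colocalization_threshold("cy5", "cy5"), "distinct")
})

test_that("homolog clustering splits well-separated clouds exactly", {
  set.seed(5)
  n <- 20
  dots <- data.frame(
    x_nm = c(rnorm(n, 5000, 600), rnorm(n, 15000, 600)),
    y_nm = c(rnorm(n, 5000, 600), rnorm(n, 5200, 600)),
    z_nm = rnorm(2 * n, 3000, 400),
    intensity = 1000)
  cl <- cluster_homologs(dots, seed = 2)
  expect_false(cl$merged)
  truth <- rep(1:2, each = n)
  got <- cl$dots$cluster_id
  expect_true(all(got[1:n] == got[1]) && all(got[(n + 1):(2 * n)] == got[n + 1]))
  expect_false(got[1] == got[n + 1])

  # an outlier ~45 px from its nearest cloud is dropped by the 40 px radius
  dots2 <- rbind(dots, data.frame(x_nm = 5000, y_nm = 5000 + 45 * 130,
                                  z_nm = 3000, intensity = 1000))
  cl2 <- cluster_homologs(dots2, seed = 2)
  expect_true(is.na(cl2$dots$cluster_id[nrow(dots2)]))

  cl3 <- cluster_homologs(dots, seed = 2)
  expect_identical(cl$dots$cluster_id, cl3$dots$cluster_id)
  expect_error(cluster_homologs(dots[1, ]), "at least 2")
})

test_that("candidate selection keeps the expected dots per channel", {
  scheme <- build_chr2_scheme()
  set.seed(3)
  dots <- data.frame(
    channel = c(rep("a488", 12), rep("ir800", 3)),
    intensity = c(runif(12, 100, 200), runif(3, 100, 200)),
    x_nm = runif(15, 0, 1000), y_nm = runif(15, 0, 1000),
    z_nm = runif(15, 0, 1000), dot_id = 1:15)
  kept <- select_candidates(dots, scheme)
  expect_equal(sum(kept$channel == "a488"), 10)
  expect_equal(sum(kept$channel == "ir800"), 2)
  # the brightest survive
  expect_true(all(sort(dots$intensity[1:12], decreasing = TRUE)[1:10] %in%
                    kept$intensity))
  expect_equal(sum(select_candidates(dots[dots$channel == "ir800", ],
                                     scheme)$channel == "a488"), 0)
})

test_that("a clean cluster decodes to all 16 probes at full accuracy", {
  scheme <- build_chr2_scheme()
  dots <- grid_cluster_dots(scheme, seed = 4)
  alloc <- decode_cluster(dots, scheme)
  expect_s3_class(alloc, "mifish_allocation")
  expect_equal(sum(alloc$status == "assigned"), 16)
  truth <- grid_cluster_truth(dots)
  expect_equal(decoding_accuracy(alloc, truth), 1.0)
  # dual probes carry their co-localization distance, singles do not
  dual <- alloc[!is.na(alloc$channel2), ]
  expect_true(all(dual$coloc_dist_um < 0.25))
  expect_true(all(is.na(alloc$coloc_dist_um[is.na(alloc$channel2)])))
})

test_that("a dual pair split farther than its threshold goes missing", {
  scheme <- build_chr2_scheme()
  dots <- grid_cluster_dots(scheme, seed = 6)
  # displace one dye of the a488/a594 probe by 0.6 um (> 0.55 threshold)
  pid <- scheme$dual_pairs[["a488|a594"]]
  i <- which(dots$probe_id == pid & dots$channel == "a594")
  dots$x_nm[i] <- dots$x_nm[i] + 600
  alloc <- decode_cluster(dots, scheme)
  expect_equal(alloc$status[alloc$probe_id == pid], "missing")
})

test_that("split same-channel dots are suppressed, not double-assigned", {
  scheme <- build_chr2_scheme()
  dots <- grid_cluster_dots(scheme, seed = 8)
  # add a split twin 0.3 um from a tmr dual dot
  pid <- scheme$dual_pairs[["cy5|tmr"]]
  i <- which(dots$probe_id == pid & dots$channel == "tmr")
  twin <- dots[i, ]
  twin$x_nm <- twin$x_nm + 300
  twin$intensity <- twin$intensity * 0.9
  twin$dot_id <- max(dots$dot_id) + 1
  alloc <- decode_cluster(rbind(dots, twin), scheme)
  used <- c(alloc$dot_id1, alloc$dot_id2)
  used <- used[!is.na(used)]
  expect_false(any(duplicated(used))) # no dot serves two probes
  expect_true(twin$dot_id %in% attr(alloc, "suppressed_dots") ||
                !(twin$dot_id %in% used))
  expect_equal(sum(alloc$status == "assigned"), 16)
})

test_that("no dot is assigned twice across random scenes", {
  scheme <- build_chr2_scheme()
  scenes <- small_scene(n_cells = 6, seed = 14)
  for (sc in scenes) {
    dt <- scene_dot_table(sc, seed = sc$cell_id)
    for (k in 1:2) {
      alloc <- decode_cluster(dt[dt$allele == k, ], scheme)
      used <- c(alloc$dot_id1, alloc$dot_id2)
      expect_false(any(duplicated(used[!is.na(used)])))
    }
  }
})

test_that("relaxing the same-cube threshold never loses dual assignments", {
  scheme <- build_chr2_scheme()
  scenes <- small_scene(n_cells = 8, seed = 17, coloc_jitter_nm = 120)
  for (sc in scenes) {
    dt <- scene_dot_table(sc, seed = sc$cell_id)
    for (k in 1:2) {
      cd <- dt[dt$allele == k, ]
      strict <- decode_cluster(cd, scheme)
      relaxed <- decode_cluster(cd, scheme, relaxed_same_cube = TRUE)
      n_dual <- function(a) sum(a$status == "assigned" & !is.na(a$channel2))
      expect_gte(n_dual(relaxed), n_dual(strict))
    }
  }
})

test_that("the multi-assignment variant may reuse dots", {
  scheme <- build_chr2_scheme()
  dots <- grid_cluster_dots(scheme, seed = 21)
  multi <- decode_cluster(dots, scheme, allow_multi_assignment = TRUE)
  expect_equal(sum(multi$status == "assigned"), 16)
})

test_that("outlier probes far from the cluster are flagged", {
  scheme <- build_chr2_scheme()
  dots <- grid_cluster_dots(scheme, seed = 23)
  pid <- scheme$probes$probe_id[is.na(scheme$probes$dye2) &
                                  scheme$probes$dye1 == "ir800"]
  i <- dots$probe_id == pid
  dots$x_nm[i] <- dots$x_nm[i] + 3e4 # 30 um away from everything
  alloc <- decode_cluster(dots, scheme)
  expect_equal(alloc$status[alloc$probe_id == pid], "outlier")
})

test_that("the random-allocation null is reproducible and weaker", {
  scheme <- build_chr2_scheme()
  sc <- small_scene(seed = 25)[[1]]
  dt <- scene_dot_table(sc, seed = 1)
  cd <- dt[dt$allele == 1, ]
  n1 <- random_allocation_null(cd, scheme, n_random = 1, n_reiterate = 1,
                               seed = 9)
  n2 <- random_allocation_null(cd, scheme, n_random = 1, n_reiterate = 1,
                               seed = 9)
  expect_identical(as.data.frame(n1[[1]]), as.data.frame(n2[[1]]))

  truth <- sc$truth[sc$truth$allele == 1, ]
  acc_decode <- decoding_accuracy(decode_cluster(cd, scheme), truth)
  null_best <- random_allocation_null(cd, scheme, n_reiterate = 10,
                                      seed = 2)[[1]]
  expect_gte(acc_decode, decoding_accuracy(null_best, truth))

  # an empty candidate channel leaves those dual probes missing
  no_pairs <- cd[cd$channel == "a488", ]
  alloc <- random_allocation_null(no_pairs, scheme, n_reiterate = 2,
                                  seed = 3)[[1]]
  expect_true(all(alloc$status[!is.na(alloc$channel2)] == "missing"))
})

test_that("decoding accuracy scores perfect, empty and partial allocations", {
  scheme <- build_chr2_scheme()
  dots <- grid_cluster_dots(scheme, seed = 27)
  truth <- grid_cluster_truth(dots)
  alloc <- decode_cluster(dots, scheme)
  expect_equal(decoding_accuracy(alloc, truth), 1.0)
  none <- alloc
  none$status <- "missing"
  expect_equal(decoding_accuracy(none, truth), 0.0)
  one_off <- alloc
  one_off$x1_nm[1] <- one_off$x1_nm[1] + 5e3
  expect_equal(decoding_accuracy(one_off, truth), 15 / 16)
})
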