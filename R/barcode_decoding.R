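#' Co-localization threshold for a dye pair
#'
#' The two dots of a dual-color probe must co-localize within a distance that
#' depends on whether the two channels are imaged through the same multi-band
#' dichroic cube (no mechanical movement between exposures, threshold
#' 0.25 um) or through different cubes (0.55 um).
#'
#' @param dye_a,dye_b Two distinct dye channel names.
#' @return Threshold in um.
#' @examples
#' colocalization_threshold("tmr", "cy5")   # 0.25, same cube
#' colocalization_threshold("a488", "a594") # 0.55, different cubes
#' @export
colocalization_threshold <- function(dye_a, dye_b) {
  if (dye_a == dye_b) stop("co-localization threshold needs two distinct dyes")
  ga <- dichroic_group(dye_a)
  gb <- dichroic_group(dye_b)
  if (ga == gb) 0.25 else 0.55
}

#' Partition a nucleus's dots into two homolog clusters
#'
#' k-means with k = 2 on the physical dot coordinates splits the dots of a
#' diploid G1 nucleus into the two chromosome homolog clusters. Dots farther
#' than `radius_px` (lateral-pixel units; the axial coordinate contributes in
#' the same units through the physical coordinates) from their cluster
#' centroid are dropped as outliers.
#'
#' @param dots data.frame with `x_nm`, `y_nm`, `z_nm` (and a `dot_id`;
#'   one is added if missing).
#' @param radius_px Cluster radius in lateral pixels (default 40 = 5.2 um).
#' @param seed Integer seed (k-means uses the best of 10 restarts).
#' @param lateral_px_nm Lateral pixel size in nm (default 130).
#' @return List with `dots` (input plus `cluster_id`, NA for outliers),
#'   `centroids` (per cluster, um) and `merged` (TRUE when the centroids are
#'   closer than 1 um, flagging a failed split).
#' @export
cluster_homologs <- function(dots, radius_px = 40, seed = NULL,
                             lateral_px_nm = 130) {
  if (nrow(dots) < 2) stop("need at least 2 dots to split homologs")
  if (!"dot_id" %in% names(dots)) dots$dot_id <- seq_len(nrow(dots))
  if (!is.null(seed)) set.seed(seed)
  xyz <- cbind(dots$x_nm, dots$y_nm, dots$z_nm)
  km <- stats::kmeans(xyz, centers = 2, nstart = 10)
  dots$cluster_id <- km$cluster
  dist_px <- sqrt(rowSums((xyz - km$centers[km$cluster, , drop = FALSE])^2)) /
    lateral_px_nm
  dots$cluster_id[dist_px > radius_px] <- NA_integer_
  centroids <- do.call(rbind, lapply(1:2, function(k) {
    sel <- !is.na(dots$cluster_id) & dots$cluster_id == k
    data.frame(cluster_id = k,
               x_um = mean(dots$x_nm[sel]) / 1000,
               y_um = mean(dots$y_nm[sel]) / 1000,
               z_um = mean(dots$z_nm[sel]) / 1000)
  }))
  sep_um <- sqrt(sum((centroids[1, 2:4] - centroids[2, 2:4])^2))
  list(dots = dots, centroids = centroids, merged = is.na(sep_um) || sep_um < 1)
}

#' Select per-channel candidate dots of one cluster
#'
#' Keeps the brightest dots of each channel, as many as expected from the
#' color scheme for one nucleus: twice the number of probes carrying the dye
#' (10 for the five dual-combination dyes of the chr2 design, 2 for ir800).
#' Fewer are kept when fewer exist.
#'
#' @param dots Dots of one cluster (`channel`, `intensity`, coordinates).
#' @param scheme A `mifish_scheme`.
#' @return The retained candidate dots.
#' @export
select_candidates <- function(dots, scheme) {
  k_per_channel <- expected_channel_counts(scheme, n_alleles = 2)
  keep <- unlist(lapply(names(k_per_channel), function(ch) {
    sel <- which(dots$channel == ch)
    if (length(sel) == 0) return(integer(0))
    sel[order(-dots$intensity[sel])][seq_len(min(k_per_channel[ch],
                                                 length(sel)))]
  }))
  out <- dots[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

dot_dist_um <- function(dots, i, j) {
  sqrt((dots$x_nm[i] - dots$x_nm[j])^2 + (dots$y_nm[i] - dots$y_nm[j])^2 +
         (dots$z_nm[i] - dots$z_nm[j])^2) / 1000
}

empty_allocation_row <- function(probe_id, ch1, ch2) {
  data.frame(probe_id = probe_id, channel1 = ch1, channel2 = ch2,
             dot_id1 = NA_integer_, dot_id2 = NA_integer_,
             x_um = NA_real_, y_um = NA_real_, z_um = NA_real_,
             x1_nm = NA_real_, y1_nm = NA_real_, z1_nm = NA_real_,
             x2_nm = NA_real_, y2_nm = NA_real_, z2_nm = NA_real_,
             coloc_dist_um = NA_real_, intensity = NA_real_,
             status = "missing", stringsAsFactors = FALSE)
}

#' Decode one homolog cluster into a probe allocation
#'
#' Implements the combinatorial dot-allocation procedure: enumerate candidate
#' dot pairs across channel pairs that form a dual-color probe and lie within
#' the channel-pair co-localization threshold; assign probes with a unique
#' candidate pair first; for contested probes choose the pair with the
#' shortest distance (ties broken by intensity sum, then stable dot id); on
#' every assignment remove the used dots and suppress same-channel dots
#' within `split_radius_um` of a used dot (split-dot filter); after dual and
#' single assignment, drop assigned dots farther than `outlier_radius_um`
#' from every other assigned dot; single-color probes receive the brightest
#' remaining dot of their channel (single probes carry twice the labelled
#' oligos, hence brighter signals). Unassignable probes are reported missing.
#'
#' @param dots Dots of one cluster (`dot_id`, `channel`, `intensity`,
#'   `x_nm`, `y_nm`, `z_nm`).
#' @param scheme A `mifish_scheme`.
#' @param relaxed_same_cube If TRUE, use 0.55 um also for same-cube channel
#'   pairs (the relaxed-threshold variant).
#' @param allow_multi_assignment If TRUE, dots may serve several dual-color
#'   probes (the less stringent variant); each probe independently takes its
#'   closest pair.
#' @param split_radius_um Same-channel split-dot suppression radius.
#' @param outlier_radius_um Outlier distance from all other assigned dots.
#' @return A `mifish_allocation`: data.frame with one row per probe
#'   (`probe_id`, channels, dot ids, probe position in um — the midpoint of
#'   the two dots for dual-color probes —, `coloc_dist_um`, `intensity`,
#'   `status` in assigned/missing/outlier), with the suppressed dot ids in
#'   `attr(, "suppressed_dots")`.
#' @export
decode_cluster <- function(dots, scheme, relaxed_same_cube = FALSE,
                           allow_multi_assignment = FALSE,
                           split_radius_um = 0.50, outlier_radius_um = 5) {
  cand <- select_candidates(dots, scheme)
  probes <- scheme$probes
  alloc <- do.call(rbind, lapply(seq_len(nrow(probes)), function(i) {
    empty_allocation_row(probes$probe_id[i], probes$dye1[i], probes$dye2[i])
  }))
  suppressed <- integer(0)
  if (nrow(cand) > 0) {
    # enumerate candidate pairs for every dual-color probe
    dual <- probes[!is.na(probes$dye2), , drop = FALSE]
    pair_list <- do.call(rbind, lapply(seq_len(nrow(dual)), function(i) {
      a <- which(cand$channel == dual$dye1[i])
      b <- which(cand$channel == dual$dye2[i])
      if (length(a) == 0 || length(b) == 0) return(NULL)
      thr <- if (relaxed_same_cube) 0.55 else
        colocalization_threshold(dual$dye1[i], dual$dye2[i])
      grid <- expand.grid(ia = a, ib = b)
      grid$dist <- dot_dist_um(cand, grid$ia, grid$ib)
      grid <- grid[grid$dist < thr, , drop = FALSE]
      if (nrow(grid) == 0) return(NULL)
      data.frame(probe_id = dual$probe_id[i], ia = grid$ia, ib = grid$ib,
                 dist = grid$dist,
                 int_sum = cand$intensity[grid$ia] + cand$intensity[grid$ib],
                 stringsAsFactors = FALSE)
    }))

    available <- rep(TRUE, nrow(cand)) # eligible for dual-color pairing
    used <- rep(FALSE, nrow(cand))     # actually assigned to a probe
    assign_pair <- function(probe_id, ia, ib, dist) {
      r <- which(alloc$probe_id == probe_id)
      alloc$dot_id1[r] <<- cand$dot_id[ia]
      alloc$dot_id2[r] <<- cand$dot_id[ib]
      alloc$x1_nm[r] <<- cand$x_nm[ia]; alloc$y1_nm[r] <<- cand$y_nm[ia]
      alloc$z1_nm[r] <<- cand$z_nm[ia]
      alloc$x2_nm[r] <<- cand$x_nm[ib]; alloc$y2_nm[r] <<- cand$y_nm[ib]
      alloc$z2_nm[r] <<- cand$z_nm[ib]
      alloc$x_um[r] <<- (cand$x_nm[ia] + cand$x_nm[ib]) / 2000
      alloc$y_um[r] <<- (cand$y_nm[ia] + cand$y_nm[ib]) / 2000
      alloc$z_um[r] <<- (cand$z_nm[ia] + cand$z_nm[ib]) / 2000
      alloc$coloc_dist_um[r] <<- dist
      alloc$intensity[r] <<- cand$intensity[ia] + cand$intensity[ib]
      alloc$status[r] <<- "assigned"
      if (!allow_multi_assignment) {
        available[c(ia, ib)] <<- FALSE
        used[c(ia, ib)] <<- TRUE
        # split-dot filter: clear nearby same-channel dots from the lists of
        # the other dual-color probes (they stay eligible for single-color
        # probes, which are picked by brightness afterwards)
        for (i in c(ia, ib)) {
          near <- which(available & cand$channel == cand$channel[i])
          if (length(near) > 0) {
            dd <- dot_dist_um(cand, rep(i, length(near)), near)
            kill <- near[dd < split_radius_um]
            if (length(kill) > 0) {
              available[kill] <<- FALSE
              suppressed <<- c(suppressed, cand$dot_id[kill])
            }
          }
        }
      }
    }

    if (!is.null(pair_list) && nrow(pair_list) > 0) {
      if (allow_multi_assignment) {
        for (pid in unique(pair_list$probe_id)) {
          pp <- pair_list[pair_list$probe_id == pid, , drop = FALSE]
          best <- pp[order(pp$dist, -pp$int_sum, pp$ia, pp$ib)[1], ]
          assign_pair(pid, best$ia, best$ib, best$dist)
        }
      } else {
        repeat {
          active <- pair_list[available[pair_list$ia] &
                                available[pair_list$ib] &
                                alloc$status[match(pair_list$probe_id,
                                                   alloc$probe_id)] ==
                                "missing", , drop = FALSE]
          if (nrow(active) == 0) break
          counts <- table(active$probe_id)
          unique_probes <- names(counts)[counts == 1]
          if (length(unique_probes) > 0) {
            # prioritize probes whose candidate pair is unambiguous,
            # tightest co-localization first
            pp <- active[active$probe_id %in% unique_probes, , drop = FALSE]
            pp <- pp[order(pp$dist, -pp$int_sum, pp$ia, pp$ib)[1], ]
            assign_pair(pp$probe_id, pp$ia, pp$ib, pp$dist)
          } else {
            best <- active[order(active$dist, -active$int_sum,
                                 active$ia, active$ib)[1], ]
            assign_pair(best$probe_id, best$ia, best$ib, best$dist)
          }
        }
      }
    }

    # single-color probes: brightest remaining dot of the channel
    singles <- probes[is.na(probes$dye2), , drop = FALSE]
    for (i in seq_len(nrow(singles))) {
      sel <- which(!used & cand$channel == singles$dye1[i])
      if (allow_multi_assignment) sel <- which(cand$channel == singles$dye1[i])
      if (length(sel) == 0) next
      j <- sel[which.max(cand$intensity[sel])]
      r <- which(alloc$probe_id == singles$probe_id[i])
      alloc$dot_id1[r] <- cand$dot_id[j]
      alloc$x1_nm[r] <- cand$x_nm[j]; alloc$y1_nm[r] <- cand$y_nm[j]
      alloc$z1_nm[r] <- cand$z_nm[j]
      alloc$x_um[r] <- cand$x_nm[j] / 1000
      alloc$y_um[r] <- cand$y_nm[j] / 1000
      alloc$z_um[r] <- cand$z_nm[j] / 1000
      alloc$intensity[r] <- cand$intensity[j]
      alloc$status[r] <- "assigned"
      if (!allow_multi_assignment) {
        available[j] <- FALSE
        used[j] <- TRUE
      }
    }

    # outlier filter: assigned dots > outlier_radius_um from all other
    # assigned dots
    arows <- which(alloc$status == "assigned")
    if (length(arows) > 1) {
      pos <- cbind(alloc$x_um[arows], alloc$y_um[arows], alloc$z_um[arows])
      D <- as.matrix(stats::dist(pos))
      diag(D) <- Inf
      far <- apply(D, 1, min) > outlier_radius_um
      alloc$status[arows[far]] <- "outlier"
    }
  }
  rownames(alloc) <- NULL
  attr(alloc, "suppressed_dots") <- unique(suppressed)
  class(alloc) <- c("mifish_allocation", "data.frame")
  alloc
}

#' Random-allocation null model
#'
#' Generates random probe allocations of a cluster: for each dual-color probe
#' the first dot is drawn at random from its channel's candidates and redrawn
#' (up to `n_random` times) until a partner in the second channel lies within
#' 0.55 um; a random such partner completes the pair. The assignment is
#' reiterated `n_reiterate` times per cluster and the resulting allocations
#' are ranked lexicographically by (1) total allocated intensity, (2) fewest
#' dots allocated to more than one probe, (3) most pairs overlapping within
#' 0.55 um, (4) fewest failed allocations, (5) fewest same-channel allocated
#' dot pairs within 0.25 um, in decreasing order of importance.
#'
#' @param dots Dots of one cluster.
#' @param scheme A `mifish_scheme`.
#' @param n_random Redraw attempts per probe.
#' @param n_reiterate Number of random allocations generated.
#' @param seed Integer seed.
#' @return List of `mifish_allocation` objects, best-ranked first; each
#'   carries its score vector in `attr(, "score")`.
#' @export
random_allocation_null <- function(dots, scheme, n_random = 100,
                                   n_reiterate = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cand <- select_candidates(dots, scheme)
  probes <- scheme$probes
  dual <- probes[!is.na(probes$dye2), , drop = FALSE]
  singles <- probes[is.na(probes$dye2), , drop = FALSE]

  one_allocation <- function() {
    alloc <- do.call(rbind, lapply(seq_len(nrow(probes)), function(i) {
      empty_allocation_row(probes$probe_id[i], probes$dye1[i], probes$dye2[i])
    }))
    used <- integer(0)
    n_failed <- 0
    for (i in sample(seq_len(nrow(dual)))) {
      a <- which(cand$channel == dual$dye1[i])
      b <- which(cand$channel == dual$dye2[i])
      done <- FALSE
      if (length(a) > 0 && length(b) > 0) {
        for (try in seq_len(n_random)) {
          ia <- a[sample.int(length(a), 1)]
          dd <- dot_dist_um(cand, rep(ia, length(b)), b)
          ok <- b[dd < 0.55]
          if (length(ok) > 0) {
            ib <- ok[sample.int(length(ok), 1)]
            r <- which(alloc$probe_id == dual$probe_id[i])
            alloc$dot_id1[r] <- cand$dot_id[ia]
            alloc$dot_id2[r] <- cand$dot_id[ib]
            alloc$x1_nm[r] <- cand$x_nm[ia]; alloc$y1_nm[r] <- cand$y_nm[ia]
            alloc$z1_nm[r] <- cand$z_nm[ia]
            alloc$x2_nm[r] <- cand$x_nm[ib]; alloc$y2_nm[r] <- cand$y_nm[ib]
            alloc$z2_nm[r] <- cand$z_nm[ib]
            alloc$x_um[r] <- (cand$x_nm[ia] + cand$x_nm[ib]) / 2000
            alloc$y_um[r] <- (cand$y_nm[ia] + cand$y_nm[ib]) / 2000
            alloc$z_um[r] <- (cand$z_nm[ia] + cand$z_nm[ib]) / 2000
            alloc$coloc_dist_um[r] <- dot_dist_um(cand, ia, ib)
            alloc$intensity[r] <- cand$intensity[ia] + cand$intensity[ib]
            alloc$status[r] <- "assigned"
            used <- c(used, ia, ib)
            done <- TRUE
            break
          }
        }
      }
      if (!done) n_failed <- n_failed + 1
    }
    for (i in seq_len(nrow(singles))) {
      sel <- which(cand$channel == singles$dye1[i])
      if (length(sel) == 0) {
        n_failed <- n_failed + 1
        next
      }
      j <- sel[sample.int(length(sel), 1)]
      r <- which(alloc$probe_id == singles$probe_id[i])
      alloc$dot_id1[r] <- cand$dot_id[j]
      alloc$x1_nm[r] <- cand$x_nm[j]; alloc$y1_nm[r] <- cand$y_nm[j]
      alloc$z1_nm[r] <- cand$z_nm[j]
      alloc$x_um[r] <- cand$x_nm[j] / 1000
      alloc$y_um[r] <- cand$y_nm[j] / 1000
      alloc$z_um[r] <- cand$z_nm[j] / 1000
      alloc$intensity[r] <- cand$intensity[j]
      alloc$status[r] <- "assigned"
      used <- c(used, j)
    }
    # score: higher is better in every component
    dup <- sum(table(used) > 1)
    same_ch_close <- 0
    uu <- unique(used)
    if (length(uu) > 1) {
      for (ch in unique(cand$channel[uu])) {
        ii <- uu[cand$channel[uu] == ch]
        if (length(ii) > 1) {
          cmb <- utils::combn(ii, 2)
          same_ch_close <- same_ch_close +
            sum(dot_dist_um(cand, cmb[1, ], cmb[2, ]) < 0.25)
        }
      }
    }
    score <- c(intensity = sum(alloc$intensity, na.rm = TRUE),
               no_dup = -dup,
               overlap_ok = sum(alloc$coloc_dist_um < 0.55, na.rm = TRUE),
               no_fail = -n_failed,
               no_split = -same_ch_close)
    rownames(alloc) <- NULL
    attr(alloc, "suppressed_dots") <- integer(0)
    attr(alloc, "score") <- score
    class(alloc) <- c("mifish_allocation", "data.frame")
    alloc
  }

  allocs <- lapply(seq_len(n_reiterate), function(i) one_allocation())
  scores <- t(vapply(allocs, function(a) attr(a, "score"), numeric(5)))
  ord <- do.call(order, c(as.data.frame(-scores), list(method = "radix")))
  allocs[ord]
}

#' Fraction of probes correctly decoded against ground truth
#'
#' A probe counts as correct when it is assigned and every assigned dot lies
#' within `tol_nm` of the probe's true position in the matching allele;
#' missing or outlier probes count as incorrect.
#'
#' @param allocation A `mifish_allocation`.
#' @param truth Scene truth rows for one allele (`probe_id`, `x_nm`, `y_nm`,
#'   `z_nm`; per-dye rows are averaged per probe).
#' @param tol_nm Tolerance (default 250 nm).
#' @return Fraction in 0..1.
#' @export
decoding_accuracy <- function(allocation, truth, tol_nm = 250) {
  pos <- stats::aggregate(truth[, c("x_nm", "y_nm", "z_nm")],
                          by = list(probe_id = truth$probe_id), FUN = mean)
  correct <- vapply(seq_len(nrow(allocation)), function(r) {
    a <- allocation[r, ]
    if (a$status != "assigned") return(FALSE)
    p <- pos[pos$probe_id == a$probe_id, ]
    if (nrow(p) == 0) stop("probe not in truth: ", a$probe_id)
    d1 <- sqrt((a$x1_nm - p$x_nm)^2 + (a$y1_nm - p$y_nm)^2 +
                 (a$z1_nm - p$z_nm)^2)
    d2 <- if (is.na(a$dot_id2)) 0 else
      sqrt((a$x2_nm - p$x_nm)^2 + (a$y2_nm - p$y_nm)^2 +
             (a$z2_nm - p$z_nm)^2)
    max(d1, d2) <= tol_nm
  }, logical(1))
  mean(correct)
}
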