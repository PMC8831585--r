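#' Interpolate a chromosome trace through decoded probe positions
#'
#' Fits a natural cubic spline through the present probe positions of one
#' allocation, in genomic order, using chord-length parameterization (the
#' spline parameter t advances by the Euclidean distance between consecutive
#' points). Missing probes are skipped; at least 3 present probes are needed.
#'
#' @param allocation A `mifish_allocation`, or a data.frame with `probe_id`,
#'   `x_um`, `y_um`, `z_um`.
#' @param scheme A `mifish_scheme` (defines the genomic order).
#' @param samples_per_segment Curve samples per inter-probe segment
#'   (default 50).
#' @return An `allele_structure`: list with `points` (present probes in
#'   genomic order), knot parameters `t`, spline functions `fx, fy, fz`
#'   (callable with `deriv`), and `samples` (data.frame t, x, y, z in um).
#' @export
interpolate_structure <- function(allocation, scheme,
                                  samples_per_segment = 50) {
  mids <- probe_midpoints(scheme)
  pts <- as.data.frame(allocation)[, c("probe_id", "x_um", "y_um", "z_um")]
  if ("status" %in% names(allocation)) {
    pts <- pts[allocation$status == "assigned", , drop = FALSE]
  }
  pts <- pts[!is.na(pts$x_um), , drop = FALSE]
  pts <- pts[order(mids[pts$probe_id]), , drop = FALSE]
  if (nrow(pts) < 3) stop("need at least 3 present probes for a cubic spline")
  seglen <- sqrt(diff(pts$x_um)^2 + diff(pts$y_um)^2 + diff(pts$z_um)^2)
  if (any(seglen == 0)) seglen[seglen == 0] <- 1e-9 # coincident points
  t <- c(0, cumsum(seglen))
  fx <- stats::splinefun(t, pts$x_um, method = "natural")
  fy <- stats::splinefun(t, pts$y_um, method = "natural")
  fz <- stats::splinefun(t, pts$z_um, method = "natural")
  ts <- unique(unlist(lapply(seq_len(length(t) - 1), function(i) {
    seq(t[i], t[i + 1], length.out = samples_per_segment + 1)
  })))
  structure(list(points = pts, t = t, fx = fx, fy = fy, fz = fz,
                 samples = data.frame(t = ts, x = fx(ts), y = fy(ts),
                                      z = fz(ts))),
            class = "allele_structure")
}

#' Curvature profile of an interpolated trace
#'
#' Evaluates the space-curve curvature
#' \deqn{k = \sqrt{(z''y'-y''z')^2 + (x''z'-z''x')^2 + (y''x'-x''y')^2} /
#'       (x'^2+y'^2+z'^2)^{3/2}}
#' at every sample of the structure, with derivatives taken analytically from
#' the piecewise cubic polynomials. Samples with vanishing speed are skipped
#' and flagged.
#'
#' @param structure An `allele_structure`.
#' @return data.frame with `t`, `k` (um^-1, non-negative) and attribute
#'   `n_skipped` (samples with zero speed).
#' @export
curvature_profile <- function(structure) {
  ts <- structure$samples$t
  d1 <- cbind(structure$fx(ts, deriv = 1), structure$fy(ts, deriv = 1),
              structure$fz(ts, deriv = 1))
  d2 <- cbind(structure$fx(ts, deriv = 2), structure$fy(ts, deriv = 2),
              structure$fz(ts, deriv = 2))
  speed2 <- rowSums(d1^2)
  num <- sqrt((d2[, 3] * d1[, 2] - d2[, 2] * d1[, 3])^2 +
                (d2[, 1] * d1[, 3] - d2[, 3] * d1[, 1])^2 +
                (d2[, 2] * d1[, 1] - d2[, 1] * d1[, 2])^2)
  ok <- speed2 > 0
  out <- data.frame(t = ts[ok], k = num[ok] / speed2[ok]^1.5)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Normalized curvature peaks
#'
#' Normalizes the curvature profile by its per-structure maximum (values in
#' (0, 1]) and reports the strict local maxima above `peak_threshold`. The
#' global maximum is always reported when it is unique; a constant (plateau)
#' profile has no strict maxima and yields an empty result with attribute
#' `plateau = TRUE`.
#'
#' @param profile Output of [curvature_profile()].
#' @param peak_threshold Minimal normalized peak height (default 0.1).
#' @return data.frame with `t` and normalized curvature `k_norm` of each
#'   peak.
#' @export
curvature_peaks <- function(profile, peak_threshold = 0.1) {
  k <- profile$k
  if (length(k) == 0 || max(k) <= 0) {
    out <- data.frame(t = numeric(0), k_norm = numeric(0))
    attr(out, "plateau") <- FALSE
    return(out)
  }
  kn <- k / max(k)
  n <- length(kn)
  is_peak <- c(FALSE, kn[2:(n - 1)] > kn[1:(n - 2)] &
                 kn[2:(n - 1)] > kn[3:n], FALSE)
  plateau <- length(unique(kn)) == 1
  gmax <- which.max(kn)
  if (!plateau && sum(kn == max(kn)) == 1) is_peak[gmax] <- TRUE
  sel <- which(is_peak & kn > peak_threshold)
  out <- data.frame(t = profile$t[sel], k_norm = kn[sel])
  attr(out, "plateau") <- plateau
  out
}

#' Pairwise probe distances across allocations
#'
#' Euclidean 3D distances between all present probe pairs, per cluster, and
#' the per-pair median across clusters. Dual-color probe positions are the
#' midpoint of their two co-localized dots.
#'
#' @param allocations List of `mifish_allocation` objects (or data.frames
#'   with `probe_id`, `x_um`, `y_um`, `z_um`, `status`).
#' @param scheme A `mifish_scheme`.
#' @return List with `samples` (cluster, probe_i, probe_j, dist_um) and
#'   `summary` (probe_i, probe_j, genomic_distance, n, median_um).
#' @export
pairwise_distance_matrix <- function(allocations, scheme) {
  stopifnot(length(allocations) >= 1)
  pairs <- probe_pair_table(scheme)
  samples <- do.call(rbind, lapply(seq_along(allocations), function(ci) {
    a <- as.data.frame(allocations[[ci]])
    a <- a[a$status == "assigned" & !is.na(a$x_um), , drop = FALSE]
    if (nrow(a) < 2) return(NULL)
    idx <- utils::combn(nrow(a), 2)
    i <- idx[1, ]; j <- idx[2, ]
    d <- sqrt((a$x_um[i] - a$x_um[j])^2 + (a$y_um[i] - a$y_um[j])^2 +
                (a$z_um[i] - a$z_um[j])^2)
    # orient each pair by genomic order
    mids <- probe_midpoints(scheme)
    swap <- mids[a$probe_id[i]] > mids[a$probe_id[j]]
    pi <- ifelse(swap, a$probe_id[j], a$probe_id[i])
    pj <- ifelse(swap, a$probe_id[i], a$probe_id[j])
    data.frame(cluster = ci, probe_i = pi, probe_j = pj, dist_um = d,
               stringsAsFactors = FALSE)
  }))
  if (is.null(samples)) {
    samples <- data.frame(cluster = integer(0), probe_i = character(0),
                          probe_j = character(0), dist_um = numeric(0))
  }
  key <- paste(samples$probe_i, samples$probe_j)
  pkey <- paste(pairs$probe_i, pairs$probe_j)
  pairs$n <- as.integer(table(factor(key, levels = pkey)))
  med <- tapply(samples$dist_um, factor(key, levels = pkey), stats::median)
  pairs$median_um <- as.numeric(med)
  list(samples = samples, summary = pairs)
}
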