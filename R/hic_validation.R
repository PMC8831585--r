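#' Construct or read a binned Hi-C contact matrix
#'
#' The contact file is a plain tab-separated table `chrom, bin_start_i,
#' bin_start_j, frequency` (100 kb bin semantics by default); a dense-matrix
#' reader is also provided. The matrix is stored dense and symmetric.
#'
#' @param chrom Chromosome name.
#' @param bin_size Bin size in bp.
#' @param mat Symmetric non-negative matrix of contact frequencies.
#' @param bin_starts Genomic start of each bin (bp); defaults to
#'   `0, bin_size, ...`.
#' @return A `contact_matrix`.
#' @export
contact_matrix <- function(chrom, bin_size, mat, bin_starts = NULL) {
  stopifnot(bin_size > 0, nrow(mat) == ncol(mat), all(mat >= 0, na.rm = TRUE))
  if (max(abs(mat - t(mat)), na.rm = TRUE) > 1e-8) {
    stop("contact matrix must be symmetric")
  }
  if (is.null(bin_starts)) bin_starts <- (seq_len(nrow(mat)) - 1) * bin_size
  structure(list(chrom = chrom, bin_size = bin_size, mat = mat,
                 bin_starts = bin_starts), class = "contact_matrix")
}

#' @rdname contact_matrix
#' @param path Contact file path.
#' @param format `"pairs"` (sparse 4-column TSV) or `"dense"` (matrix TSV).
#' @export
read_contact_matrix <- function(path, bin_size = 1e5, format = c("pairs", "dense"),
                                chrom = NULL) {
  format <- match.arg(format)
  if (format == "dense") {
    mat <- as.matrix(utils::read.table(path, sep = "\t"))
    dimnames(mat) <- NULL
    return(contact_matrix(chrom %||% "unknown", bin_size, mat))
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start_i", "start_j", "freq"),
                           stringsAsFactors = FALSE)
  if (is.null(chrom)) chrom <- tab$chrom[1]
  tab <- tab[tab$chrom == chrom, , drop = FALSE]
  starts <- sort(unique(c(tab$start_i, tab$start_j)))
  n_bins <- max(starts) / bin_size + 1
  bin_starts <- (seq_len(n_bins) - 1) * bin_size
  mat <- matrix(0, n_bins, n_bins)
  i <- tab$start_i / bin_size + 1
  j <- tab$start_j / bin_size + 1
  mat[cbind(i, j)] <- tab$freq
  mat[cbind(j, i)] <- tab$freq
  contact_matrix(chrom, bin_size, mat, bin_starts)
}

#' @rdname contact_matrix
#' @param x A `contact_matrix`.
#' @export
write_contact_matrix <- function(x, path) {
  idx <- which(upper.tri(x$mat, diag = TRUE) & x$mat != 0, arr.ind = TRUE)
  tab <- data.frame(chrom = x$chrom,
                    start_i = x$bin_starts[idx[, 1]],
                    start_j = x$bin_starts[idx[, 2]],
                    freq = x$mat[idx])
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an eigenvector (compartment) track
#'
#' bedGraph-like TSV with columns `chrom, start, end, value`. The sign
#' convention (which sign denotes the A compartment) is arbitrary in Hi-C
#' eigenvector extraction and must be declared.
#'
#' @param path Track file.
#' @param sign_convention `"positive_A"` (default) or `"negative_A"`.
#' @return An `eigenvector_track`: data.frame with class attributes.
#' @export
read_eigenvector <- function(path, sign_convention = c("positive_A",
                                                       "negative_A")) {
  sign_convention <- match.arg(sign_convention)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "value"),
                           stringsAsFactors = FALSE)
  eigenvector_track(tab, sign_convention)
}

#' @rdname read_eigenvector
#' @param tab data.frame with `chrom, start, end, value`.
#' @export
eigenvector_track <- function(tab, sign_convention = c("positive_A",
                                                       "negative_A")) {
  sign_convention <- match.arg(sign_convention)
  structure(tab, sign_convention = sign_convention,
            class = c("eigenvector_track", "data.frame"))
}

#' Call A/B compartments from an eigenvector track
#'
#' Bins with |eigenvector| at or below `min_abs` are left unassigned
#' (uncertain regions); the rest are labelled by sign according to the
#' declared convention.
#'
#' @param track An `eigenvector_track`.
#' @param min_abs Minimal absolute eigenvector value (default 0.01).
#' @return The track with an added `compartment` column ("A", "B",
#'   "unassigned").
#' @export
ab_compartments <- function(track, min_abs = 0.01) {
  conv <- attr(track, "sign_convention")
  if (is.null(conv)) stop("track has no declared sign convention")
  a_sign <- if (conv == "positive_A") 1 else -1
  lab <- rep("unassigned", nrow(track))
  lab[track$value * a_sign > 0 & abs(track$value) > min_abs] <- "A"
  lab[track$value * a_sign < 0 & abs(track$value) > min_abs] <- "B"
  track$compartment <- lab
  track
}

# compartment label of each probe (by midpoint bin)
probe_compartments <- function(track, scheme) {
  track <- if ("compartment" %in% names(track)) track else
    ab_compartments(track)
  mids <- probe_midpoints(scheme)
  vapply(seq_along(mids), function(i) {
    sel <- track$chrom == scheme$probes$chrom[i] & track$start <= mids[i] &
      track$end > mids[i]
    if (!any(sel)) return("unassigned")
    track$compartment[which(sel)[1]]
  }, character(1)) -> lab
  stats::setNames(lab, names(mids))
}

#' Hi-C contact frequency of every probe pair
#'
#' Looks up the contact frequency at the bin pair containing the two probe
#' midpoints, for all unordered probe pairs of the scheme (120 for the chr2
#' design).
#'
#' @param matrix A `contact_matrix`.
#' @param scheme A `mifish_scheme` on the same chromosome.
#' @return The [probe_pair_table()] with an added `hic_freq` column.
#' @export
probe_pair_contact_freq <- function(matrix, scheme) {
  stopifnot(inherits(matrix, "contact_matrix"))
  if (!all(scheme$probes$chrom == matrix$chrom)) {
    stop("probes not on contact matrix chromosome")
  }
  mids <- probe_midpoints(scheme)
  bin <- floor(mids / matrix$bin_size) + 1
  if (any(bin < 1 | bin > nrow(matrix$mat))) {
    stop("probe midpoint outside contact matrix range")
  }
  pairs <- probe_pair_table(scheme)
  pairs$hic_freq <- matrix$mat[cbind(bin[pairs$probe_i], bin[pairs$probe_j])]
  pairs
}

#' FISH contact frequency per probe pair
#'
#' Fraction of per-cluster 3D distances at or below the contact threshold
#' (1 um by default: dots 1 um or less apart count as being in contact).
#' Pairs without samples are omitted (NA).
#'
#' @param distances Output of [pairwise_distance_matrix()] (or its `samples`
#'   data.frame).
#' @param threshold_um Contact-calling threshold (inclusive).
#' @return data.frame `probe_i, probe_j, n, contact_freq`.
#' @export
fish_contact_frequency <- function(distances, threshold_um = 1.0) {
  samples <- if (is.data.frame(distances)) distances else distances$samples
  key <- interaction(samples$probe_i, samples$probe_j, drop = TRUE)
  agg <- data.frame(
    probe_i = tapply(samples$probe_i, key, `[`, 1),
    probe_j = tapply(samples$probe_j, key, `[`, 1),
    n = as.integer(tapply(samples$dist_um, key, length)),
    contact_freq = as.numeric(tapply(samples$dist_um <= threshold_um, key,
                                     mean)),
    stringsAsFactors = FALSE)
  rownames(agg) <- NULL
  agg
}

#' Correlate a FISH per-pair statistic with Hi-C contact frequencies
#'
#' @param x,y Paired numeric vectors (e.g. per-pair median distance and
#'   Hi-C frequency); pairs with missing values are dropped and counted.
#' @return List with `pearson`, `spearman`, `n`, `n_dropped`.
#' @export
correlate_fish_hic <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    stop("correlation undefined for constant input")
  }
  list(pearson = stats::cor(x[ok], y[ok], method = "pearson"),
       spearman = stats::cor(x[ok], y[ok], method = "spearman"),
       n = sum(ok), n_dropped = sum(!ok))
}

#' Lamina distance by compartment
#'
#' Per-probe median normalized lamina distance and the A-minus-B summary:
#' positive values mean A-compartment probes lie farther from the lamina
#' (more interior) than B-compartment probes.
#'
#' @param dots data.frame with `probe_id` and `lamina_norm`.
#' @param compartment_labels Named character vector probe_id -> "A"/"B".
#' @return List with `per_probe` (probe_id, compartment, n, median_norm) and
#'   `summary` (median over A probes minus median over B probes; NA with a
#'   `comparison_defined = FALSE` flag when either side is empty).
#' @export
lamina_by_compartment <- function(dots, compartment_labels) {
  dots <- dots[!is.na(dots$lamina_norm), , drop = FALSE]
  per_probe <- data.frame(
    probe_id = names(compartment_labels),
    compartment = unname(compartment_labels),
    stringsAsFactors = FALSE)
  per_probe$n <- vapply(per_probe$probe_id, function(p) {
    sum(dots$probe_id == p)
  }, integer(1))
  per_probe$median_norm <- vapply(per_probe$probe_id, function(p) {
    v <- dots$lamina_norm[dots$probe_id == p]
    if (length(v) == 0) NA_real_ else stats::median(v)
  }, numeric(1))
  med_a <- per_probe$median_norm[per_probe$compartment == "A"]
  med_b <- per_probe$median_norm[per_probe$compartment == "B"]
  defined <- length(stats::na.omit(med_a)) > 0 &&
    length(stats::na.omit(med_b)) > 0
  list(per_probe = per_probe,
       summary = if (defined) {
         stats::median(med_a, na.rm = TRUE) - stats::median(med_b, na.rm = TRUE)
       } else NA_real_,
       comparison_defined = defined)
}

#' Build a matched synthetic contact matrix from distance samples
#'
#' Converts per-pair FISH distance samples into a contact matrix at the
#' probes' bins: the contact frequency of a bin pair is the fraction of
#' structures in which the probe pair was closer than `threshold_um`. Used to
#' validate the FISH/Hi-C comparison machinery on simulated data.
#'
#' @param distances Output of [pairwise_distance_matrix()].
#' @param scheme A `mifish_scheme`.
#' @param threshold_um Contact threshold.
#' @param bin_size Bin size (bp).
#' @return A `contact_matrix` labelled synthetic in its `chrom` field suffix.
#' @export
contact_matrix_from_distances <- function(distances, scheme,
                                          threshold_um = 1.0,
                                          bin_size = 1e5) {
  freq <- fish_contact_frequency(distances, threshold_um)
  mids <- probe_midpoints(scheme)
  n_bins <- floor(max(mids) / bin_size) + 1
  mat <- matrix(0, n_bins, n_bins)
  bi <- floor(mids[freq$probe_i] / bin_size) + 1
  bj <- floor(mids[freq$probe_j] / bin_size) + 1
  mat[cbind(bi, bj)] <- freq$contact_freq
  mat[cbind(bj, bi)] <- freq$contact_freq
  diag(mat) <- 1
  contact_matrix(scheme$probes$chrom[1], bin_size, mat)
}
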