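#' Fluorescent dyes resolved by the miFISH imaging setup
#'
#' Returns the table of the six FISH dyes plus the DNA stain channel, with
#' their dataset channel names, emission wavelengths and dichroic-mirror
#' grouping. Channels sharing a multi-band dichroic cube can be imaged without
#' moving optical components, which determines the co-localization threshold
#' used during decoding (see [colocalization_threshold()]).
#'
#' Channel naming follows the deposited-dataset dialect: `a488` = AF488,
#' `tmr` = AT542, `a594` = AF594, `cy5` = AT647N, `a700` = AF700,
#' `ir800` = AF790, `dapi` = Hoechst DNA stain.
#'
#' @return A data.frame with columns `channel`, `dye`, `emission_nm`,
#'   `dichroic_group`.
#' @export
mifish_dyes <- function() {
  data.frame(
    channel = c("dapi", "a488", "tmr", "a594", "cy5", "a700", "ir800"),
    dye = c("Hoechst", "AF488", "AT542", "AF594", "AT647N", "AF700", "AF790"),
    emission_nm = c(447, 525, 562, 617, 664, 723, 814),
    # cube 1: dapi/tmr/cy5/ir800 multi-band polychroic; cube 2: a594/a700;
    # cube 3: a488 single-band dichroic
    dichroic_group = c(1L, 3L, 1L, 2L, 1L, 2L, 1L),
    stringsAsFactors = FALSE
  )
}

#' @rdname mifish_dyes
#' @param channel Channel name(s).
#' @return `dichroic_group()`: integer group label(s).
#' @export
dichroic_group <- function(channel) {
  dyes <- mifish_dyes()
  idx <- match(channel, dyes$channel)
  if (anyNA(idx)) {
    stop("unknown channel(s): ", paste(channel[is.na(idx)], collapse = ", "))
  }
  dyes$dichroic_group[idx]
}

fish_channels <- function() setdiff(mifish_dyes()$channel, "dapi")

dye_pair_key <- function(a, b) {
  paste(sort(c(a, b)), collapse = "|")
}

new_scheme <- function(probes) {
  stopifnot(is.data.frame(probes))
  required <- c("probe_id", "chrom", "start", "end", "dye1", "dye2")
  if (!all(required %in% names(probes))) {
    stop("probe table must have columns ", paste(required, collapse = ", "))
  }
  known <- fish_channels()
  bad <- setdiff(stats::na.omit(c(probes$dye1, probes$dye2)), known)
  if (length(bad) > 0) stop("unknown dye(s): ", paste(bad, collapse = ", "))
  if (any(probes$end <= probes$start)) stop("probe end must exceed start")
  dual <- probes[!is.na(probes$dye2), , drop = FALSE]
  if (any(dual$dye1 == dual$dye2)) stop("dual-color probe with |dyes| < 2")
  dual_pairs <- character(0)
  if (nrow(dual) > 0) {
    keys <- mapply(dye_pair_key, dual$dye1, dual$dye2)
    if (anyDuplicated(keys)) stop("duplicate dye pair in scheme")
    dual_pairs <- stats::setNames(dual$probe_id, keys)
  }
  probes <- probes[order(probes$chrom, probes$start), , drop = FALSE]
  rownames(probes) <- NULL
  structure(list(probes = probes, dual_pairs = dual_pairs),
            class = "mifish_scheme")
}

#' @export
print.mifish_scheme <- function(x, ...) {
  n_dual <- sum(!is.na(x$probes$dye2))
  cat(sprintf("miFISH color scheme: %d probes (%d dual-color, %d single-color)\n",
              nrow(x$probes), n_dual, nrow(x$probes) - n_dual))
  print(x$probes)
  invisible(x)
}

#' Build the 16-probe chromosome 2 color scheme
#'
#' Constructs the default combinatorial coding design: 16 probes along the
#' chr2 q-arm, 11 of them spaced 3 Mb apart (midpoints 55-85 Mb) and 5 further
#' probes at 20 Mb steps, each spanning 66 kb. Ten probes are dual-color and
#' use exactly the ten unordered pairs of the five dyes
#' \{a488, tmr, a594, cy5, a700\}; the remaining six are single-color, one per
#' dye (ir800 appears only as a single-color probe). The nominal coordinates
#' are synthetic defaults; a probe-definition file overrides them.
#'
#' @param coords_file Optional path to a BED-like probe definition file with
#'   columns `chrom, start, end, probe_id, dye1[, dye2]` (tab-separated,
#'   optional header, `#` comments ignored).
#' @return A `mifish_scheme`: list with `probes` (data.frame, genomic order)
#'   and `dual_pairs` (named map from sorted dye pair to probe id).
#' @examples
#' scheme <- build_chr2_scheme()
#' nrow(scheme$probes)      # 16
#' length(scheme$dual_pairs) # 10
#' @export
build_chr2_scheme <- function(coords_file = NULL) {
  if (!is.null(coords_file)) {
    return(read_probe_file(coords_file))
  }
  mid_mb <- c(seq(55, 85, by = 3), seq(105, 185, by = 20))
  span <- 66e3
  n <- length(mid_mb) # 16
  # single-color probes spread along the design, one per dye
  single_idx <- c(1L, 4L, 7L, 10L, 13L, 16L)
  single_dye <- c("a488", "tmr", "a594", "cy5", "a700", "ir800")
  dual_dyes <- c("a488", "tmr", "a594", "cy5", "a700")
  pairs <- utils::combn(dual_dyes, 2)
  dual_idx <- setdiff(seq_len(n), single_idx)
  dye1 <- dye2 <- rep(NA_character_, n)
  dye1[single_idx] <- single_dye
  dye1[dual_idx] <- pairs[1, ]
  dye2[dual_idx] <- pairs[2, ]
  mid <- mid_mb * 1e6
  probes <- data.frame(
    probe_id = sprintf("chr2_p%02d", seq_len(n)),
    chrom = "chr2",
    start = as.numeric(mid - span / 2),
    end = as.numeric(mid + span / 2),
    dye1 = dye1,
    dye2 = dye2,
    stringsAsFactors = FALSE
  )
  new_scheme(probes)
}

#' Read a BED-like probe definition file
#'
#' @param path Tab-separated file with columns
#'   `chrom, start, end, probe_id, dye1[, dye2]`; a header line is detected
#'   automatically and `#` comment lines are skipped.
#' @return A `mifish_scheme`.
#' @export
read_probe_file <- function(path) {
  if (!file.exists(path)) stop("probe file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty probe file: ", path)
  first <- strsplit(lines[[1]], "\t")[[1]]
  if (length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2])))) {
    lines <- lines[-1] # header
  }
  if (length(lines) == 0) stop("probe file has no data rows: ", path)
  fields <- strsplit(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 5 | nf > 6)) {
    stop("malformed probe file: expected 5 or 6 tab-separated columns")
  }
  probes <- data.frame(
    probe_id = vapply(fields, `[`, "", 4),
    chrom = vapply(fields, `[`, "", 1),
    start = as.numeric(vapply(fields, `[`, "", 2)),
    end = as.numeric(vapply(fields, `[`, "", 3)),
    dye1 = vapply(fields, `[`, "", 5),
    dye2 = vapply(fields, function(f) if (length(f) >= 6) f[6] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
  probes$dye2[!is.na(probes$dye2) & !nzchar(probes$dye2)] <- NA_character_
  if (anyNA(probes$start) || anyNA(probes$end)) {
    stop("malformed probe file: non-numeric coordinates")
  }
  new_scheme(probes)
}

#' Probe genomic midpoints
#'
#' Probe position is the midpoint of its (0-based half-open) genomic interval.
#'
#' @param scheme A `mifish_scheme`.
#' @return Named numeric vector of midpoints (bp).
#' @export
probe_midpoints <- function(scheme) {
  stats::setNames((scheme$probes$start + scheme$probes$end) / 2,
                  scheme$probes$probe_id)
}

#' Expected dot counts per channel
#'
#' For a diploid nucleus (two alleles of the target chromosome) the expected
#' number of FISH dots in a channel is the number of probes carrying that dye
#' times the number of alleles. For the default chr2 design this yields 10
#' dots in each of the five dyes used in dual-color combinations and 2 dots
#' in the AF790 (`ir800`) channel.
#'
#' @param scheme A `mifish_scheme`.
#' @param n_alleles Number of alleles per nucleus (>= 1).
#' @return Named numeric vector of expected dot counts per channel.
#' @examples
#' expected_channel_counts(build_chr2_scheme(), 2)
#' @export
expected_channel_counts <- function(scheme, n_alleles) {
  stopifnot(inherits(scheme, "mifish_scheme"))
  if (length(n_alleles) != 1 || n_alleles < 1) stop("n_alleles must be >= 1")
  channels <- fish_channels()
  counts <- vapply(channels, function(ch) {
    sum(scheme$probes$dye1 == ch, na.rm = TRUE) +
      sum(scheme$probes$dye2 == ch, na.rm = TRUE)
  }, numeric(1))
  counts * n_alleles
}

#' All unordered probe pairs with genomic separations
#'
#' @param scheme A `mifish_scheme` with at least two probes.
#' @return data.frame with columns `probe_i`, `probe_j` (i before j in genomic
#'   order) and `genomic_distance` (bp, between interval midpoints). The
#'   default chr2 design yields choose(16, 2) = 120 pairs.
#' @export
probe_pair_table <- function(scheme) {
  stopifnot(inherits(scheme, "mifish_scheme"))
  mids <- probe_midpoints(scheme)
  if (length(mids) < 2) stop("need at least 2 probes")
  idx <- utils::combn(length(mids), 2)
  data.frame(
    probe_i = names(mids)[idx[1, ]],
    probe_j = names(mids)[idx[2, ]],
    genomic_distance = abs(mids[idx[2, ]] - mids[idx[1, ]]),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# dyes carried by each probe, as a list of character vectors
probe_dye_list <- function(scheme) {
  mapply(function(d1, d2) {
    if (is.na(d2)) d1 else c(d1, d2)
  }, scheme$probes$dye1, scheme$probes$dye2, SIMPLIFY = FALSE)
}
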