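# shared fixtures, all generated in code

# a minimal probe file with the given rows (tab-separated BED-like dialect)
write_probe_fixture <- function(lines, header = FALSE) {
  path <- tempfile(fileext = ".tsv")
  if (header) lines <- c("chrom\tstart\tend\tprobe_id\tdye1\tdye2", lines)
  writeLines(lines, path)
  path
}

tiny_scheme <- function() {
  build_chr2_scheme(write_probe_fixture(c(
    "chr2\t1000000\t1066000\tpA\ta488\ttmr",
    "chr2\t4000000\t4066000\tpB\tcy5",
    "chr2\t24000000\t24066000\tpC\ta594\ta700"
  )))
}

# compact scene parameters for fast rendered tests (small nucleus, small
# stack); geometry scaled down but same voxel size
small_scene <- function(n_cells = 1, seed = 1, ...) {
  simulate_structures(
    build_chr2_scheme(), n_cells, seed = seed,
    nucleus_semiaxes_nm = c(4200, 3800, 2000),
    territory_radius_nm = 1900, min_allele_separation_nm = 4600,
    stack_dim = c(90, 90, 30), ...)
}

# dot table with exactly one well-separated dot per probe per allele, built
# directly (no imaging); positions on a coarse jittered grid so that no two
# dots of any channel fall within the split/coloc radii
grid_cluster_dots <- function(scheme, spacing_nm = 1500, seed = 1,
                              origin_nm = c(10000, 10000, 3000)) {
  set.seed(seed)
  probes <- scheme$probes
  n <- nrow(probes)
  side <- ceiling(sqrt(n))
  rows <- NULL
  for (i in seq_len(n)) {
    gx <- ((i - 1) %% side) * spacing_nm + origin_nm[1]
    gy <- ((i - 1) %/% side) * spacing_nm + origin_nm[2]
    gz <- origin_nm[3] + (i %% 3) * 400
    dyes <- c(probes$dye1[i], probes$dye2[i])
    dyes <- dyes[!is.na(dyes)]
    ph <- if (length(dyes) == 1) 30000 else 15000
    for (ch in dyes) {
      rows <- rbind(rows, data.frame(
        channel = ch, x_nm = gx + rnorm(1, 0, 15), y_nm = gy + rnorm(1, 0, 15),
        z_nm = gz + rnorm(1, 0, 15),
        intensity = ph * (1 + rnorm(1, 0, 0.05)),
        probe_id = probes$probe_id[i], stringsAsFactors = FALSE))
    }
  }
  rows$dot_id <- seq_len(nrow(rows))
  rows
}

# truth table matching grid_cluster_dots (mean position per probe)
grid_cluster_truth <- function(dots) {
  agg <- stats::aggregate(dots[, c("x_nm", "y_nm", "z_nm")],
                          by = list(probe_id = dots$probe_id), FUN = mean)
  agg
}
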