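#' Dot table of a scene's ground truth
#'
#' Converts a simulated scene into the dot-table form produced by spot
#' detection (one row per detectable dye-dot), optionally adding localization
#' jitter and intensity noise. Useful for exercising clustering, decoding and
#' geometry directly on ground truth, without rendering and re-detecting
#' images. The true `probe_id` and `allele` columns are retained for scoring.
#'
#' @param scene A `mifish_scene`.
#' @param localization_sd_nm Isotropic Gaussian localization error sd (nm).
#' @param intensity_cv Coefficient of variation of measured dot intensity.
#' @param seed Optional seed.
#' @return data.frame: `dot_id`, `channel`, `x_nm`, `y_nm`, `z_nm`,
#'   `intensity`, `probe_id`, `allele`.
#' @export
scene_dot_table <- function(scene, localization_sd_nm = 20,
                            intensity_cv = 0.1, seed = NULL) {
  stopifnot(inherits(scene, "mifish_scene"))
  if (!is.null(seed)) set.seed(seed)
  tr <- scene$truth[scene$truth$present, , drop = FALSE]
  n <- nrow(tr)
  out <- data.frame(
    dot_id = seq_len(n), channel = tr$channel,
    x_nm = tr$x_nm + stats::rnorm(n, 0, localization_sd_nm),
    y_nm = tr$y_nm + stats::rnorm(n, 0, localization_sd_nm),
    z_nm = tr$z_nm + stats::rnorm(n, 0, localization_sd_nm),
    intensity = pmax(tr$photons * (1 + stats::rnorm(n, 0, intensity_cv)), 1),
    probe_id = tr$probe_id, allele = tr$allele,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write scene ground truth as CSV
#'
#' @param scenes List of `mifish_scene` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scene_truth <- function(scenes, path) {
  tab <- do.call(rbind, lapply(scenes, function(s) {
    cbind(cell_id = s$cell_id, s$truth,
          cell_cycle = s$nucleus$cell_cycle[1])
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Match homolog clusters to ground-truth alleles
#'
#' Pairs each cluster centroid with the nearest true-allele centroid of the
#' scene (the mean of the allele's true dot positions).
#'
#' @param centroids `centroids` from [cluster_homologs()] (um).
#' @param scene The `mifish_scene` the dots came from.
#' @return Integer vector: allele index per cluster_id.
#' @export
match_clusters_to_alleles <- function(centroids, scene) {
  tru <- scene$truth
  tcent <- t(vapply(1:2, function(a) {
    sel <- tru$allele == a
    c(mean(tru$x_nm[sel]), mean(tru$y_nm[sel]), mean(tru$z_nm[sel])) / 1000
  }, numeric(3)))
  vapply(seq_len(nrow(centroids)), function(i) {
    p <- as.numeric(centroids[i, c("x_um", "y_um", "z_um")])
    which.min(colSums((t(tcent) - p)^2))
  }, integer(1))
}
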