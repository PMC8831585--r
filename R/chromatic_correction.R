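# 3D distance in lateral-pixel units: z (axial px) scaled by voxel anisotropy
px_dist3d <- function(dx, dy, dz, z_aniso = 200 / 130) {
  sqrt(dx^2 + dy^2 + (dz * z_aniso)^2)
}

#' Match beads between a reference and another channel
#'
#' Mutual-nearest-neighbor matching of localized bead dots within a radius;
#' each dot appears in at most one pair.
#'
#' @param ref_dots,other_dots data.frames of localized dots with columns
#'   `x`, `y`, `z` (px; z in axial px).
#' @param max_radius_px Match radius in lateral-pixel units (z scaled by the
#'   voxel anisotropy).
#' @param z_aniso Axial/lateral voxel size ratio (default 200/130).
#' @return data.frame of pairs: `x_ref, y_ref, z_ref, x, y, z, dist_px`.
#' @export
match_beads <- function(ref_dots, other_dots, max_radius_px = 5,
                        z_aniso = 200 / 130) {
  n <- nrow(ref_dots); m <- nrow(other_dots)
  if (n == 0 || m == 0) stop("no dots to match")
  D <- outer(ref_dots$x, other_dots$x, `-`)^2 +
    outer(ref_dots$y, other_dots$y, `-`)^2 +
    (outer(ref_dots$z, other_dots$z, `-`) * z_aniso)^2
  D <- sqrt(D)
  nn_ref <- apply(D, 1, which.min)  # for each ref, nearest other
  nn_other <- apply(D, 2, which.min)
  keep <- which(nn_other[nn_ref] == seq_len(n) &
                  D[cbind(seq_len(n), nn_ref)] <= max_radius_px)
  if (length(keep) == 0) stop("zero bead matches within max_radius_px")
  j <- nn_ref[keep]
  data.frame(
    x_ref = ref_dots$x[keep], y_ref = ref_dots$y[keep],
    z_ref = ref_dots$z[keep],
    x = other_dots$x[j], y = other_dots$y[j], z = other_dots$z[j],
    dist_px = D[cbind(keep, j)]
  )
}

#' Fit the per-channel chromatic aberration model
#'
#' Least-squares fit of the displacement between a channel and the reference
#' channel (AT647N, `cy5`): a 2nd-order polynomial over the lateral plane
#' (coefficients 1, x, y, x^2, x*y, y^2, fitted per axis) and a constant
#' axial shift (the mean axial displacement).
#'
#' @param pairs Either a data.frame of matched pairs for one channel (columns
#'   as returned by [match_beads()]) or a named list of such data.frames, one
#'   per channel.
#' @param degree Polynomial degree (only 2 supported).
#' @return An `aberration_model`: per channel the coefficient vectors
#'   `dx`, `dy`, scalar `dz`, `n_beads`, and residual `mse_px` (squared px).
#' @export
fit_aberration <- function(pairs, degree = 2) {
  if (degree != 2) stop("only degree 2 is supported")
  if (is.data.frame(pairs)) pairs <- list(channel = pairs)
  fit_one <- function(p) {
    if (nrow(p) < 6) stop("need at least 6 bead pairs per channel")
    X <- poly2_design(p$x_ref, p$y_ref)
    if (qr(X)$rank < 6) stop("rank-deficient bead layout (collinear beads)")
    dx <- p$x - p$x_ref
    dy <- p$y - p$y_ref
    dz <- p$z - p$z_ref
    cx <- stats::lm.fit(X, dx)
    cy <- stats::lm.fit(X, dy)
    dz_hat <- mean(dz)
    res <- cx$residuals^2 + cy$residuals^2 +
      ((dz - dz_hat) * (200 / 130))^2
    list(dx = unname(cx$coefficients), dy = unname(cy$coefficients),
         dz = dz_hat, n_beads = nrow(p), mse_px = mean(res),
        se_dx = coef_se(X, cx$residuals), se_dy = coef_se(X, cy$residuals))
  }
  models <- lapply(pairs, fit_one)
  models$cy5 <- list(dx = rep(0, 6), dy = rep(0, 6), dz = 0,
                     n_beads = NA_integer_, mse_px = 0,
                     se_dx = rep(0, 6), se_dy = rep(0, 6))
  structure(list(reference_channel = "cy5", channels = models),
            class = "aberration_model")
}

# standard errors of least-squares coefficients
coef_se <- function(X, residuals) {
  n <- nrow(X); p <- ncol(X)
  s2 <- sum(residuals^2) / max(n - p, 1)
  sqrt(diag(s2 * solve(crossprod(X))))
}

#' @export
print.aberration_model <- function(x, ...) {
  cat("Chromatic aberration model (reference:", x$reference_channel, ")\n")
  for (ch in names(x$channels)) {
    m <- x$channels[[ch]]
    cat(sprintf("  %-6s dz=%+.3f px  residual MSE=%.4f px^2  n=%s\n",
                ch, m$dz, m$mse_px, m$n_beads))
  }
  invisible(x)
}

#' Apply an aberration correction to dot coordinates
#'
#' Subtracts the model-predicted (dx, dy, dz) displacement from each
#' non-reference-channel dot, bringing all channels into the reference frame.
#' The paper-equivalent operation on images (resampling) is applied here in
#' coordinate space, which is exact for point data.
#'
#' @param dots data.frame with columns `x`, `y`, `z` (px) and `channel`.
#' @param model An `aberration_model`.
#' @param voxel_size_nm If the dots carry `x_nm/y_nm/z_nm` columns they are
#'   updated using this voxel size.
#' @return The corrected dots.
#' @export
apply_correction <- function(dots, model, voxel_size_nm = c(130, 130, 200)) {
  stopifnot(inherits(model, "aberration_model"))
  for (ch in unique(dots$channel)) {
    if (ch == model$reference_channel) next
    if (!ch %in% names(model$channels)) stop("channel not in model: ", ch)
    m <- model$channels[[ch]]
    sel <- dots$channel == ch
    # the model maps reference coordinates to displacements; invert the
    # forward map x_obs = x_ref + f(x_ref) by fixed-point iteration (the
    # displacements are small, so three sweeps reach machine-level accuracy)
    xr <- dots$x[sel]
    yr <- dots$y[sel]
    for (it in 1:3) {
      X <- poly2_design(xr, yr)
      xr <- dots$x[sel] - as.numeric(X %*% m$dx)
      yr <- dots$y[sel] - as.numeric(X %*% m$dy)
    }
    dots$x[sel] <- xr
    dots$y[sel] <- yr
    dots$z[sel] <- dots$z[sel] - m$dz
  }
  if (all(c("x_nm", "y_nm", "z_nm") %in% names(dots))) {
    dots$x_nm <- dots$x * voxel_size_nm[1]
    dots$y_nm <- dots$y * voxel_size_nm[2]
    dots$z_nm <- dots$z * voxel_size_nm[3]
  }
  dots
}

#' Registration error before and after correction
#'
#' Mean squared pair distance between matched beads before correction (3D)
#' and after applying the model (2D lateral and 3D), in pixel units with the
#' axial coordinate scaled by the voxel anisotropy.
#'
#' @param pairs Matched pairs for one channel ([match_beads()] output).
#' @param model An `aberration_model`.
#' @param channel The channel the pairs belong to.
#' @return Named numeric: `mse_3d_before`, `mse_2d_after`, `mse_3d_after`
#'   (squared px).
#' @export
correction_mse <- function(pairs, model, channel) {
  before <- mean(px_dist3d(pairs$x - pairs$x_ref, pairs$y - pairs$y_ref,
                           pairs$z - pairs$z_ref)^2)
  dots <- data.frame(x = pairs$x, y = pairs$y, z = pairs$z,
                     channel = channel, stringsAsFactors = FALSE)
  corr <- apply_correction(dots, model)
  d2 <- (corr$x - pairs$x_ref)^2 + (corr$y - pairs$y_ref)^2
  d3 <- d2 + ((corr$z - pairs$z_ref) * (200 / 130))^2
  c(mse_3d_before = before, mse_2d_after = mean(d2), mse_3d_after = mean(d3))
}

#' Serialize / restore an aberration model
#'
#' The model is stored as a small JSON-like YAML text file recording, per
#' channel, the lateral polynomial coefficients, the axial shift and the
#' number of beads used.
#'
#' @param model An `aberration_model`.
#' @param path Output file.
#' @return `write_aberration_model()` returns `path` invisibly;
#'   `read_aberration_model()` returns the restored model.
#' @export
write_aberration_model <- function(model, path) {
  obj <- list(reference_channel = model$reference_channel,
              channels = lapply(model$channels, function(m) {
                list(dx = m$dx, dy = m$dy, dz = m$dz,
                     n_beads = m$n_beads, mse_px = m$mse_px)
              }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_aberration_model
#' @export
read_aberration_model <- function(path) {
  obj <- yaml::read_yaml(path)
  channels <- lapply(obj$channels, function(m) {
    list(dx = as.numeric(m$dx), dy = as.numeric(m$dy), dz = m$dz,
         n_beads = m$n_beads, mse_px = m$mse_px,
         se_dx = rep(NA_real_, 6), se_dy = rep(NA_real_, 6))
  })
  structure(list(reference_channel = obj$reference_channel,
                 channels = channels),
            class = "aberration_model")
}
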