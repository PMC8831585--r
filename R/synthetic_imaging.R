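#' Construct a voxel stack
#'
#' One channel's 3D image with anisotropic voxel size. Arrays use R's
#' column-major layout with dim (ny, nx, nz); the continuous coordinate system
#' is in pixels with the center of voxel (i, j, k) at (x = j, y = i, z = k),
#' 1-based, so physical coordinates are `px * voxel_size_nm`.
#'
#' @param data 3D numeric array, dim (ny, nx, nz); non-negative intensities.
#' @param channel Channel name (`dapi` or a dye channel).
#' @param voxel_size_nm Voxel size c(x, y, z) in nm (default 130, 130, 200).
#' @return A `voxel_stack` object.
#' @export
voxel_stack <- function(data, channel, voxel_size_nm = c(130, 130, 200)) {
  stopifnot(length(dim(data)) == 3, all(data >= 0))
  structure(list(data = data, channel = channel,
                 voxel_size_nm = as.numeric(voxel_size_nm)),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("voxel_stack [%s]: %d x %d x %d voxels, %.0f x %.0f x %.0f nm\n",
              x$channel, d[2], d[1], d[3],
              x$voxel_size_nm[1], x$voxel_size_nm[2], x$voxel_size_nm[3]))
  invisible(x)
}

# reflect a point into the unit ball of normalized ellipsoid coordinates
reflect_inside <- function(u) {
  rho <- sqrt(sum(u^2))
  while (rho > 1) {
    if (rho < 2) {
      u <- u * (2 - rho) / rho
    } else {
      u <- u / rho * 0.99
    }
    rho <- sqrt(sum(u^2))
  }
  u
}

#' Simulate ground-truthed chromatin-chain scenes
#'
#' Generates diploid nuclei with two allele clusters of the probed chromosome.
#' Each nucleus is an ellipsoid; within each allele, successive loci of the
#' color scheme are displaced by isotropic Gaussian steps whose standard
#' deviation grows with genomic gap as `step_scale_nm * gap_Mb^nu` (a random
#' polymer-walk scaling; nu = 0.5 corresponds to an ideal chain), reflected to
#' stay inside the nucleus. Probes labelled `B` in `compartments` are pushed
#' toward the nuclear lamina by `lamina_bias`, emulating the peripheral
#' positioning of B-compartment chromatin.
#'
#' Dual-color probes contribute one true dot per dye at the same physical
#' position; single-color probes carry twice the per-dye photon count (twice
#' as many labelled oligos). `detection_efficiency` drops individual dye-dots
#' at random (hybridization efficiency); `coloc_jitter_nm` adds an isotropic
#' Gaussian offset per dye-dot, emulating residual chromatic registration
#' error.
#'
#' Each allele's chain is confined to a chromosome-territory sphere of radius
#' `territory_radius_nm` around its anchor, and the two territories are kept
#' at least `min_allele_separation_nm` apart, emulating the spatially
#' distinct homolog territories that make homolog clustering possible.
#'
#' @param scheme A `mifish_scheme`.
#' @param n_cells Number of cells (>= 1).
#' @param step_scale_nm Chain step scale in nm per Mb^nu (default 550).
#' @param nu Chain exponent in (0, 1] (default 0.5).
#' @param territory_radius_nm Chromosome territory radius (default 3200).
#' @param compartments Optional named character vector probe_id -> "A"/"B".
#' @param lamina_bias Fraction of the remaining radial range that B probes are
#'   moved outward (default 0.4 when `compartments` given).
#' @param g1_fraction Fraction of cells in G1 (others G2, rendered at 2x DNA
#'   intensity).
#' @param nucleus_semiaxes_nm Nominal ellipsoid semi-axes c(x, y, z) in nm.
#' @param stack_dim Rendered stack dimension c(ny, nx, nz) in voxels.
#' @param voxel_size_nm Voxel size c(x, y, z) in nm.
#' @param photons_per_dye Photons per dye-dot of a dual-color probe; a
#'   single-color probe's dot gets twice this.
#' @param background Background level (counts).
#' @param read_noise_sigma Gaussian sensor noise sigma (counts, default 5).
#' @param detection_efficiency Probability that a dye-dot is present.
#' @param coloc_jitter_nm Per-dye-dot isotropic Gaussian jitter sd (nm).
#' @param min_allele_separation_nm Minimal distance between the two allele
#'   cluster anchors.
#' @param seed Integer seed; all randomness flows through it.
#' @return List of `mifish_scene` objects, one per cell, each with elements
#'   `cell_id`, `nucleus` (center, semi-axes, cell_cycle), `truth`
#'   (per dye-dot: probe_id, allele, channel, x/y/z_nm, photons, present),
#'   `background`, `read_noise_sigma`, `stack_dim`, `voxel_size_nm`.
#' @export
simulate_structures <- function(scheme, n_cells,
                                step_scale_nm = 550, nu = 0.5,
                                territory_radius_nm = 3200,
                                compartments = NULL, lamina_bias = 0.4,
                                g1_fraction = 1,
                                nucleus_semiaxes_nm = c(7000, 6400, 2700),
                                stack_dim = c(150, 150, 44),
                                voxel_size_nm = c(130, 130, 200),
                                photons_per_dye = 15000,
                                background = 100, read_noise_sigma = 5,
                                detection_efficiency = 1,
                                coloc_jitter_nm = 0,
                                min_allele_separation_nm = 7400,
                                seed = NULL) {
  stopifnot(inherits(scheme, "mifish_scheme"), n_cells >= 1)
  if (nu <= 0 || nu > 1) stop("chain exponent nu must be in (0, 1]")
  if (step_scale_nm < 0) stop("step_scale_nm must be non-negative")
  if (!is.null(seed)) set.seed(seed)

  mids <- probe_midpoints(scheme)
  ord <- order(mids)
  gaps_mb <- diff(mids[ord]) / 1e6
  probes <- scheme$probes[ord, , drop = FALSE]
  dyes <- probe_dye_list(scheme)[ord]
  extent_nm <- c(
    x = stack_dim[2] * voxel_size_nm[1],
    y = stack_dim[1] * voxel_size_nm[2],
    z = stack_dim[3] * voxel_size_nm[3]
  )

  lapply(seq_len(n_cells), function(cell) {
    semi <- nucleus_semiaxes_nm * stats::runif(3, 0.92, 1.08)
    center <- extent_nm / 2 + stats::rnorm(3, 0, 0.02 * extent_nm)
    # keep the nucleus inside the stack
    center <- pmin(pmax(center, semi + voxel_size_nm),
                   extent_nm - semi - voxel_size_nm)
    cycle <- if (stats::runif(1) < g1_fraction) "G1" else "G2"

    # two territory anchors symmetric about the nuclear center along a
    # mostly-lateral random direction, min_allele_separation_nm apart
    dir <- stats::rnorm(3) * c(1, 1, 0.1)
    dir <- dir / sqrt(sum(dir^2))
    # anchors placed so the whole territory sphere fits inside the nucleus
    allowed <- pmax(semi - territory_radius_nm, 0.1 * semi)
    anchors <- vapply(c(-1, 1), function(sgn) {
      a <- sgn * dir * min_allele_separation_nm / 2 +
        stats::rnorm(3, 0, 0.05 * semi)
      # clamp the axial offset and the lateral offset independently: flat
      # nuclei leave little axial margin, and coupling the two through one
      # ellipsoidal cap would collapse the lateral territory separation
      az <- min(max(a[3], -0.8 * allowed[3]), 0.8 * allowed[3])
      lat2 <- (a[1] / allowed[1])^2 + (a[2] / allowed[2])^2
      if (lat2 > 1) a[1:2] <- a[1:2] / sqrt(lat2) * 0.99
      center + c(a[1], a[2], az)
    }, numeric(3))

    truth <- do.call(rbind, lapply(1:2, function(allele) {
      pos <- matrix(NA_real_, nrow = nrow(probes), ncol = 3)
      anchor <- anchors[, allele]
      pos[1, ] <- anchor
      for (i in seq_along(gaps_mb)) {
        step <- stats::rnorm(3, 0, step_scale_nm * gaps_mb[i]^nu)
        # confine to the chromosome territory, then to the nucleus
        u <- reflect_inside((pos[i, ] + step - anchor) / territory_radius_nm)
        p <- anchor + u * territory_radius_nm
        u <- reflect_inside((p - center) / semi)
        pos[i + 1, ] <- center + u * semi
      }
      if (!is.null(compartments)) {
        lab <- compartments[probes$probe_id]
        for (i in which(!is.na(lab) & lab == "B")) {
          u <- (pos[i, ] - center) / semi
          rho <- sqrt(sum(u^2))
          if (rho > 0) {
            pos[i, ] <- center + u * ((rho + lamina_bias * (1 - rho)) / rho) * semi
          }
        }
      }
      do.call(rbind, lapply(seq_len(nrow(probes)), function(i) {
        chans <- dyes[[i]]
        ph <- if (length(chans) == 1) 2 * photons_per_dye else photons_per_dye
        out <- data.frame(
          probe_id = probes$probe_id[i], allele = allele, channel = chans,
          x_nm = pos[i, 1], y_nm = pos[i, 2], z_nm = pos[i, 3],
          photons = ph, stringsAsFactors = FALSE)
        if (coloc_jitter_nm > 0) {
          jit <- matrix(stats::rnorm(3 * nrow(out), 0, coloc_jitter_nm),
                        ncol = 3)
          out$x_nm <- out$x_nm + jit[, 1]
          out$y_nm <- out$y_nm + jit[, 2]
          out$z_nm <- out$z_nm + jit[, 3]
        }
        out$present <- stats::runif(nrow(out)) < detection_efficiency
        out
      }))
    }))
    rownames(truth) <- NULL

    structure(list(
      cell_id = cell, kind = "nuclei",
      nucleus = data.frame(cx_nm = center[1], cy_nm = center[2],
                           cz_nm = center[3], ax_nm = semi[1], ay_nm = semi[2],
                           az_nm = semi[3], cell_cycle = cycle,
                           stringsAsFactors = FALSE),
      truth = truth, background = background,
      read_noise_sigma = read_noise_sigma,
      stack_dim = stack_dim, voxel_size_nm = voxel_size_nm
    ), class = "mifish_scene")
  })
}

# add one integrated-Gaussian dot (in place) to array `a`;
# position in px, sigma in px per axis (y, x, z); returns modified array
add_gaussian_dot <- function(a, x, y, z, photons, sigma_yxz, halfwidth = 5) {
  d <- dim(a)
  ry <- max(1, floor(y - halfwidth * sigma_yxz[1])):
    min(d[1], ceiling(y + halfwidth * sigma_yxz[1]))
  rx <- max(1, floor(x - halfwidth * sigma_yxz[2])):
    min(d[2], ceiling(x + halfwidth * sigma_yxz[2]))
  rz <- max(1, floor(z - halfwidth * sigma_yxz[3])):
    min(d[3], ceiling(z + halfwidth * sigma_yxz[3]))
  gy <- stats::pnorm((ry + 0.5 - y) / sigma_yxz[1]) -
    stats::pnorm((ry - 0.5 - y) / sigma_yxz[1])
  gx <- stats::pnorm((rx + 0.5 - x) / sigma_yxz[2]) -
    stats::pnorm((rx - 0.5 - x) / sigma_yxz[2])
  gz <- stats::pnorm((rz + 0.5 - z) / sigma_yxz[3]) -
    stats::pnorm((rz - 0.5 - z) / sigma_yxz[3])
  dot <- photons * (outer(gy, gx) %o% gz)
  a[ry, rx, rz] <- a[ry, rx, rz] + dot
  a
}

apply_sensor_noise <- function(signal, background, read_noise_sigma) {
  lambda <- signal + background
  noisy <- stats::rpois(length(lambda), lambda) +
    stats::rnorm(length(lambda), 0, read_noise_sigma)
  noisy[noisy < 0] <- 0
  dim(noisy) <- dim(signal)
  noisy
}

#' Render one channel of a scene as a voxel stack
#'
#' Each true dot carrying the channel's dye is rendered as a 3D Gaussian
#' integrated over voxels with the channel's PSF sigma. The `dapi` channel
#' renders filled nuclear ellipsoids (G2 nuclei at twice the intensity).
#' Sensor noise is Poisson on (signal + background) followed by additive
#' Gaussian read noise, clipped at zero.
#'
#' @param scene A `mifish_scene`.
#' @param channel Channel to render (`dapi` or a dye).
#' @param noise Add sensor noise (default TRUE).
#' @param dna_intensity Per-voxel DNA stain signal of a G1 nucleus (counts).
#' @param background,read_noise_sigma Override the scene's noise parameters.
#' @param seed Optional seed.
#' @return A `voxel_stack`.
#' @export
render_stack <- function(scene, channel, noise = TRUE, dna_intensity = 400,
                         background = scene$background,
                         read_noise_sigma = scene$read_noise_sigma,
                         seed = NULL) {
  stopifnot(inherits(scene, "mifish_scene"))
  if (!is.null(seed)) set.seed(seed)
  vs <- scene$voxel_size_nm
  d <- scene$stack_dim
  a <- array(0, d)
  if (channel == "dapi") {
    nuc <- scene$nucleus
    xs <- (seq_len(d[2])) * vs[1]
    ys <- (seq_len(d[1])) * vs[2]
    for (r in seq_len(nrow(nuc))) {
      lev <- dna_intensity * ifelse(nuc$cell_cycle[r] == "G1", 1, 2)
      for (k in seq_len(d[3])) {
        zq <- ((k * vs[3] - nuc$cz_nm[r]) / nuc$az_nm[r])^2
        if (zq > 1) next
        q <- outer(((ys - nuc$cy_nm[r]) / nuc$ay_nm[r])^2,
                   ((xs - nuc$cx_nm[r]) / nuc$ax_nm[r])^2, `+`) + zq
        a[, , k] <- a[, , k] + lev * (q <= 1)
      }
    }
  } else {
    if (!channel %in% fish_channels()) stop("unknown channel: ", channel)
    psf <- channel_psf_params(channel)
    sig <- c(psf$expected_sigma_px, psf$expected_sigma_px,
             psf$expected_sigma_z_px)
    dots <- scene$truth[scene$truth$channel == channel & scene$truth$present, ,
                        drop = FALSE]
    for (r in seq_len(nrow(dots))) {
      a <- add_gaussian_dot(a, dots$x_nm[r] / vs[1], dots$y_nm[r] / vs[2],
                            dots$z_nm[r] / vs[3], dots$photons[r], sig)
    }
  }
  if (noise) {
    a <- apply_sensor_noise(a, background, read_noise_sigma)
  } else {
    a <- a + background
  }
  voxel_stack(a, channel, vs)
}

#' Construct a chromatic aberration field
#'
#' Per channel, lateral displacement is a 2nd-order polynomial in (x, y)
#' (coefficient order: 1, x, y, x^2, x*y, y^2; px units) plus a constant
#' axial shift (axial px). The reference channel `cy5` always has the
#' identity field.
#'
#' @param channels Channels covered by the field.
#' @param dx,dy Named lists of length-6 coefficient vectors (missing channels
#'   get zeros).
#' @param dz Named numeric of constant axial shifts (axial px).
#' @return An `aberration_field`.
#' @export
aberration_field <- function(channels = fish_channels(), dx = list(),
                             dy = list(), dz = numeric(0)) {
  get6 <- function(lst, ch) {
    v <- if (ch %in% names(lst)) lst[[ch]] else rep(0, 6)
    stopifnot(length(v) == 6)
    as.numeric(v)
  }
  field <- lapply(channels, function(ch) {
    if (ch == "cy5") {
      list(dx = rep(0, 6), dy = rep(0, 6), dz = 0)
    } else {
      list(dx = get6(dx, ch), dy = get6(dy, ch),
           dz = if (ch %in% names(dz)) unname(dz[ch]) else 0)
    }
  })
  names(field) <- channels
  structure(field, class = "aberration_field")
}

poly2_design <- function(x, y) cbind(1, x, y, x^2, x * y, y^2)

#' Evaluate an aberration field at lateral positions
#'
#' @param field An `aberration_field`.
#' @param channel Channel name.
#' @param x,y Lateral positions (px).
#' @return data.frame with `dx`, `dy` (px) and `dz` (axial px).
#' @export
eval_aberration <- function(field, channel, x, y) {
  if (!channel %in% names(field)) stop("channel not in field: ", channel)
  f <- field[[channel]]
  X <- poly2_design(x, y)
  data.frame(dx = as.numeric(X %*% f$dx), dy = as.numeric(X %*% f$dy),
             dz = rep(f$dz, length(x)))
}

#' Render a multi-channel bead calibration field
#'
#' Beads are placed uniformly at random and are visible in every channel; in
#' channel c each bead is rendered displaced by the aberration field of c.
#' Used to fit and validate the chromatic correction model.
#'
#' @param n_beads Number of beads (>= 6 recommended to constrain a 2nd-order
#'   fit; fewer triggers a warning).
#' @param field An `aberration_field`.
#' @param channels Channels to render.
#' @param stack_dim Stack dimension c(ny, nx, nz).
#' @param photons Photons per bead.
#' @param background,read_noise_sigma Noise parameters.
#' @param noise Add sensor noise.
#' @param seed Integer seed.
#' @param voxel_size_nm Voxel size c(x, y, z) nm.
#' @return List with `stacks` (named list of `voxel_stack`), `truth`
#'   (bead_id, x, y, z in px, reference positions) and `displaced`
#'   (per channel true rendered positions).
#' @export
render_bead_field <- function(n_beads, field, channels = fish_channels(),
                              stack_dim = c(90, 90, 24), photons = 20000,
                              background = 100, read_noise_sigma = 5,
                              noise = TRUE, seed = NULL,
                              voxel_size_nm = c(130, 130, 200)) {
  if (n_beads < 6) warning("fewer than 6 beads under-constrains a 2nd-order fit")
  if (!is.null(seed)) set.seed(seed)
  truth <- data.frame(
    bead_id = seq_len(n_beads),
    x = stats::runif(n_beads, 7, stack_dim[2] - 6),
    y = stats::runif(n_beads, 7, stack_dim[1] - 6),
    z = stats::runif(n_beads, 5, stack_dim[3] - 4)
  )
  displaced <- do.call(rbind, lapply(channels, function(ch) {
    ab <- eval_aberration(field, ch, truth$x, truth$y)
    data.frame(bead_id = truth$bead_id, channel = ch,
               x = truth$x + ab$dx, y = truth$y + ab$dy, z = truth$z + ab$dz,
               stringsAsFactors = FALSE)
  }))
  stacks <- lapply(channels, function(ch) {
    psf <- channel_psf_params(ch)
    sig <- c(psf$expected_sigma_px, psf$expected_sigma_px,
             psf$expected_sigma_z_px)
    a <- array(0, stack_dim)
    dd <- displaced[displaced$channel == ch, , drop = FALSE]
    for (r in seq_len(nrow(dd))) {
      a <- add_gaussian_dot(a, dd$x[r], dd$y[r], dd$z[r], photons, sig)
    }
    if (noise) {
      a <- apply_sensor_noise(a, background, read_noise_sigma)
    } else {
      a <- a + background
    }
    voxel_stack(a, ch, voxel_size_nm)
  })
  names(stacks) <- channels
  list(stacks = stacks, truth = truth, displaced = displaced)
}

#' Simulate single-dot patches for localization-precision scoring
#'
#' Each patch contains one integrated-Gaussian dot whose true location is
#' uniform within the central voxel, on a flat background, with Poisson noise
#' on (signal + background) and additive Gaussian sensor noise.
#'
#' @param channel Dye channel (sets the PSF sigma).
#' @param photons Total dot photons.
#' @param background Background level (counts).
#' @param n Number of patches (default 1000).
#' @param patch_dim Patch dimension (default 15 x 15 x 15 voxels).
#' @param read_noise_sigma Gaussian sensor noise sigma (default 5).
#' @param seed Integer seed.
#' @return List with `patches` (list of `voxel_stack`), `truth`
#'   (data.frame x, y, z in px) and `center_voxel` c(y, x, z).
#' @export
simulate_patch <- function(channel, photons, background = 100, n = 1000,
                           patch_dim = c(15, 15, 15), read_noise_sigma = 5,
                           seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  psf <- channel_psf_params(channel)
  sig <- c(psf$expected_sigma_px, psf$expected_sigma_px,
           psf$expected_sigma_z_px)
  c0 <- ceiling(patch_dim / 2) # central voxel (y, x, z)
  truth <- data.frame(
    x = c0[2] + stats::runif(n, -0.5, 0.5),
    y = c0[1] + stats::runif(n, -0.5, 0.5),
    z = c0[3] + stats::runif(n, -0.5, 0.5)
  )
  patches <- lapply(seq_len(n), function(i) {
    a <- array(0, patch_dim)
    a <- add_gaussian_dot(a, truth$x[i], truth$y[i], truth$z[i], photons, sig)
    voxel_stack(apply_sensor_noise(a, background, read_noise_sigma), channel)
  })
  list(patches = patches, truth = truth, center_voxel = c0)
}
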