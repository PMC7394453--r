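#' Phantom simulation parameters
#'
#' Controls the synthetic head phantom and the susceptibility field used to
#' emulate a heterogeneous multi-site training corpus: grid geometry, tissue
#' contrasts for T1 and b0, off-resonance field amplitude and smoothness,
#' hotspot placement, noise level and seed.
#'
#' Tissue vectors are ordered (CSF, gray matter, white matter,
#' skull/background).  T1 means follow the 0-150 normalized-T1 convention
#' (white > gray > CSF); b0 means have CSF brightest, so the volume's 99th
#' percentile captures CSF intensity.  `noise_sd` is a dimensionless global
#' scale multiplying the per-tissue SDs (0 gives a piecewise-constant
#' phantom).  `readout_ref` (seconds) is the nominal readout at which the
#' field's invertibility margin is enforced outside hotspots.
#'
#' @param shape grid dims (scalar or length 3), each >= 16.
#' @param voxel_size_mm voxel size in mm (scalar or length 3).
#' @param t1_means,t1_sds,b0_means,b0_sds length-4 tissue intensity stats.
#' @param field_amplitude_hz max off-resonance magnitude, Hz.
#' @param field_smoothness_vox correlation length (Gaussian sigma), voxels, >= 1.
#' @param n_hotspots number of high-amplitude field hotspots.
#' @param hotspot_spread_vox Gaussian width of each hotspot, voxels.
#' @param noise_sd global noise scale (>= 0).
#' @param readout_ref nominal readout time (s) for the invertibility clamp.
#' @param seed integer RNG seed.
#' @return object of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(48L, 48L, 48L), voxel_size_mm = 2.5,
                           t1_means = c(30, 80, 110, 4), t1_sds = c(4, 6, 6, 2),
                           b0_means = c(100, 45, 40, 2), b0_sds = c(6, 4, 4, 1),
                           field_amplitude_hz = 50, field_smoothness_vox = 8,
                           n_hotspots = 2L, hotspot_spread_vox = 3,
                           noise_sd = 1, readout_ref = 0.05, seed = 1L) {
  shape <- as.integer(rep_len(shape, 3L))
  if (any(shape < 16L)) stop("phantom grid must be at least 16 voxels per axis")
  voxel_size_mm <- rep_len(voxel_size_mm, 3L)
  for (v in list(t1_means, t1_sds, b0_means, b0_sds))
    if (length(v) != 4L || any(v < 0)) stop("tissue stats must be 4 non-negative values")
  if (field_amplitude_hz < 0) stop("field amplitude must be >= 0")
  if (field_smoothness_vox < 1) stop("field smoothness must be >= 1 voxel")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 t1_means = t1_means, t1_sds = t1_sds,
                 b0_means = b0_means, b0_sds = b0_sds,
                 field_amplitude_hz = field_amplitude_hz,
                 field_smoothness_vox = field_smoothness_vox,
                 n_hotspots = as.integer(n_hotspots),
                 hotspot_spread_vox = hotspot_spread_vox,
                 noise_sd = noise_sd, readout_ref = readout_ref,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# Tissue label volume: 1 CSF, 2 gray, 3 white, 4 skull/background.
# Ellipsoidal head with nested shells, smooth cortical-like boundary
# perturbations and CSF ventricles.
phantom_labels <- function(params) {
  gd <- params$shape
  uc <- unit_coords(gd)
  with_seed(params$seed, {
    pert <- array(stats::rnorm(prod(gd)), gd)
    pert <- gaussian_smooth_3d(pert, 3)
    pert <- pert / max(stats::sd(pert), 1e-12)
    # effective radius with cortical-like boundary modulation
    rho <- sqrt((uc$x / 0.80)^2 + (uc$y / 0.90)^2 + (uc$z / 0.75)^2)
    rho <- rho * (1 + 0.05 * pert)
    lab <- array(4L, gd)                       # skull/background
    lab[rho <= 0.96] <- 1L                     # CSF rim
    lab[rho <= 0.88] <- 2L                     # gray shell
    lab[rho <= 0.70] <- 3L                     # white core
    # ventricles: central CSF cavities
    rv <- sqrt(((uc$x - 0.04) / 0.20)^2 + ((uc$y - 0.05) / 0.34)^2 +
                 ((uc$z - 0.08) / 0.18)^2)
    lab[rv <= 1 & lab == 3L] <- 1L
    mask <- rho <= 1.02
    list(labels = lab, head = mask)
  })
}

#' Generate a co-registered T1/b0 phantom pair
#'
#' Builds an ellipsoidal head with nested tissue shells (CSF rim, gray
#' shell, white core, ventricles) perturbed by smooth random boundary
#' modulation, then paints T1 contrast (white > gray > CSF) and b0 contrast
#' (CSF brightest).  Per-tissue Gaussian noise scaled by `noise_sd` is added.
#' Deterministic under the params seed.
#'
#' @param params a [phantom_params].
#' @return list with `b0_volume` elements `t1`, `b0_u`, `mask` (binary head
#'   mask) and the integer `labels` array.
#' @export
make_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  gd <- params$shape
  ph <- phantom_labels(params)
  lab <- ph$labels
  paint <- function(means, sds, noise) {
    img <- array(means[lab], gd)
    if (params$noise_sd > 0)
      img <- img + params$noise_sd * array(sds[lab], gd) * noise
    img
  }
  vols <- with_seed(params$seed + 1000L, {
    nz1 <- array(stats::rnorm(prod(gd)), gd)
    nz2 <- array(stats::rnorm(prod(gd)), gd)
    list(t1 = paint(params$t1_means, params$t1_sds, nz1),
         b0 = paint(params$b0_means, params$b0_sds, nz2))
  })
  vox <- params$voxel_size_mm
  list(t1 = b0_volume(pmax(vols$t1, 0), vox),
       b0_u = b0_volume(pmax(vols$b0, 0), vox),
       mask = b0_volume(array(as.numeric(ph$head), gd), vox),
       labels = lab)
}

#' Generate a smooth susceptibility off-resonance field with hotspots
#'
#' Correlated Gaussian noise (white noise smoothed at the configured
#' correlation length) scaled to the configured amplitude, plus localized
#' high-amplitude hotspots near the inferior-frontal and temporal mask
#' boundary where air-tissue interfaces concentrate off-resonance in real
#' heads.  The smooth component is scaled so the induced displacement at the
#' nominal readout keeps `1 + d(shift)/d(axis) > 0.05` (invertible forward
#' map) outside hotspots; the total field is clipped to +/- amplitude, then
#' tapered and zeroed outside the head mask.  Deterministic under seed.
#'
#' @param params a [phantom_params].
#' @param mask head-mask `b0_volume` from [make_phantom()].
#' @return object of class `susceptibility_field`: list(`field` Hz array,
#'   `hotspot_mask` logical array, `voxel_size`).
#' @export
make_field <- function(params, mask) {
  gd <- params$shape
  m <- mask$data > 0.5
  amp <- params$field_amplitude_hz
  if (amp == 0) {
    return(structure(list(field = array(0, gd), hotspot_mask = array(FALSE, gd),
                          voxel_size = params$voxel_size_mm),
                     class = "susceptibility_field"))
  }
  taper <- gaussian_smooth_3d(array(as.numeric(m), gd), 2)
  uc <- unit_coords(gd)
  with_seed(params$seed + 2000L, {
    sm <- gaussian_smooth_3d(array(stats::rnorm(prod(gd)), gd),
                             params$field_smoothness_vox)
    sm <- sm * taper
    # robust scale after tapering: masked SD set to amp/3 so the bulk field
    # energy is seed-stable; the final clip enforces max |field| <= amp
    sm <- sm / max(stats::sd(sm[m]), 1e-12) * (amp / 3)
    sm <- pmin(pmax(sm, -amp), amp)
    # invertibility margin outside hotspots, at the nominal readout: where
    # the induced shift gradient is too steep, smooth locally rather than
    # rescaling globally (a lone steep edge must not flatten the whole field)
    max_grad <- function(x) max(vapply(1:3, function(ax)
      max(abs(forward_diff(x, ax))), numeric(1)))
    for (iter in 1:5) {
      if (max_grad(sm) * params$readout_ref <= 0.90) break
      sm <- gaussian_smooth_3d(sm, 1) * taper
    }
    g <- max_grad(sm) * params$readout_ref
    if (g > 0.90) sm <- sm * (0.90 / g)
    hot <- array(0, gd)
    hotmask <- array(FALSE, gd)
    if (params$n_hotspots > 0) {
      shell <- m & !(gaussian_smooth_3d(array(as.numeric(m), gd), 1.5) > 0.95)
      cand <- which(shell & uc$z < -0.2 & (uc$y > 0.25 | abs(uc$x) > 0.55))
      if (length(cand) == 0) cand <- which(shell & uc$z < 0)
      if (length(cand) > 0) {
        centers <- sample(cand, min(params$n_hotspots, length(cand)))
        ci <- arrayInd(centers, gd)
        i1 <- array(rep(seq_len(gd[1]), times = gd[2] * gd[3]), gd)
        i2 <- array(rep(rep(seq_len(gd[2]), each = gd[1]), times = gd[3]), gd)
        i3 <- array(rep(seq_len(gd[3]), each = gd[1] * gd[2]), gd)
        for (h in seq_len(nrow(ci))) {
          sgn <- sample(c(-1, 1), 1)
          a <- stats::runif(1, 0.6, 1) * amp * sgn
          w <- params$hotspot_spread_vox
          r2 <- (i1 - ci[h, 1])^2 + (i2 - ci[h, 2])^2 + (i3 - ci[h, 3])^2
          bump <- a * exp(-r2 / (2 * w^2))
          hot <- hot + bump
          hotmask <- hotmask | (r2 <= (2.5 * w)^2)
        }
      }
    }
    f <- sm + hot * taper
    f <- pmin(pmax(f, -amp), amp)
    f[!m] <- 0
    structure(list(field = f, hotspot_mask = hotmask,
                   voxel_size = params$voxel_size_mm),
              class = "susceptibility_field")
  })
}

#' Convert an off-resonance field to a PE-axis displacement field
#'
#' Voxel displacement along the phase-encoding axis is
#' `polarity * field (Hz) * total readout time (s)`, in voxel units.  A
#' readout time of 0 (infinite bandwidth) gives zero displacement.
#'
#' @param field a `susceptibility_field`.
#' @param pe a [pe_spec].
#' @return object of class `displacement_field`: list(`shift` array in voxel
#'   units, `pe`).
#' @export
field_to_displacement <- function(field, pe) {
  stopifnot(inherits(field, "susceptibility_field"), inherits(pe, "pe_spec"))
  structure(list(shift = pe$polarity * field$field * pe$readout_time, pe = pe),
            class = "displacement_field")
}

displacement_field <- function(shift, pe) {
  stopifnot(is.array(shift), length(dim(shift)) == 3L, inherits(pe, "pe_spec"))
  if (any(!is.finite(shift))) stop("displacement field contains non-finite values")
  structure(list(shift = shift, pe = pe), class = "displacement_field")
}

#' Apply susceptibility distortion (mass-preserving pushforward)
#'
#' Forward model of EPI susceptibility distortion: each source voxel's
#' intensity is linearly splatted along the PE axis to position
#' `index + shift`, so per-line intensity sums are conserved to float
#' tolerance and signal pileup emerges where the shift gradient compresses
#' voxels (areas of bright signal and matching voids elsewhere).  Deposits
#' falling past a line end accumulate at the edge voxel.
#'
#' @param vol `b0_volume` to distort.
#' @param dfield `displacement_field` on the same grid.
#' @return distorted `b0_volume`.
#' @export
apply_distortion <- function(vol, dfield) {
  stopifnot(inherits(vol, "b0_volume"), inherits(dfield, "displacement_field"))
  if (!identical(dim(vol$data), dim(dfield$shift)))
    stop("volume and displacement field must share the grid")
  ax <- dfield$pe$axis
  perm <- c(ax, setdiff(1:3, ax))
  v <- aperm(vol$data, perm)
  s <- aperm(dfield$shift, perm)
  n <- dim(v)[1]
  if (max(abs(s)) > n)
    stop("displacement exceeds the PE line extent (unphysical configuration)")
  nl <- prod(dim(v)[-1])
  i1 <- rep_len(seq_len(n), n * nl)
  line0 <- rep(seq_len(nl) - 1L, each = n) * n
  t <- i1 + as.vector(s)
  i0 <- floor(t)
  w <- t - i0
  j0 <- pmin(pmax(i0, 1), n) + line0
  j1 <- pmin(pmax(i0 + 1, 1), n) + line0
  vals <- c(as.vector(v) * (1 - w), as.vector(v) * w)
  g <- c(j0, j1)
  acc <- rowsum(vals, g, reorder = TRUE)
  out <- numeric(n * nl)
  out[sort(unique(g))] <- acc
  out <- array(out, dim(v))
  b0_volume(aperm(out, order(perm)), vol$voxel_size, vol$affine)
}

#' Simulate one subject session (phantom + field + distorted blips)
#'
#' Composes [make_phantom()], [make_field()], [field_to_displacement()] and
#' [apply_distortion()] into a bundled sample.  With `n_blips = 2` the two
#' distorted b0s come from the same truth with exactly opposite blip
#' polarities.  Scanner noise is applied to the phantom intensities before
#' the distortion pushforward, so each stored blip is exactly the splat of
#' the stored undistorted b0 (per-line mass conservation is exact by
#' construction).
#'
#' @param params [phantom_params] (its seed makes the subject).
#' @param pe_axis PE axis (1-3), default 2 (anterior-posterior).
#' @param readout total readout time, seconds.
#' @param n_blips 1 or 2.
#' @return object of class `subject_sample`: list(`t1`, `b0_u`, `mask`
#'   `b0_volume`s; `blips` list of list(`vol`, `pe`); `truth_field`;
#'   `truth_disp` list of `displacement_field`; `params`).
#' @export
simulate_subject <- function(params, pe_axis = 2L, readout = 0.05, n_blips = 1L) {
  if (!n_blips %in% 1:2) stop("n_blips must be 1 or 2")
  ph <- make_phantom(params)
  fld <- make_field(params, ph$mask)
  pols <- if (n_blips == 2L) c(1L, -1L) else 1L
  blips <- lapply(pols, function(p) {
    pe <- pe_spec(pe_axis, p, readout)
    d <- field_to_displacement(fld, pe)
    list(vol = apply_distortion(ph$b0_u, d), pe = pe, disp = d)
  })
  structure(list(t1 = ph$t1, b0_u = ph$b0_u, mask = ph$mask,
                 blips = lapply(blips, function(b) b[c("vol", "pe")]),
                 truth_field = fld,
                 truth_disp = lapply(blips, `[[`, "disp"),
                 params = params),
            class = "subject_sample")
}

#' Simulate a cohort of subjects
#'
#' Per-subject seeds are derived deterministically from the master seed, so
#' the whole cohort is reproducible and subjects are distinct.  Blip counts
#' can be mixed (as in a multi-site corpus where some sites acquire
#' opposite-polarity pairs and others a single blip).
#'
#' @param n_subjects number of subjects.
#' @param base_params template [phantom_params]; per-subject seed overrides.
#' @param seed master seed.
#' @param pe_axis,readout acquisition settings.
#' @param blip_pattern vector recycled over subjects giving each `n_blips`.
#' @return list of `subject_sample`.
#' @export
simulate_cohort <- function(n_subjects, base_params = phantom_params(),
                            seed = 1L, pe_axis = 2L, readout = 0.05,
                            blip_pattern = c(1L, 2L)) {
  blips <- rep_len(blip_pattern, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    p <- base_params
    p$seed <- as.integer((seed * 10000L + i) %% .Machine$integer.max)
    s <- simulate_subject(p, pe_axis = pe_axis, readout = readout,
                          n_blips = blips[i])
    s$subject_id <- sprintf("sub-%03d", i)
    s
  })
}
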