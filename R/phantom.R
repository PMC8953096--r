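#' Draw biexponential voxel parameters from a tissue specification
#'
#' T2 times are drawn from normal distributions truncated below at 1 ms and
#' resampled until `t2_short < t2_long`; the short fraction is drawn from a
#' normal truncated to (0.01, 0.99). Amplitudes are set to
#' `(frac_short, 1 - frac_short)` so the per-voxel amplitude sum is 1.
#' With all SD fields zero the configured means are returned exactly.
#'
#' @param tissue a tissue spec as returned by [tissue_spec()].
#' @param seed optional integer; when given, the draw is made reproducible
#'   by seeding R's RNG locally.
#' @return A [biexp_params()] object.
#' @export
sample_voxel_params <- function(tissue, seed = NULL) {
  validate_tissue_spec(tissue)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  rtrunc_norm <- function(mean, sd, lower, upper = Inf) {
    if (sd == 0) return(min(max(mean, lower), upper))
    for (i in 1:1000) {
      x <- stats::rnorm(1L, mean, sd)
      if (x > lower && x < upper) return(x)
    }
    stop("truncated-normal sampling failed to accept after 1000 tries",
         call. = FALSE)
  }
  for (i in 1:1000) {
    t2s <- rtrunc_norm(tissue$mean_t2_short, tissue$sd_t2_short, 1)
    t2l <- rtrunc_norm(tissue$mean_t2_long, tissue$sd_t2_long, 1)
    if (t2s < t2l) break
    if (i == 1000L) stop("could not sample t2_short < t2_long", call. = FALSE)
  }
  fs <- rtrunc_norm(tissue$mean_frac_short, tissue$sd_frac_short, 0.01, 0.99)
  biexp_params(amp_short = fs, amp_long = 1 - fs, t2_short = t2s, t2_long = t2l)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Phantom specification
#'
#' Describes a synthetic multi-echo acquisition: grid shape, echo times,
#' ROI placements with their generative tissue parameters, and a noise
#' model. The default grid is deliberately small (32 x 32 x 1); per-voxel
#' physics does not depend on matrix size.
#'
#' @param dim integer vector of 3 voxel counts (x, y, z).
#' @param tes echo times (ms); default [default_echo_times()].
#' @param rois list of ROI entries, each a list with `label` (positive
#'   integer), `structure`, `tissue` (a [tissue_spec()]), and `region`
#'   (a list with 1-based inclusive index ranges `x`, `y`, `z`).
#'   ROIs must not overlap.
#' @param noise `"none"`, `"gaussian"` or `"rician"`.
#' @param sigmas per-echo noise standard deviations (recycled if length 1).
#' @param seed integer RNG seed used for parameter sampling and noise.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(32L, 32L, 1L), tes = default_echo_times(),
                         rois = list(), noise = c("none", "gaussian", "rician"),
                         sigmas = 0, seed = 1L) {
  noise <- match.arg(noise)
  validate_echo_times(tes)
  if (length(dim) != 3L || any(dim < 1L)) {
    stop("dim must give 3 positive voxel counts", call. = FALSE)
  }
  sigmas <- rep_len(sigmas, length(tes))
  if (any(sigmas < 0)) stop("noise sigmas must be >= 0", call. = FALSE)
  structure(
    list(dim = as.integer(dim), tes = tes, rois = rois, noise = noise,
         sigmas = sigmas, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

roi_voxel_index <- function(region, dim) {
  rng <- function(r, n) {
    r <- as.integer(r)
    if (length(r) == 1L) r <- c(r, r)
    if (r[1] < 1L || r[2] > n || r[1] > r[2]) {
      stop("ROI region out of grid bounds", call. = FALSE)
    }
    r[1]:r[2]
  }
  idx <- expand.grid(x = rng(region$x, dim[1]), y = rng(region$y, dim[2]),
                     z = rng(region$z, dim[3]))
  cbind(idx$x, idx$y, idx$z)
}

#' Generate a synthetic multi-echo phantom
#'
#' Each ROI voxel receives biexponential parameters drawn from its tissue
#' spec; its noiseless signal is the closed-form decay evaluated on the
#' echo grid. Background voxels are zero before noise. Truth maps record
#' the sampled per-voxel parameters and the integer label mask.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `volume` (4-D array x,y,z,echo), `tes`, `label`
#'   (3-D integer mask), and `truth` (list of 3-D arrays `t2_short`,
#'   `t2_long`, `frac_short`; `NA` outside ROIs), plus the spec itself.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(spec$seed)

  dm <- spec$dim
  n_echo <- length(spec$tes)
  volume <- array(0, dim = c(dm, n_echo))
  label <- array(0L, dim = dm)
  t2s_map <- array(NA_real_, dim = dm)
  t2l_map <- array(NA_real_, dim = dm)
  fs_map <- array(NA_real_, dim = dm)

  for (roi in spec$rois) {
    vox <- roi_voxel_index(roi$region, dm)
    if (any(label[vox] != 0L)) stop("ROIs overlap", call. = FALSE)
    label[vox] <- as.integer(roi$label)
    for (k in seq_len(nrow(vox))) {
      p <- sample_voxel_params(roi$tissue)
      sig <- biexp_signal(p, spec$tes)
      volume[vox[k, 1], vox[k, 2], vox[k, 3], ] <- sig
      t2s_map[vox[k, , drop = FALSE]] <- p$t2_short
      t2l_map[vox[k, , drop = FALSE]] <- p$t2_long
      fs_map[vox[k, , drop = FALSE]] <- p$amp_short / (p$amp_short + p$amp_long)
    }
  }

  if (spec$noise != "none") {
    volume <- add_noise(volume, spec$sigmas, model = spec$noise)
  }

  list(volume = volume, tes = spec$tes, label = label,
       truth = list(t2_short = t2s_map, t2_long = t2l_map, frac_short = fs_map),
       spec = spec)
}

#' Add acquisition noise to a multi-echo volume
#'
#' Gaussian: additive zero-mean noise per echo (high-SNR magnitude
#' approximation). Rician: the magnitude of the complex signal with
#' independent Gaussian noise on both quadratures,
#' `sqrt((S + n1)^2 + n2^2)`.
#'
#' @param volume 4-D array (x, y, z, echo).
#' @param sigmas one noise SD per echo.
#' @param model `"gaussian"` or `"rician"`.
#' @param seed optional integer seed for a reproducible draw.
#' @return The noisy volume, same shape.
#' @export
add_noise <- function(volume, sigmas, model = c("gaussian", "rician"),
                      seed = NULL) {
  model <- match.arg(model)
  dm <- dim(volume)
  if (length(dm) != 4L) stop("volume must be 4-D (x, y, z, echo)", call. = FALSE)
  if (length(sigmas) != dm[4]) {
    stop("need one sigma per echo: got ", length(sigmas), " sigmas for ",
         dm[4], " echoes", call. = FALSE)
  }
  if (any(sigmas < 0)) stop("sigmas must be >= 0", call. = FALSE)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  n_vox <- prod(dm[1:3])
  sig_full <- rep(sigmas, each = n_vox)
  if (model == "gaussian") {
    volume + array(stats::rnorm(length(volume), 0, sig_full), dim = dm)
  } else {
    n1 <- array(stats::rnorm(length(volume), 0, sig_full), dim = dm)
    n2 <- array(stats::rnorm(length(volume), 0, sig_full), dim = dm)
    sqrt((volume + n1)^2 + n2^2)
  }
}
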