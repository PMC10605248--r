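#' Configuration for the synthetic spheroid z-stack generator
#'
#' The generator renders a transparent spheroid as a geometric defocus cone:
#' at the focal plane `z_f` the transmitted light collapses into a tight 2-D
#' Gaussian spot of width `sigma0`; away from the focal plane the spot widens
#' linearly with slope `cone_slope_s` while its total flux is conserved, so
#' the peak amplitude falls as \eqn{A(z) = F (1-\tau) / (2\pi\sigma(z)^2)}
#' with \eqn{\sigma(z) = \sigma_0 + s |z - z_f|}. Opacity (cataract) enters
#' as a multiplicative flux attenuation \eqn{(1-\tau)}: a fully opaque
#' spheroid (`opacity_tau = 1`) transmits no focused light at all.
#'
#' @param image_side image side in pixels (>= 32).
#' @param n_slices number of z-slices.
#' @param z_min,z_max acquisition range in micrometres (slices are evenly
#'   spaced); by convention z = 0 is the microscope focus and negative values
#'   are below the sample.
#' @param z_f focal plane of the spheroid lens, micrometres; must lie in
#'   `[z_min, z_max]`.
#' @param background_b background intensity (camera counts).
#' @param spot_flux_F total flux of the focused spot (camera counts summed
#'   over pixels, before attenuation).
#' @param sigma0 spot width at focus, pixels (> 0).
#' @param cone_slope_s defocus cone slope, pixels per micrometre.
#' @param opacity_tau opacity in `[0, 1]`; 0 = fully transparent.
#' @param disk_radius spheroid disk radius in pixels; the spot is rendered
#'   only inside this central disk.
#' @param disk_gain relative brightness of the spheroid body over background
#'   (0 = invisible body, only the focused spot is rendered).
#' @param noise_model one of `"none"`, `"poisson"` (shot noise) or
#'   `"gaussian"` (read noise of standard deviation `noise_sd`).
#' @param noise_sd standard deviation for `noise_model = "gaussian"`.
#' @param seed integer RNG seed; fixed seed gives byte-identical stacks.
#'
#' @return A validated list of class `stack_sim_config`.
#' @export
stack_sim_config <- function(image_side = 256L, n_slices = 25L,
                             z_min = -50, z_max = 10, z_f = -20,
                             background_b = 500, spot_flux_F = 2e5,
                             sigma0 = 3, cone_slope_s = 0.4,
                             opacity_tau = 0, disk_radius = 60,
                             disk_gain = 0,
                             noise_model = c("none", "poisson", "gaussian"),
                             noise_sd = 10, seed = 1L) {
  noise_model <- match.arg(noise_model)
  cfg <- list(image_side = as.integer(image_side), n_slices = as.integer(n_slices),
              z_min = z_min, z_max = z_max, z_f = z_f,
              background_b = background_b, spot_flux_F = spot_flux_F,
              sigma0 = sigma0, cone_slope_s = cone_slope_s,
              opacity_tau = opacity_tau, disk_radius = disk_radius,
              disk_gain = disk_gain, noise_model = noise_model,
              noise_sd = noise_sd, seed = as.integer(seed))
  if (cfg$image_side < 32L) stop("invalid config: image_side must be >= 32")
  if (cfg$n_slices < 1L) stop("invalid config: n_slices must be >= 1")
  if (cfg$opacity_tau < 0 || cfg$opacity_tau > 1)
    stop("invalid config: opacity_tau must lie in [0, 1]")
  if (cfg$sigma0 <= 0) stop("invalid config: sigma0 must be > 0")
  if (!(cfg$z_min <= cfg$z_f && cfg$z_f <= cfg$z_max))
    stop("invalid config: z_f must lie in [z_min, z_max]")
  if (cfg$background_b < 0) stop("invalid config: background_b must be >= 0")
  if (cfg$spot_flux_F < 0) stop("invalid config: spot_flux_F must be >= 0")
  if (cfg$disk_radius <= 0) stop("invalid config: disk_radius must be > 0")
  if (cfg$cone_slope_s < 0) stop("invalid config: cone_slope_s must be >= 0")
  class(cfg) <- "stack_sim_config"
  cfg
}

#' Simulate a spheroid z-stack under the defocus-cone model
#'
#' Each slice is `background_b` everywhere, plus the spheroid body
#' (`disk_gain * background_b` inside the central disk) and, inside the same
#' disk, a radially symmetric Gaussian spot whose width grows and amplitude
#' falls away from the focal plane (see [stack_sim_config()]). Noise is then
#' applied per `noise_model` and values are quantized to unsigned 16-bit with
#' clipping.
#'
#' @param cfg a [stack_sim_config()].
#' @param center optional spot/disk centre `c(row, col)`; default image centre.
#' @return A [zstack()] with integer-valued intensities in `[0, 65535]`.
#' @export
simulate_zstack <- function(cfg, center = NULL) {
  if (!inherits(cfg, "stack_sim_config")) cfg <- do.call(stack_sim_config, cfg)
  set.seed(cfg$seed)
  side <- cfg$image_side
  if (is.null(center)) center <- c((side + 1) / 2, (side + 1) / 2)
  z <- if (cfg$n_slices == 1L) cfg$z_min else
    seq(cfg$z_min, cfg$z_max, length.out = cfg$n_slices)
  rows <- matrix(seq_len(side), side, side)
  cols <- t(rows)
  r2 <- (rows - center[1L])^2 + (cols - center[2L])^2
  indisk <- r2 <= cfg$disk_radius^2
  base <- cfg$background_b * (1 + cfg$disk_gain * indisk)
  arr <- array(0, dim = c(cfg$n_slices, side, side))
  for (i in seq_len(cfg$n_slices)) {
    sig <- cfg$sigma0 + cfg$cone_slope_s * abs(z[i] - cfg$z_f)
    amp <- cfg$spot_flux_F * (1 - cfg$opacity_tau) / (2 * pi * sig^2)
    img <- base + amp * exp(-r2 / (2 * sig^2)) * indisk
    img <- switch(cfg$noise_model,
                  none = img,
                  poisson = matrix(rpois(length(img), lambda = img), side, side),
                  gaussian = img + rnorm(length(img), sd = cfg$noise_sd))
    arr[i, , ] <- pmin(pmax(round(img), 0), 65535)
  }
  zstack(arr, z)
}

#' Closed-form peak amplitude of the simulated spot
#'
#' Amplitude of the defocus-cone Gaussian above background at z-position `z`,
#' \eqn{A(z) = F (1-\tau) / (2\pi \sigma(z)^2)}. Used as the generator-truth
#' oracle for the focal-ratio curve.
#'
#' @inheritParams simulate_zstack
#' @param z z-position(s), micrometres.
#' @return numeric amplitude(s).
#' @export
spot_amplitude <- function(cfg, z) {
  sig <- cfg$sigma0 + cfg$cone_slope_s * abs(z - cfg$z_f)
  cfg$spot_flux_F * (1 - cfg$opacity_tau) / (2 * pi * sig^2)
}
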