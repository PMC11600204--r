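#' Sensing-probe specification
#'
#' Geometry and material of the hollow quartz cantilever used as the force
#' sensor. The probe is clamped at its base; the fiber sample rests at the
#' mount position `l` (measured from the clamp) and the optical readout
#' tracks the tip, at `L_p`. All lengths are in metres, moduli in pascals.
#'
#' @param outer_diameter Outer diameter `D_p` of the tube (m).
#' @param inner_diameter Inner diameter `d_p` of the bore (m); `0` for a
#'   solid rod.
#' @param probe_length Free length `L_p` from clamp to tip (m).
#' @param mount_position Distance `l` from the clamp to where the sample
#'   rests (m); must satisfy `0 < l < L_p`.
#' @param pixel_size Object-plane size of one camera pixel (m/px).
#' @param material_modulus Young's modulus of the probe material (Pa).
#'   Defaults to 72 GPa, a standard literature value for fused quartz.
#'
#' @return An object of class `probe_spec`.
#' @seealso [probe_preset()], [probe_stiffness()], [force_per_pixel()]
#' @export
probe_spec <- function(outer_diameter, inner_diameter, probe_length,
                       mount_position, pixel_size,
                       material_modulus = 72e9) {
  stopifnot(is.numeric(outer_diameter), is.numeric(inner_diameter),
            is.numeric(probe_length), is.numeric(mount_position),
            is.numeric(pixel_size), is.numeric(material_modulus))
  if (material_modulus <= 0) stop("material_modulus must be > 0")
  if (inner_diameter < 0 || inner_diameter >= outer_diameter)
    stop("invalid geometry: need 0 <= inner_diameter < outer_diameter")
  if (probe_length <= 0) stop("probe_length must be > 0")
  if (mount_position <= 0 || mount_position >= probe_length)
    stop("mount_position must satisfy 0 < l < L_p (load beyond tip unsupported)")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(
    list(material_modulus = material_modulus,
         outer_diameter = outer_diameter,
         inner_diameter = inner_diameter,
         probe_length = probe_length,
         mount_position = mount_position,
         pixel_size = pixel_size),
    class = "probe_spec")
}

#' @export
print.probe_spec <- function(x, ...) {
  cat("<probe_spec>\n")
  cat(sprintf("  OD %.3g mm, ID %.3g mm, L_p %.3g mm, l %.3g mm\n",
              x$outer_diameter * 1e3, x$inner_diameter * 1e3,
              x$probe_length * 1e3, x$mount_position * 1e3))
  cat(sprintf("  E = %.3g GPa, pixel %.3g um/px\n",
              x$material_modulus / 1e9, x$pixel_size * 1e6))
  cat(sprintf("  k = %.4g N/m, resolution %.4g uN/px\n",
              probe_stiffness(x), force_per_pixel(x) * 1e6))
  invisible(x)
}

#' Bundled probe presets
#'
#' Two sensing-probe configurations used throughout:
#' * `"short"`: the standard viscoelasticity probe (also used for combined
#'   viscoelasticity + contractile-force runs), resolution about 0.88 µN per
#'   pixel;
#' * `"long"`: the doubled-length probe used for sensitive contractile-force
#'   work, resolution about 0.11 µN per pixel (stiffness falls by 8 when the
#'   length doubles at fixed load-position ratio).
#'
#' Tube diameters (OD 0.3 mm, ID 0.1 mm) are the instrument's; probe length,
#' mount position and pixel size are declared fixture values chosen to
#' reproduce the two per-pixel resolutions.
#'
#' @param name `"short"` or `"long"`.
#' @return A [probe_spec()].
#' @export
probe_preset <- function(name = c("short", "long")) {
  name <- match.arg(name)
  switch(name,
    short = probe_spec(outer_diameter = 0.3e-3, inner_diameter = 0.1e-3,
                       probe_length = 50e-3, mount_position = 45e-3,
                       pixel_size = 1.1e-6),
    long  = probe_spec(outer_diameter = 0.3e-3, inner_diameter = 0.1e-3,
                       probe_length = 100e-3, mount_position = 90e-3,
                       pixel_size = 1.1e-6))
}

#' Second moment of area of the probe cross-section
#'
#' For a hollow circular section, `I_z = pi/64 (D_p^4 - d_p^4)`.
#'
#' @param spec A [probe_spec()].
#' @return Moment of inertia in m^4.
#' @export
moment_of_inertia <- function(spec) {
  stopifnot(inherits(spec, "probe_spec"))
  pi / 64 * (spec$outer_diameter^4 - spec$inner_diameter^4)
}

#' Cantilever spring stiffness at the tip
#'
#' Small-deflection Euler-Bernoulli stiffness relating the force applied at
#' the mount position `l` to the deflection observed at the tip `L_p`:
#' `k = 6 E I_z / (l^2 (3 L_p - l))`. The magnitude is returned; positive
#' deflection is toward the moving probe (restoring stiffness positive).
#'
#' @param spec A [probe_spec()].
#' @return Stiffness in N/m.
#' @export
probe_stiffness <- function(spec) {
  stopifnot(inherits(spec, "probe_spec"))
  Iz <- moment_of_inertia(spec)
  l <- spec$mount_position
  6 * spec$material_modulus * Iz / (l^2 * (3 * spec$probe_length - l))
}

#' Force corresponding to one pixel of tip deflection
#'
#' @param spec A [probe_spec()].
#' @return Force in N per pixel (`k * pixel_size`).
#' @export
force_per_pixel <- function(spec) {
  probe_stiffness(spec) * spec$pixel_size
}

#' Force from a pixel-quantized tip deflection
#'
#' The optical readout reports the tip deflection as an integer number of
#' pixels; the sensed force is an integral multiple of the per-pixel force,
#' `F_s = k * pixel_size * n_px`.
#'
#' @param spec A [probe_spec()].
#' @param tip_deflection_pixels Non-negative integer pixel count (vector ok).
#' @return Force in N.
#' @export
force_from_deflection <- function(spec, tip_deflection_pixels) {
  stopifnot(inherits(spec, "probe_spec"))
  px <- tip_deflection_pixels
  if (any(px < 0)) stop("negative pixel count")
  if (any(px != round(px))) stop("tip deflection must be an integer pixel count")
  force_per_pixel(spec) * px
}

#' Quantize a continuous tip deflection to integer pixels
#'
#' The sensed force is reported as an integral multiple of pixels:
#' `n_px = floor(|x| / pixel_size)`, carrying the sign of `x`.
#'
#' @param spec A [probe_spec()].
#' @param deflection Tip deflection in metres (vector ok).
#' @return Integer pixel count (signed).
#' @export
quantize_deflection <- function(spec, deflection) {
  sign(deflection) * floor(abs(deflection) / spec$pixel_size)
}

#' Per-pixel force resolution after rescaling the probe length
#'
#' Rescales `L_p` and `l` by a common factor at fixed load-position ratio
#' `l / L_p`: the tip stiffness, and with it the per-pixel force, scales as
#' `length_scale^-3`. Halving a probe with 0.11 µN/px resolution therefore
#' yields 0.88 µN/px.
#'
#' @param x A [probe_spec()], or a bare numeric force-per-pixel (N/px).
#' @param length_scale Positive ratio of new to old probe length.
#' @return For a `probe_spec`, the rescaled spec (use [force_per_pixel()] to
#'   read the resolution); for a numeric, the rescaled force per pixel.
#' @export
resolution_after_rescale <- function(x, length_scale) {
  if (!is.numeric(length_scale) || length_scale <= 0)
    stop("length_scale must be > 0")
  if (inherits(x, "probe_spec")) {
    probe_spec(outer_diameter = x$outer_diameter,
               inner_diameter = x$inner_diameter,
               probe_length = x$probe_length * length_scale,
               mount_position = x$mount_position * length_scale,
               pixel_size = x$pixel_size,
               material_modulus = x$material_modulus)
  } else if (is.numeric(x)) {
    x * length_scale^(-3)
  } else {
    stop("x must be a probe_spec or a numeric force per pixel")
  }
}
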