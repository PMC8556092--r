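#' Phenomenological pristine-Bragg-curve beam model
#'
#' A plateau-plus-Gaussian-peak description of a pristine carbon-ion depth-
#' ionization curve, sufficient for exercising peak localization and
#' effective-point shift recovery (it is not a transport model: no
#' fragmentation tail, no LET or quenching effects). The range follows a
#' power law R = a * E^p; by default p = 1.7 and a is solved so that a 330
#' MeV/u beam peaks at 195.78 mm water-equivalent depth. The straggling
#' width defaults to 1% of the range and the entrance plateau to 25% of
#' the peak amplitude, rising gently toward the peak.
#'
#' @param energy Beam energy in MeV/u (> 0).
#' @param range_exp Range-energy exponent p (default 1.7).
#' @param range_coeff Coefficient a in mm/(MeV/u)^p; default anchored so
#'   R(330) = 195.78 mm.
#' @param peak_sigma Gaussian straggling width in mm (default 0.01 * R).
#' @param plateau_level Plateau height as a fraction of the peak, in
#'   \[0, 1) (default 0.25).
#' @param noise_sigma Relative multiplicative Gaussian noise on readings
#'   (default 0).
#' @param seed Integer seed for the noise generator.
#' @return Object of class `beam_model`.
#' @export
beam_model <- function(energy, range_exp = 1.7,
                       range_coeff = 195.78 / 330^range_exp,
                       peak_sigma = NULL, plateau_level = 0.25,
                       noise_sigma = 0, seed = 1L) {
  stopifnot(energy > 0, range_exp > 0, range_coeff > 0,
            plateau_level >= 0, plateau_level < 1, noise_sigma >= 0)
  R <- range_coeff * energy^range_exp
  if (is.null(peak_sigma)) peak_sigma <- 0.01 * R
  stopifnot(peak_sigma > 0)
  structure(list(energy = energy, range_exp = range_exp,
                 range_coeff = range_coeff, range_mm = R,
                 peak_sigma = peak_sigma, plateau_level = plateau_level,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "beam_model")
}

#' Range of a beam model
#' @param model A [beam_model()].
#' @return Water-equivalent range (peak depth) in mm.
#' @export
beam_range <- function(model) model$range_mm

# Noise-free curve shape: Gaussian straggling peak at R on top of a gently
# rising pedestal (entrance plateau continuing through the peak region as a
# crude stand-in for the distal fragment pedestal, so the baseline is
# locally symmetric about the peak); identically zero beyond R + 5 sigma.
# The pedestal slope (0.3 * plateau over the range) displaces the analytic
# maximum from R by ~ slope * sigma^2 / (1 - plateau), well under one grid
# step at the default settings.
.pristine_shape <- function(d, model) {
  R <- model$range_mm; s <- model$peak_sigma
  peak <- exp(-(d - R)^2 / (2 * s^2))
  pedestal <- model$plateau_level * (1 + 0.3 * d / R)
  y <- (1 - model$plateau_level) * peak + pedestal
  y[d > R + 5 * s] <- 0
  y
}

#' Generate a pristine synthetic depth-ionization curve
#'
#' Samples the beam model on a regular depth grid. Deterministic for a
#' fixed seed; the single global maximum lies at the model range within one
#' grid step; the plateau rises monotonically into the peak; readings are
#' identically zero beyond R + 5 * peak_sigma.
#'
#' @param model A [beam_model()].
#' @param step Depth grid step in mm; must not exceed `peak_sigma`.
#' @param depth_min,depth_max Grid limits in mm (defaults 0 and
#'   R + 8 * peak_sigma).
#' @return A [depth_curve()] with generator metadata.
#' @examples
#' cv <- generate_pristine(beam_model(330), step = 0.1)
#' find_peak_depth(cv) # ~195.78
#' @export
generate_pristine <- function(model, step = 0.1, depth_min = 0,
                              depth_max = NULL) {
  if (step > model$peak_sigma) {
    stop(sprintf("grid step %.3g mm is coarser than the straggling width %.3g mm; refine the grid",
                 step, model$peak_sigma), call. = FALSE)
  }
  if (is.null(depth_max)) depth_max <- model$range_mm + 8 * model$peak_sigma
  d <- seq(depth_min, depth_max, by = step)
  y <- .pristine_shape(d, model)
  if (model$noise_sigma > 0) {
    old <- .Random.seed_save()
    set.seed(model$seed)
    y <- pmax(y * (1 + stats::rnorm(length(y), sd = model$noise_sigma)), 0)
    .Random.seed_restore(old)
  }
  depth_curve(d, y, metadata = list(
    generator = "synthbeam", energy = model$energy,
    range_mm = model$range_mm, peak_sigma = model$peak_sigma,
    plateau_level = model$plateau_level, noise_sigma = model$noise_sigma,
    seed = model$seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Cylindrical-cavity response with an injected effective-point shift
#'
#' The detector response of a cylindrical air cavity of radius r plotted at
#' its geometric centre: readings are chord-length-weighted averages of the
#' pristine curve, kernel w(u) = 2 sqrt(r^2 - u^2) on u in \[-r, r\]
#' (normalized to unit mass), and the whole curve is then relabeled
#' downstream by `peff_ratio * r` - i.e. the effective point of measurement
#' sits that far upstream of the centre, so the centre-labelled peak
#' appears deeper than the reference peak by exactly the injected shift.
#'
#' @param r Cavity inner radius in mm (> 0).
#' @param peff_ratio Injected ground-truth shift ratio, |ratio| <= 1.
#' @return Object of class `cavity_response`.
#' @export
cavity_response <- function(r, peff_ratio) {
  stopifnot(r >= 0, abs(peff_ratio) <= 1)   # r = 0: identity response
  structure(list(r = r, peff_ratio = peff_ratio), class = "cavity_response")
}

#' Apply a cylindrical-cavity response to a pristine curve
#'
#' Volume-averages the curve with the chord kernel (Gauss-Legendre
#' quadrature over the cavity diameter, linear interpolation between grid
#' samples) and shifts the depth labels by the injected effective-point
#' displacement. With r -> 0 the transform is the identity; a symmetric
#' peak with zero injected shift keeps its peak depth. The curve must
#' extend at least r beyond both sides of its sampled range interior.
#'
#' @param curve A [depth_curve()].
#' @param response A [cavity_response()].
#' @param n_nodes Kernel quadrature nodes (default 64).
#' @return A [depth_curve()] on the restricted grid where the full kernel
#'   support is available, with ground-truth metadata attached.
#' @export
apply_cavity <- function(curve, response, n_nodes = 64) {
  r <- response$r
  if (r == 0) return(curve)
  dmin <- min(curve$depth_mm); dmax <- max(curve$depth_mm)
  keep <- curve$depth_mm >= dmin + r & curve$depth_mm <= dmax - r
  if (sum(keep) < 5L) {
    stop("curve does not extend at least r beyond the region of interest; ",
         "extend the depth grid", call. = FALSE)
  }
  gl <- gauss_nodes(n_nodes, -r, r)
  w <- gl$w * 2 * sqrt(pmax(r^2 - gl$x^2, 0))
  w <- w / sum(w)                       # unit kernel mass
  f <- stats::approxfun(curve$depth_mm, curve$reading, rule = 2)
  d <- curve$depth_mm[keep]
  y <- vapply(d, function(di) sum(w * f(di + gl$x)), numeric(1))
  meta <- curve_meta(curve)
  meta$cavity_r <- r
  meta$injected_peff_ratio <- response$peff_ratio
  depth_curve(d + response$peff_ratio * r, y, metadata = meta)
}

#' Generate a matched reference / cylindrical-chamber curve pair
#'
#' Convenience wrapper producing the plane-parallel reference curve and
#' the cavity-averaged, shift-injected cylindrical-chamber curve from one
#' beam model, sharing the same noise-free shape (noise, if any, is drawn
#' independently per curve from the model seed).
#'
#' @inheritParams generate_pristine
#' @param response A [cavity_response()].
#' @return List with elements `reference` and `test` ([depth_curve()]s).
#' @export
generate_pair <- function(model, response, step = 0.1) {
  reference <- generate_pristine(model, step = step)
  pristine <- generate_pristine(
    beam_model(model$energy, range_exp = model$range_exp,
               range_coeff = model$range_coeff, peak_sigma = model$peak_sigma,
               plateau_level = model$plateau_level, noise_sigma = 0),
    step = step,
    depth_max = model$range_mm + 8 * model$peak_sigma + 2 * response$r)
  test <- apply_cavity(pristine, response)
  if (model$noise_sigma > 0) {
    old <- .Random.seed_save()
    set.seed(model$seed + 1L)
    test <- depth_curve(test$depth_mm,
                        pmax(test$reading *
                             (1 + stats::rnorm(nrow(test), sd = model$noise_sigma)), 0),
                        metadata = curve_meta(test))
    .Random.seed_restore(old)
  }
  list(reference = reference, test = test)
}
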