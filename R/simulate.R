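#' Lognormal size law for Feret diameters
#'
#' @param mu Log-scale location (log-nm).
#' @param sigma Log-scale standard deviation (> 0).
#' @return An object of class `lognormal_size`; `mean_diameter()` gives
#'   `exp(mu + sigma^2/2)` and `median_diameter()` gives `exp(mu)`.
#' @export
lognormal_size <- function(mu, sigma) {
  stopifnot(is.numeric(mu), is.numeric(sigma), length(mu) == 1,
            length(sigma) == 1)
  if (sigma <= 0) stop("sigma must be positive")
  structure(list(mu = mu, sigma = sigma), class = "lognormal_size")
}

#' @rdname lognormal_size
#' @param size A `lognormal_size`.
#' @export
mean_diameter <- function(size) exp(size$mu + size$sigma^2 / 2)

#' @rdname lognormal_size
#' @export
median_diameter <- function(size) exp(size$mu)

#' @export
print.lognormal_size <- function(x, ...) {
  cat(sprintf("lognormal_size: mu = %.3f, sigma = %.3f (mean %.1f nm)\n",
              x$mu, x$sigma, mean_diameter(x)))
  invisible(x)
}

#' RSA model parameters
#'
#' Intensity plus the lognormal law of Feret diameters, and the convention
#' mapping a diameter to an exclusion radius. Under `half_feret` (default) a
#' synapse is the sphere circumscribing the junction, so two synapses must
#' satisfy `||c_k - c_l|| >= (D_k + D_l)/2`; `full_feret` doubles the
#' exclusion radii.
#'
#' @param intensity Target intensity, synapses/um^3 (> 0).
#' @param size A [lognormal_size()].
#' @param radius_convention `"half_feret"` or `"full_feret"`.
#' @return An object of class `rsa_params`.
#' @export
rsa_params <- function(intensity, size,
                       radius_convention = c("half_feret", "full_feret")) {
  radius_convention <- match.arg(radius_convention)
  stopifnot(inherits(size, "lognormal_size"))
  if (intensity <= 0) stop("intensity must be positive")
  structure(list(intensity = intensity, size = size,
                 radius_convention = radius_convention),
            class = "rsa_params")
}

radius_factor <- function(params)
  if (params$radius_convention == "half_feret") 0.5 else 1.0

#' Simulate complete spatial randomness
#'
#' Homogeneous Poisson process in a box window; with `fixed_n = TRUE` the
#' count is fixed at `round(intensity * volume)` (a binomial process).
#'
#' @param box A [box3d()].
#' @param intensity Intensity, synapses/um^3.
#' @param seed Optional integer seed (ambient RNG restored afterwards).
#' @param fixed_n Fix the count instead of drawing it Poisson.
#' @param sample_id Identifier for the simulated pattern.
#' @return A [pp3_pattern()] without Feret diameters.
#' @export
simulate_csr <- function(box, intensity, seed = NULL, fixed_n = FALSE,
                         sample_id = "csr") {
  if (volume_um3(box) <= 0) stop("zero-volume box")
  with_seed(seed, {
    lam <- intensity * volume_um3(box)
    n <- if (fixed_n) round(lam) else rpois(1, lam)
    pp3_pattern(x = box$origin[1] + runif(n) * box$side_lengths[1],
                y = box$origin[2] + runif(n) * box$side_lengths[2],
                z = box$origin[3] + runif(n) * box$side_lengths[3],
                box = box, sample_id = sample_id)
  })
}

#' Simulate a random sequential adsorption hard-sphere process
#'
#' Spheres with lognormal Feret diameters are added one at a time at uniform
#' locations; a candidate intersecting any accepted sphere is discarded and
#' a fresh location *and* diameter are drawn. Placement continues until the
#' target count `round(intensity * volume)` is reached.
#'
#' @param box A [box3d()].
#' @param params An [rsa_params()].
#' @param seed Optional integer seed.
#' @param max_consecutive_rejections Jamming guard: abort with an error of
#'   class `rsa_jamming` after this many consecutive rejections.
#' @param sample_id Identifier for the simulated pattern.
#' @return A [pp3_pattern()] whose points carry their sampled diameters; no
#'   pair of points violates the exclusion constraint.
#' @export
simulate_rsa <- function(box, params, seed = NULL,
                         max_consecutive_rejections = 10000,
                         sample_id = "rsa") {
  stopifnot(inherits(params, "rsa_params"))
  target <- round(params$intensity * volume_um3(box))
  with_seed(seed, {
    sim <- cpp_rsa(box$side_lengths, box$origin, target,
                   params$size$mu, params$size$sigma, radius_factor(params),
                   as.integer(max_consecutive_rejections))
    if (isTRUE(sim$jammed)) {
      cond <- structure(
        class = c("rsa_jamming", "error", "condition"),
        list(message = sprintf(
          "RSA simulation jammed: placed %d of %d points (%d consecutive rejections)",
          length(sim$x), target, max_consecutive_rejections),
          call = sys.call(-1), achieved = length(sim$x), target = target))
      stop(cond)
    }
    pp3_pattern(x = sim$x, y = sim$y, z = sim$z, feret = sim$feret,
                box = box, sample_id = sample_id)
  })
}

#' Randomly thin a pattern to a target intensity
#'
#' Keeps a uniformly random subset (without replacement) of size
#' `round(target_intensity * volume)`; retained points keep their
#' coordinates and diameters, so a hard-core pattern stays hard-core.
#'
#' @param p A [pp3_pattern()].
#' @param target_intensity Target intensity, synapses/um^3; at most the
#'   current intensity.
#' @param seed Optional integer seed.
#' @return The thinned [pp3_pattern()].
#' @export
thin_to_intensity <- function(p, target_intensity, seed = NULL) {
  m <- round(target_intensity * volume_um3(p$box))
  if (m > npoints(p))
    stop("target intensity exceeds the current intensity")
  with_seed(seed, {
    keep <- sort(sample.int(npoints(p), m))
    pp3_pattern(x = p$points$x[keep], y = p$points$y[keep],
                z = p$points$z[keep], feret = p$points$feret[keep],
                box = p$box, layer = p$layer, animal = p$animal,
                sample_id = p$sample_id)
  })
}

#' Maximum-likelihood lognormal fit of Feret diameters
#'
#' `mu` is the mean of log diameters and `sigma` the population (maximum
#' likelihood, divisor n) standard deviation of log diameters.
#'
#' @param diameters Numeric vector of at least two strictly positive nm
#'   values, not all identical.
#' @return A [lognormal_size()].
#' @export
fit_lognormal <- function(diameters) {
  diameters <- diameters[!is.na(diameters)]
  if (length(diameters) < 2) stop("at least two diameters are required")
  if (any(diameters <= 0)) stop("diameters must be positive")
  lg <- log(diameters)
  mu <- mean(lg)
  sigma <- sqrt(mean((lg - mu)^2))
  if (sigma == 0) stop("zero variance: all diameters identical")
  lognormal_size(mu, sigma)
}
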