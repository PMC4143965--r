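#' Specification of one synthetic layer
#'
#' @param label Layer label (`"I"`..`"VI"`).
#' @param intensity Layer intensity, synapses/um^3.
#' @param size A [lognormal_size()] Feret-diameter law.
#' @param n_samples Number of replicate samples.
#' @param box_sides Sample window sides, nm.
#' @param core_scale Multiplier applied to simulated diameters, for
#'   contrast layers with inflated exclusion cores (>= 1; 1 = standard).
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(label, intensity, size, n_samples, box_sides,
                       core_scale = 1) {
  stopifnot(intensity > 0, n_samples >= 1, core_scale >= 1,
            inherits(size, "lognormal_size"))
  structure(list(label = label, intensity = intensity, size = size,
                 n_samples = n_samples, box_sides = as.numeric(box_sides),
                 core_scale = core_scale),
            class = "layer_spec")
}

#' Default synthetic study specification
#'
#' Six layers with the reference per-layer intensities and sample counts
#' (see [cortex_layer_means()]), the shared lognormal size law
#' (mu = 5.911, sigma = 0.404), and box windows with the 7.6 x 5.7 um
#' field of view and a whole number of 20 nm sections chosen so that each
#' layer's window volume matches its reference mean sample volume.
#'
#' @param core_scale_I Diameter multiplier for the layer I analogue
#'   (1 = standard; > 1 emulates the slightly stronger repulsion seen in
#'   layer I).
#' @return List of six [layer_spec()] objects.
#' @export
default_study_spec <- function(core_scale_I = 1) {
  means <- cortex_layer_means()
  n_samples <- c(2, 3, 10, 3, 3, 4)
  size <- cortex_global_size()
  fov <- c(7600, 5700)
  lapply(seq_len(6), function(k) {
    depth_nm <- means$mean_volume_um3[k] * NM3_PER_UM3 / prod(fov)
    sections <- round(depth_nm / 20)
    layer_spec(means$layer[k], means$mean_density[k], size, n_samples[k],
               c(fov, sections * 20),
               core_scale = if (k == 1) core_scale_I else 1)
  })
}

#' Generate a synthetic replicated study
#'
#' Each sample is an independent RSA simulation at its layer's intensity
#' and size law (diameters multiplied by the layer's `core_scale`);
#' animals are assigned round-robin over three identifiers so that
#' by-animal replicated tests can run.
#'
#' @param spec List of [layer_spec()]s, e.g. [default_study_spec()].
#' @param seed Optional master seed; each sample uses a derived sub-seed.
#' @param radius_convention See [rsa_params()].
#' @return A [study_collection()].
#' @export
generate_study <- function(spec = default_study_spec(), seed = NULL,
                           radius_convention = "half_feret") {
  animals <- c("r1", "r2", "r3")
  counter <- 0
  pats <- list()
  for (ls in spec) {
    stopifnot(inherits(ls, "layer_spec"))
    # diameters x core_scale <=> shifting mu by log(core_scale)
    size <- lognormal_size(ls$size$mu + log(ls$core_scale), ls$size$sigma)
    params <- rsa_params(ls$intensity, size, radius_convention)
    box <- box3d(ls$box_sides)
    for (s in seq_len(ls$n_samples)) {
      counter <- counter + 1
      p <- simulate_rsa(box, params,
                        seed = if (is.null(seed)) NULL
                        else derive_seed(seed, counter),
                        sample_id = as.character(s))
      p$layer <- ls$label
      p$animal <- animals[(counter - 1) %% 3 + 1]
      pats[[counter]] <- p
    }
  }
  study_collection(pats)
}
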