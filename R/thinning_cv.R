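#' Window for dense global simulations
#'
#' A box with the standard imaging field of view (7.6 x 5.7 um) and depth
#' chosen so that the volume equals `volume_um3` (300 um^3 by default).
#'
#' @param volume_um3 Target volume, um^3.
#' @param fov_nm Field of view (x, y), nm.
#' @return A [box3d()].
#' @export
dense_box <- function(volume_um3 = 300, fov_nm = c(7600, 5700)) {
  box3d(c(fov_nm, volume_um3 * NM3_PER_UM3 / prod(fov_nm)))
}

#' Global intensity from member sample intensities
#'
#' The global model is made 1% denser than the densest member sample,
#' rounded to one decimal (rounding is dropped if it would not exceed the
#' maximum member intensity).
#'
#' @param intensities Member sample intensities, synapses/um^3.
#' @param round_digits Decimal places for reporting-style rounding;
#'   `NULL` disables rounding.
#' @return Global intensity, synapses/um^3.
#' @export
lambda_global <- function(intensities, round_digits = 1) {
  lam <- 1.01 * max(intensities)
  if (!is.null(round_digits)) {
    r <- round(lam, round_digits)
    if (r > max(intensities)) lam <- r
  }
  lam
}

#' Fit a dense global RSA model to a set of layers
#'
#' Pools all member samples of the given layers: the size law is the
#' lognormal fit of all their Feret diameters, the intensity is
#' [lambda_global()] of the member intensities, and `n_dense` dense RSA
#' simulations are generated once in `volume_box` and reused (thinned
#' differently) for every held-out sample.
#'
#' @param study A [study_collection()].
#' @param layers Member layer labels.
#' @param volume_box Window of the dense simulations ([dense_box()]).
#' @param n_dense Number of dense simulations (198 = 99 central + 99
#'   envelope by default).
#' @param seed Optional integer seed.
#' @param round_digits Passed to [lambda_global()].
#' @param radius_convention See [rsa_params()].
#' @return An object of class `global_model` with fields `params`,
#'   `layers`, `dense` (list of patterns), `seed`.
#' @export
fit_global_model <- function(study, layers = c("II", "III", "IV", "V", "VI"),
                             volume_box = dense_box(), n_dense = 198,
                             seed = NULL, round_digits = 1,
                             radius_convention = "half_feret") {
  members <- study$patterns[study_layers(study) %in% layers]
  if (length(members) == 0) stop("no samples in the requested layers")
  lam_members <- vapply(members, estimate_intensity, numeric(1))
  lam <- lambda_global(lam_members, round_digits)
  if (any(lam <= lam_members))
    stop("global intensity must exceed every member sample intensity")
  d <- unlist(lapply(members, function(p) p$points$feret))
  size <- fit_lognormal(d[!is.na(d)])
  params <- rsa_params(lam, size, radius_convention)
  dense <- with_seed(seed, lapply(seq_len(n_dense), function(i)
    simulate_rsa(volume_box, params, sample_id = paste0("dense", i))))
  structure(list(params = params, layers = layers, dense = dense,
                 seed = seed),
            class = "global_model")
}

#' @export
print.global_model <- function(x, ...) {
  cat(sprintf(
    "global_model: lambda = %.3f /um^3, size (mu %.3f, sigma %.3f), %d dense simulations of %d points\n",
    x$params$intensity, x$params$size$mu, x$params$size$sigma,
    length(x$dense), npoints(x$dense[[1]])))
  invisible(x)
}

#' Thinning cross-validation for one held-out sample
#'
#' Tests whether the held-out sample is a thinned version of the common
#' dense model: the model's dense simulations are each randomly thinned to
#' the leave-one-out intensity \eqn{\hat\lambda_{ij}} of the sample's layer,
#' the first 99 thinned patterns give the central L curve, the second 99
#' the envelope half-width, and the sample's L function is checked against
#' the band.
#'
#' @param study A [study_collection()].
#' @param model A [fit_global_model()] result.
#' @param layer,sample_id Held-out sample (its layer must have >= 2
#'   samples and belong to the model).
#' @param seed Optional integer seed for the thinning draws.
#' @param grid Distance grid; default [default_grid()] of the sample's box.
#' @return An `envelope_result` (see [global_envelope_test()]).
#' @export
thinning_cv_run <- function(study, model, layer, sample_id, seed = NULL,
                            grid = NULL) {
  stopifnot(inherits(model, "global_model"))
  if (!layer %in% model$layers) stop("layer ", layer, " is not in the model")
  p <- get_sample(study, layer, sample_id)
  lam_hat <- loo_intensity(study, layer, sample_id)
  if (lam_hat > model$params$intensity)
    stop("leave-one-out intensity exceeds the global intensity")
  if (is.null(grid)) grid <- default_grid(p$box)
  check_grid(grid)
  observed <- l_from_k(k3_translation(p, grid))$values
  n_dense <- length(model$dense)
  n_central <- floor(n_dense / 2)
  with_seed(seed, {
    curves <- vapply(model$dense, function(dp)
      l_from_k(k3_translation(thin_to_intensity(dp, lam_hat), grid))$values,
      numeric(length(grid)))
    res <- envelope_from_l(grid, observed,
                           curves[, seq_len(n_central), drop = FALSE],
                           curves[, (n_central + 1):n_dense, drop = FALSE],
                           seed = seed)
    res$lambda_hat <- lam_hat
    res
  })
}

#' Thinning cross-validation sweep over all member samples
#'
#' Applies [thinning_cv_run()] to every sample of the model's layers and
#' tabulates the verdicts.
#'
#' @inheritParams thinning_cv_run
#' @param seed Optional master seed; each sample uses a derived sub-seed.
#' @return Data frame with columns `layer`, `sample_id`, `lambda_hat`,
#'   `n_thinned`, `reject`, `first_exceed_nm`.
#' @export
thinning_cv_sweep <- function(study, model, seed = NULL) {
  members <- which(study_layers(study) %in% model$layers)
  if (length(members) == 0) stop("empty member set")
  rows <- lapply(seq_along(members), function(k) {
    p <- study$patterns[[members[k]]]
    res <- thinning_cv_run(study, model, p$layer, p$sample_id,
                           seed = if (is.null(seed)) NULL
                           else derive_seed(seed, k))
    data.frame(layer = p$layer, sample_id = p$sample_id,
               lambda_hat = res$lambda_hat,
               n_thinned = round(res$lambda_hat *
                                   volume_um3(model$dense[[1]]$box)),
               reject = res$reject,
               first_exceed_nm = if (res$reject) min(res$exceed_distances)
               else NA_real_)
  })
  do.call(rbind, rows)
}
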