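#' Leave-one-out intensity estimate
#'
#' Volume-weighted aggregate intensity of the other samples of the same
#' layer:
#' \deqn{\hat\lambda_{ij} = \frac{\sum_{t \ne j} \lambda_{it} vol_{it}}
#'   {\sum_{t \ne j} vol_{it}}
#'   = \frac{\text{total count of other samples}}
#'   {\text{total volume of other samples}}.}
#'
#' @param study A [study_collection()].
#' @param layer Layer label of the held-out sample.
#' @param sample_id Identifier of the held-out sample.
#' @return Intensity in synapses/um^3.
#' @export
loo_intensity <- function(study, layer, sample_id) {
  others <- keep_others(study, layer, sample_id)
  counts <- vapply(others, npoints, numeric(1))
  vols <- vapply(others, function(p) volume_um3(p$box), numeric(1))
  pooled_intensity(counts, vols)
}

#' @rdname loo_intensity
#' @param counts,volumes Per-sample synapse counts and volumes (um^3).
#' @export
pooled_intensity <- function(counts, volumes) sum(counts) / sum(volumes)

keep_others <- function(study, layer, sample_id) {
  in_layer <- patterns_by_layer(study, layer)
  if (length(in_layer) < 2)
    stop("layer ", layer, " needs at least 2 samples for leave-one-out")
  ids <- vapply(in_layer, function(p) p$sample_id, character(1))
  if (!as.character(sample_id) %in% ids)
    stop("no sample ", sample_id, " in layer ", layer)
  in_layer[ids != as.character(sample_id)]
}

#' Leave-one-out lognormal size fit
#'
#' Fits the lognormal Feret-diameter law on the pooled diameters of the
#' remaining samples of the same layer.
#'
#' @inheritParams loo_intensity
#' @return A [lognormal_size()].
#' @export
loo_size <- function(study, layer, sample_id) {
  others <- keep_others(study, layer, sample_id)
  d <- unlist(lapply(others, function(p) p$points$feret))
  d <- d[!is.na(d)]
  if (length(d) < 2)
    stop("remaining samples of layer ", layer, " carry no Feret diameters")
  fit_lognormal(d)
}

# Envelope verdict from an observed L curve, a central curve and simulated
# L curves used for the half-width. Shared by global_envelope_test() and
# the thinning cross-validation.
envelope_from_l <- function(grid, observed, central_mat, envelope_mat,
                            seed = NULL) {
  central <- rowMeans(central_mat)
  w_max <- max(abs(envelope_mat - central))
  dev <- abs(observed - central)
  exceed <- grid[dev > w_max]
  structure(list(grid = grid, central = central, w_max = w_max,
                 observed = observed, reject = length(exceed) > 0,
                 exceed_distances = exceed,
                 n_central = ncol(central_mat),
                 n_envelope = ncol(envelope_mat), seed = seed),
            class = "envelope_result")
}

#' @export
print.envelope_result <- function(x, ...) {
  cat(sprintf(
    "global envelope test: %d + %d simulations, w_max = %.2f nm -> %s\n",
    x$n_central, x$n_envelope, x$w_max,
    if (x$reject) sprintf("REJECT (|L - Lbar| > w_max at %d distance(s), first %.0f nm)",
                          length(x$exceed_distances), min(x$exceed_distances))
    else "do not reject"))
  invisible(x)
}

#' Global envelope goodness-of-fit test against an RSA null
#'
#' Simulates the null model in the pattern's own window. The first
#' `n_central` simulations give the central curve `Lbar` (pointwise mean L);
#' `w_max` is the furthest deviation from `Lbar` of a *separate* set of
#' `n_envelope` simulated L functions, over the whole grid. The envelope is
#' the constant-width band `Lbar +/- w_max`, and the null is rejected when
#' the observed L leaves the band at any distance (two-sided).
#'
#' @param p Observed [pp3_pattern()].
#' @param null_params [rsa_params()] of the null model.
#' @param n_central,n_envelope Simulation counts (99 + 99 by default).
#' @param grid Distance grid; defaults to [default_grid()] of `p`'s box.
#' @param seed Optional integer seed governing all simulations.
#' @return An `envelope_result` with fields `grid`, `central`, `w_max`,
#'   `observed` (L values), `reject`, `exceed_distances`.
#' @export
global_envelope_test <- function(p, null_params, n_central = 99,
                                 n_envelope = 99, grid = default_grid(p$box),
                                 seed = NULL) {
  stopifnot(n_central >= 1, n_envelope >= 1)
  check_grid(grid)
  observed <- l_from_k(k3_translation(p, grid))$values
  with_seed(seed, {
    sims <- simulate_l_curves(p$box, null_params, n_central + n_envelope,
                              grid)
    envelope_from_l(grid, observed, sims[, seq_len(n_central), drop = FALSE],
                    sims[, n_central + seq_len(n_envelope), drop = FALSE],
                    seed = seed)
  })
}

# n RSA simulations -> matrix of L curves (length(grid) x n), in the ambient
# RNG stream.
simulate_l_curves <- function(box, params, n, grid) {
  vapply(seq_len(n), function(i) {
    sim <- simulate_rsa(box, params, sample_id = paste0("sim", i))
    l_from_k(k3_translation(sim, grid))$values
  }, numeric(length(grid)))
}

#' Per-sample RSA goodness-of-fit with leave-one-out parameters
#'
#' For the held-out sample, the null intensity is [loo_intensity()] and the
#' size law [loo_size()] of the remaining samples of the layer (so the
#' Monte-Carlo test does not reuse the tested data for estimation), then
#' [global_envelope_test()] is applied.
#'
#' @inheritParams loo_intensity
#' @inheritParams global_envelope_test
#' @param radius_convention Exclusion-radius convention, see [rsa_params()].
#' @return An `envelope_result`.
#' @export
loo_envelope_test <- function(study, layer, sample_id, n_central = 99,
                              n_envelope = 99, grid = NULL, seed = NULL,
                              radius_convention = "half_feret") {
  p <- get_sample(study, layer, sample_id)
  params <- rsa_params(loo_intensity(study, layer, sample_id),
                       loo_size(study, layer, sample_id),
                       radius_convention)
  if (is.null(grid)) grid <- default_grid(p$box)
  global_envelope_test(p, params, n_central, n_envelope, grid, seed)
}

#' Plot an envelope test result
#'
#' Observed L in blue, central curve in green, the constant-width band
#' shaded, and the CSR diagonal dashed red, mirroring the usual
#' goodness-of-fit display.
#'
#' @param x An `envelope_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.envelope_result <- function(x, ...) {
  lo <- x$central - x$w_max
  hi <- x$central + x$w_max
  plot(x$grid, x$observed, type = "n",
       ylim = range(lo, hi, x$observed, x$grid),
       xlab = "d (nm)", ylab = "L(d) (nm)", ...)
  polygon(c(x$grid, rev(x$grid)), c(lo, rev(hi)), border = NA,
          col = adjustcolor("grey60", 0.5))
  abline(0, 1, lty = 2, col = "red")
  lines(x$grid, x$central, col = "darkgreen")
  lines(x$grid, x$observed, col = "blue")
  legend("topleft", bty = "n", lty = c(1, 1, 2), cex = 0.8,
         col = c("blue", "darkgreen", "red"),
         legend = c("observed", "simulation mean", "CSR"))
  invisible(x)
}
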