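#' Largest common subsampling box
#'
#' Box with the componentwise minimum side lengths over all samples, so it
#' fits inside every sample window.
#'
#' @param study A [study_collection()].
#' @return A [box3d()] at the origin.
#' @export
min_box <- function(study) {
  sides <- vapply(study$patterns, function(p) p$box$side_lengths,
                  numeric(3))
  box3d(apply(sides, 1, min))
}

#' Fixed-box density subsampling within a layer
#'
#' Each repetition picks a sample of the layer uniformly at random (with
#' replacement across repetitions), places the box uniformly among the
#' positions where it fits, counts the centroids falling in the half-open
#' box, and records count / box volume.
#'
#' @param study A [study_collection()].
#' @param layer Layer label.
#' @param box Subsampling window, typically [min_box()].
#' @param n_rep Number of repetitions (50 by default).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_rep` densities, synapses/um^3.
#' @export
subsample_densities <- function(study, layer, box = min_box(study),
                                n_rep = 50, seed = NULL) {
  pats <- patterns_by_layer(study, layer)
  if (length(pats) == 0) stop("no samples in layer ", layer)
  slack <- lapply(pats, function(p) p$box$side_lengths - box$side_lengths)
  if (any(unlist(slack) < 0))
    stop("subsampling box does not fit inside every sample of layer ", layer)
  vol <- volume_um3(box)
  with_seed(seed, vapply(seq_len(n_rep), function(r) {
    i <- sample.int(length(pats), 1)
    p <- pats[[i]]
    lo <- p$box$origin + runif(3) * slack[[i]]
    hi <- lo + box$side_lengths
    inside <- p$points$x >= lo[1] & p$points$x < hi[1] &
      p$points$y >= lo[2] & p$points$y < hi[2] &
      p$points$z >= lo[3] & p$points$z < hi[3]
    sum(inside) / vol
  }, numeric(1)))
}

#' Subsampled density draws for every layer
#'
#' @inheritParams subsample_densities
#' @param seed Optional master seed; each layer uses a derived sub-seed.
#' @return Data frame with columns `layer` and `density`
#'   (`n_rep` rows per layer), with the box recorded as an attribute.
#' @export
density_draws <- function(study, box = min_box(study), n_rep = 50,
                          seed = NULL) {
  layers <- sort(unique(study_layers(study)))
  out <- do.call(rbind, lapply(seq_along(layers), function(k)
    data.frame(layer = layers[k],
               density = subsample_densities(
                 study, layers[k], box, n_rep,
                 seed = if (is.null(seed)) NULL else derive_seed(seed, k)))))
  attr(out, "box") <- box
  out
}

#' Kruskal-Wallis comparison of per-layer density draws
#'
#' Rank-based H statistic with tie correction and chi-square p-value. The
#' fully degenerate case (every value identical) is reported as H = 0,
#' p = 1.
#'
#' @param draws Data frame with columns `layer` (or any grouping column
#'   named `layer`) and `density`, as from [density_draws()].
#' @return List with `H`, `df` and `p_value`.
#' @export
kruskal_wallis_draws <- function(draws) {
  g <- factor(draws$layer)
  if (nlevels(g) < 2) stop("at least two groups are required")
  if (length(unique(draws$density)) == 1)
    return(list(H = 0, df = nlevels(g) - 1L, p_value = 1))
  kt <- kruskal.test(draws$density, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Pairwise Mann-Whitney tests with Bonferroni adjustment
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test for every pair of
#' groups; p-values are multiplied by the number of pairs and capped at 1.
#' Exact enumeration is used for small untied groups (both sizes at most
#' `exact_max_n`), the normal approximation with tie correction otherwise.
#'
#' @inheritParams kruskal_wallis_draws
#' @param exact_max_n Largest group size for exact enumeration.
#' @return Symmetric matrix of adjusted p-values (diagonal `NA`).
#' @export
pairwise_mw_bonferroni <- function(draws, exact_max_n = 8) {
  g <- factor(draws$layer)
  lv <- levels(g)
  if (length(lv) < 2) stop("at least two groups are required")
  pairs <- utils::combn(lv, 2)
  raw <- apply(pairs, 2, function(pr) {
    a <- draws$density[g == pr[1]]
    b <- draws$density[g == pr[2]]
    exact <- max(length(a), length(b)) <= exact_max_n &&
      !anyDuplicated(c(a, b))
    suppressWarnings(wilcox.test(a, b, exact = exact)$p.value)
  })
  adj <- pmin(raw * ncol(pairs), 1)
  out <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (k in seq_len(ncol(pairs))) {
    out[pairs[1, k], pairs[2, k]] <- adj[k]
    out[pairs[2, k], pairs[1, k]] <- adj[k]
  }
  out
}

#' Levene homoscedasticity check (report only)
#'
#' The rank-based pipeline is used regardless; this reports whether the
#' equal-variance assumption of ANOVA would have held for the draws.
#'
#' @inheritParams kruskal_wallis_draws
#' @return One-row data frame with the Levene F statistic and p-value.
#' @export
levene_check <- function(draws) {
  lt <- car::leveneTest(draws$density, factor(draws$layer))
  data.frame(F = lt[1, "F value"], p_value = lt[1, "Pr(>F)"])
}
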