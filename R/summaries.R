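#' Distance grid for summary functions
#'
#' Equally spaced distances starting at 0. The default upper limit is a
#' quarter of the shortest box side: the translation correction degrades and
#' the set covariance approaches zero as distances approach the box
#' dimensions.
#'
#' @param box A [box3d()].
#' @param n Number of grid points.
#' @param r_max Largest distance, nm; default `0.25 * min(side_lengths)`.
#' @return Numeric vector of distances, nm.
#' @export
default_grid <- function(box, n = 128, r_max = 0.25 * min(box$side_lengths)) {
  seq(0, r_max, length.out = n)
}

check_grid <- function(grid) {
  if (length(grid) < 2 || grid[1] != 0 || any(diff(grid) <= 0))
    stop("grid must be strictly increasing and start at 0")
  invisible(grid)
}

#' Summary-function container
#'
#' Holds K or L values on a distance grid, with the point count of the
#' pattern that produced them.
#'
#' @param grid Distance grid, nm.
#' @param values Function values (nm^3 for K, nm for L).
#' @param kind `"K"` or `"L"`.
#' @param n_points Point count used (NA for theoretical curves).
#' @return An object of class `summary_fn`.
#' @export
summary_fn <- function(grid, values, kind = c("K", "L"), n_points = NA) {
  kind <- match.arg(kind)
  stopifnot(length(grid) == length(values))
  structure(list(grid = as.numeric(grid), values = as.numeric(values),
                 kind = kind, n_points = n_points),
            class = "summary_fn")
}

#' @export
print.summary_fn <- function(x, ...) {
  cat(sprintf("summary_fn (%s): %d grid points, r in [0, %.0f] nm, n = %s\n",
              x$kind, length(x$grid), max(x$grid), format(x$n_points)))
  invisible(x)
}

#' @export
as.data.frame.summary_fn <- function(x, ...)
  data.frame(d_nm = x$grid, value = x$values)

#' Set covariance of a box window
#'
#' `gamma_B(v) = vol(B intersect (B - v))`; for an axis-aligned box this is
#' the product of the clipped side lengths.
#'
#' @param box A [box3d()].
#' @param v Translation vector, nm (length 3).
#' @return Volume in nm^3.
#' @examples
#' set_covariance(box3d(c(1000, 1000, 1000)), c(100, 0, 0))  # 9e8
#' @export
set_covariance <- function(box, v) {
  stopifnot(length(v) == 3)
  prod(pmax(0, box$side_lengths - abs(v)))
}

#' Translation edge-corrected 3D Ripley K function
#'
#' Estimates
#' \deqn{\hat K(d) = \frac{vol(B)^2}{N^2} \sum_{k} \sum_{l \neq k}
#'   \frac{1\{\|x_k - x_l\| \le d\}}{\gamma_B(x_k - x_l)}}
#' on the supplied distance grid, using the Miles-Lantuejoul-Stoyan-Hanisch
#' translation correction for an axis-aligned box window. Note the `N^2`
#' normalisation (not `N(N-1)`).
#'
#' @param p A [pp3_pattern()] with at least two points.
#' @param grid Distance grid (see [default_grid()]).
#' @param r_max_frac Largest admissible `max(grid)` as a fraction of the
#'   shortest box side; raising it beyond the default 0.25 is allowed but
#'   the correction becomes increasingly variable.
#' @return A [summary_fn()] of kind `"K"`.
#' @export
k3_translation <- function(p, grid = default_grid(p$box), r_max_frac = 0.25) {
  if (npoints(p) < 2) stop("at least two points are required")
  check_grid(grid)
  if (max(grid) > r_max_frac * min(p$box$side_lengths) + 1e-9)
    stop("grid exceeds r_max policy (", r_max_frac,
         " of the shortest box side); pass a larger r_max_frac explicitly")
  K <- cpp_k3_translation(as.matrix(p$points[, c("x", "y", "z")]),
                          p$box$side_lengths, as.numeric(grid))
  summary_fn(grid, K, "K", npoints(p))
}

#' Theoretical K function of complete spatial randomness
#'
#' `K_CSR(d) = (4/3) pi d^3` for the homogeneous Poisson process in 3D.
#'
#' @param grid Distance grid, nm.
#' @return A [summary_fn()] of kind `"K"`.
#' @export
k_csr <- function(grid) {
  check_grid(grid)
  summary_fn(grid, (4 / 3) * pi * grid^3, "K", NA)
}

#' Besag L transform
#'
#' `L(d) = (3 K(d) / (4 pi))^(1/3)`; maps the CSR K function to the
#' diagonal `L(d) = d` and approximately stabilises the estimator variance.
#'
#' @param K A [summary_fn()] of kind `"K"` with non-negative values.
#' @return A [summary_fn()] of kind `"L"`.
#' @export
l_from_k <- function(K) {
  stopifnot(inherits(K, "summary_fn"), K$kind == "K")
  if (any(K$values < 0)) stop("negative K values")
  summary_fn(K$grid, (3 * K$values / (4 * pi))^(1 / 3), "L", K$n_points)
}

#' Serialise a summary function to CSV with a JSON header sidecar
#'
#' @param s A [summary_fn()].
#' @param path CSV path (`d_nm,value`); a JSON sidecar records kind and
#'   point count.
#' @export
write_summary_fn <- function(s, path) {
  write.table(data.frame(d_nm = fmt_num(s$grid), value = fmt_num(s$values)),
              path, sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(kind = s$kind, n_points = s$n_points),
                       sidecar_path(path), auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_summary_fn
#' @export
read_summary_fn <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  df <- read.csv(path, colClasses = "numeric")
  summary_fn(df$d_nm, df$value, meta$kind, meta$n_points %||% NA)
}
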