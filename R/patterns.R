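#' Axis-aligned 3D box window
#'
#' Observation window for a 3D point pattern: a rectangular box given by its
#' side lengths and origin, in nanometres.
#'
#' @param side_lengths Numeric vector of length 3, side lengths in nm
#'   (all > 0).
#' @param origin Numeric vector of length 3, lower corner in nm.
#'
#' @return An object of class `box3d` with fields `side_lengths` and `origin`.
#' @examples
#' b <- box3d(c(7600, 5700, 5000))
#' volume_um3(b)
#' @export
box3d <- function(side_lengths, origin = c(0, 0, 0)) {
  side_lengths <- as.numeric(side_lengths)
  origin <- as.numeric(origin)
  stopifnot(length(side_lengths) == 3, length(origin) == 3,
            all(is.finite(side_lengths)), all(is.finite(origin)))
  if (any(side_lengths <= 0)) stop("box side lengths must be positive")
  structure(list(side_lengths = side_lengths, origin = origin),
            class = "box3d")
}

#' @rdname box3d
#' @param box A `box3d`.
#' @export
volume_nm3 <- function(box) prod(box$side_lengths)

#' @rdname box3d
#' @export
volume_um3 <- function(box) volume_nm3(box) / NM3_PER_UM3

#' @export
print.box3d <- function(x, ...) {
  cat(sprintf("box3d: %.0f x %.0f x %.0f nm (%.2f um^3)\n",
              x$side_lengths[1], x$side_lengths[2], x$side_lengths[3],
              volume_um3(x)))
  invisible(x)
}

#' 3D synaptic point pattern
#'
#' A point pattern of synapse centroids inside a [box3d()] window, optionally
#' carrying a Feret diameter (the diameter of the smallest circumscribing
#' sphere of the reconstructed synaptic junction) per point, plus layer,
#' animal and sample identifiers. Box membership is half-open:
#' `origin <= coord < origin + side` on every axis.
#'
#' @param x,y,z Numeric vectors of centroid coordinates, nm.
#' @param box A [box3d()] window.
#' @param feret Optional numeric vector of Feret diameters, nm (`NA` allowed;
#'   positive where present).
#' @param layer Optional cortical layer label, one of `"I"`..`"VI"`.
#' @param animal Optional animal identifier.
#' @param sample_id Sample identifier.
#'
#' @return An object of class `pp3pattern` with fields `points` (data frame
#'   `x`, `y`, `z`, `feret`), `box`, `layer`, `animal`, `sample_id`.
#' @examples
#' p <- pp3_pattern(x = 500, y = 500, z = 500, feret = 400,
#'                  box = box3d(c(1000, 1000, 1000)), sample_id = "demo")
#' npoints(p)
#' @export
pp3_pattern <- function(x = numeric(), y = numeric(), z = numeric(),
                        box, feret = NULL, layer = NULL, animal = NULL,
                        sample_id = "sample") {
  stopifnot(inherits(box, "box3d"))
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("x, y, z must have equal length")
  if (is.null(feret)) feret <- rep(NA_real_, n)
  feret <- as.numeric(feret)
  if (length(feret) != n) stop("feret must match the number of points")
  if (any(!is.na(feret) & feret <= 0))
    stop("Feret diameters must be positive where present")
  if (!is.null(layer)) {
    layer <- as.character(layer)
    if (!layer %in% c("I", "II", "III", "IV", "V", "VI"))
      stop("layer must be one of I..VI")
  }
  lo <- box$origin
  hi <- box$origin + box$side_lengths
  inside <- x >= lo[1] & x < hi[1] & y >= lo[2] & y < hi[2] &
    z >= lo[3] & z < hi[3]
  if (n > 0 && !all(inside))
    stop(sprintf("%d point(s) outside the box window", sum(!inside)))
  structure(list(points = data.frame(x = x, y = y, z = z, feret = feret),
                 box = box, layer = layer, animal = animal,
                 sample_id = as.character(sample_id)),
            class = "pp3pattern")
}

#' Number of points in a pattern
#' @param p A `pp3pattern`.
#' @export
npoints <- function(p) nrow(p$points)

#' @export
print.pp3pattern <- function(x, ...) {
  cat(sprintf("pp3pattern '%s'%s%s: %d points in %.2f um^3 (%.3f /um^3)\n",
              x$sample_id,
              if (is.null(x$layer)) "" else paste0(", layer ", x$layer),
              if (is.null(x$animal)) "" else paste0(", animal ", x$animal),
              npoints(x), volume_um3(x$box), estimate_intensity(x)))
  invisible(x)
}

#' Estimate the intensity of a pattern
#'
#' Intensity is the average number of points per unit volume,
#' `lambda = N / vol(B)`, reported in synapses per cubic micron.
#'
#' @param p A [pp3_pattern()].
#' @return Intensity in synapses/um^3.
#' @export
estimate_intensity <- function(p) {
  v <- volume_um3(p$box)
  if (v <= 0) stop("zero-volume box")
  npoints(p) / v
}

#' Correct a pattern for linear tissue shrinkage
#'
#' Tissue shrinks during processing for electron microscopy; measured
#' distances are restored to pre-processing scale by dividing every
#' coordinate, diameter and box side by the linear shrinkage factor
#' (default 0.90, giving a volume factor of 0.729).
#'
#' @param p A [pp3_pattern()].
#' @param linear_factor Linear shrinkage factor in (0, 1].
#' @return The corrected `pp3pattern`.
#' @export
shrinkage_correct <- function(p, linear_factor = 0.90) {
  if (!is.numeric(linear_factor) || length(linear_factor) != 1 ||
      linear_factor <= 0 || linear_factor > 1)
    stop("linear_factor must be in (0, 1]")
  box <- box3d(p$box$side_lengths / linear_factor,
               p$box$origin / linear_factor)
  pp3_pattern(x = p$points$x / linear_factor,
              y = p$points$y / linear_factor,
              z = p$points$z / linear_factor,
              feret = p$points$feret / linear_factor,
              box = box, layer = p$layer, animal = p$animal,
              sample_id = p$sample_id)
}

#' Nearest-neighbour distances
#'
#' Distance from each centroid to its nearest other centroid, without edge
#' correction, as used for descriptive per-sample summaries.
#'
#' @param p A [pp3_pattern()] with at least two points.
#' @return Numeric vector of nm distances, one per point, in point order.
#' @export
nearest_neighbor_distances <- function(p) {
  if (npoints(p) < 2) stop("at least two points are required")
  cpp_nn_distances(as.matrix(p$points[, c("x", "y", "z")]))
}

# ---- I/O: CSV of points + JSON sidecar ------------------------------------

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

#' Read / write a pattern as CSV plus JSON sidecar
#'
#' The on-disk format is a CSV with header `x_nm,y_nm,z_nm,feret_nm` (the
#' `feret_nm` field may be empty) and a JSON sidecar of the same basename
#' holding `box_side_nm`, `box_origin_nm`, `layer`, `animal` and `sample_id`.
#' `write_pattern()` followed by `read_pattern()` restores every field
#' exactly.
#'
#' @param path Path of the CSV file; the sidecar lives next to it.
#' @return `read_pattern()` returns a [pp3_pattern()]; `write_pattern()`
#'   returns `path` invisibly.
#' @export
read_pattern <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing JSON sidecar: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  df <- read.csv(path, colClasses = "numeric")
  need <- c("x_nm", "y_nm", "z_nm", "feret_nm")
  if (!all(need %in% names(df)))
    stop("pattern CSV must have header x_nm,y_nm,z_nm,feret_nm")
  origin <- if (!is.null(meta$box_origin_nm)) meta$box_origin_nm else c(0, 0, 0)
  pp3_pattern(x = df$x_nm, y = df$y_nm, z = df$z_nm, feret = df$feret_nm,
              box = box3d(meta$box_side_nm, origin),
              layer = meta$layer, animal = meta$animal,
              sample_id = meta$sample_id)
}

#' @rdname read_pattern
#' @param p A [pp3_pattern()].
#' @export
write_pattern <- function(p, path) {
  df <- data.frame(x_nm = fmt_num(p$points$x), y_nm = fmt_num(p$points$y),
                   z_nm = fmt_num(p$points$z),
                   feret_nm = fmt_num(p$points$feret))
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  meta <- list(box_side_nm = p$box$side_lengths,
               box_origin_nm = p$box$origin,
               layer = p$layer, animal = p$animal, sample_id = p$sample_id)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

# ---- Study collections ----------------------------------------------------

#' Collection of replicated patterns
#'
#' Groups per-sample patterns for replicated-pattern analyses. The pair
#' (layer, sample_id) must be unique across the collection.
#'
#' @param patterns List of [pp3_pattern()] objects.
#' @return An object of class `study_collection`.
#' @export
study_collection <- function(patterns) {
  stopifnot(is.list(patterns), length(patterns) >= 1,
            all(vapply(patterns, inherits, logical(1), "pp3pattern")))
  key <- vapply(patterns, function(p)
    paste(p$layer %||% "", p$sample_id), character(1))
  if (anyDuplicated(key)) stop("(layer, sample_id) must be unique")
  structure(list(patterns = patterns), class = "study_collection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.study_collection <- function(x, ...) {
  cat(sprintf("study_collection: %d samples, layers %s\n",
              length(x$patterns),
              paste(sort(unique(study_layers(x))), collapse = ", ")))
  invisible(x)
}

#' @rdname study_collection
#' @param study A `study_collection`.
#' @export
study_layers <- function(study)
  vapply(study$patterns, function(p) p$layer %||% NA_character_, character(1))

#' @rdname study_collection
#' @export
study_animals <- function(study)
  vapply(study$patterns, function(p) p$animal %||% NA_character_, character(1))

#' @rdname study_collection
#' @param layer Layer label.
#' @export
patterns_by_layer <- function(study, layer)
  study$patterns[study_layers(study) == layer]

#' @rdname study_collection
#' @param animal Animal identifier.
#' @export
patterns_by_animal <- function(study, animal)
  study$patterns[study_animals(study) == animal]

#' @rdname study_collection
#' @param sample_id Sample identifier within `layer`.
#' @export
get_sample <- function(study, layer, sample_id) {
  hit <- which(study_layers(study) == layer &
                 vapply(study$patterns, function(p) p$sample_id,
                        character(1)) == as.character(sample_id))
  if (length(hit) != 1) stop("no unique sample ", sample_id,
                             " in layer ", layer)
  study$patterns[[hit]]
}

#' Read / write a study from a YAML manifest
#'
#' The manifest lists pattern CSV files (relative to the manifest's
#' directory); layer/animal/sample metadata live in each pattern's sidecar.
#'
#' @param manifest Path of the YAML manifest (`samples:` list of CSV paths).
#' @return A [study_collection()].
#' @export
read_study <- function(manifest) {
  m <- yaml::read_yaml(manifest)
  dir <- dirname(manifest)
  study_collection(lapply(m$samples, function(f)
    read_pattern(file.path(dir, f))))
}

#' @rdname read_study
#' @param study A [study_collection()].
#' @param dir Output directory (created if needed).
#' @export
write_study <- function(study, dir, manifest = "study.yaml") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- vapply(study$patterns, function(p) {
    f <- sprintf("%s_%s.csv", p$layer %||% "NA", p$sample_id)
    write_pattern(p, file.path(dir, f))
    f
  }, character(1))
  yaml::write_yaml(list(samples = as.list(files)), file.path(dir, manifest))
  invisible(file.path(dir, manifest))
}
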