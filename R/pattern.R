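#' Rectangular observation window
#'
#' An axis-aligned rectangle in micron coordinates. Most workflows use
#' `[0, Sx] x [0, Sy]`, but arbitrary offsets are supported so that patterns
#' can be translated without re-registering coordinates.
#'
#' @param xrange,yrange Numeric length-2 vectors, `c(min, max)` in microns.
#'   A single number `s` is shorthand for `c(0, s)`.
#' @return An object of class `shade_window`.
#' @export
shade_window <- function(xrange, yrange = xrange) {
  if (length(xrange) == 1) xrange <- c(0, xrange)
  if (length(yrange) == 1) yrange <- c(0, yrange)
  stopifnot(length(xrange) == 2, length(yrange) == 2,
            is.finite(xrange), is.finite(yrange))
  if (diff(xrange) <= 0 || diff(yrange) <= 0) {
    stopf("degenerate window: sides must have positive length")
  }
  structure(list(xrange = as.numeric(xrange), yrange = as.numeric(yrange)),
            class = "shade_window")
}

#' Area of a window in square microns
#' @param w A `shade_window`.
#' @return Numeric scalar.
#' @export
window_area <- function(w) {
  stopifnot(inherits(w, "shade_window"))
  diff(w$xrange) * diff(w$yrange)
}

as_window <- function(w) {
  if (inherits(w, "shade_window")) return(w)
  if (is.numeric(w) && length(w) == 2 && all(w > 0)) {
    return(shade_window(w[1], w[2]))
  }
  stopf("cannot interpret window; supply shade_window() or c(Sx, Sy)")
}

#' Multitype planar point pattern
#'
#' One image's cells: continuous micron coordinates plus a categorical cell
#' type per point, observed in a rectangular window. Empty patterns (zero
#' points) are allowed; the window is always required.
#'
#' @param x,y Numeric coordinate vectors (microns).
#' @param type Character or factor of cell-type labels, recycled if length 1.
#'   May be omitted for single-type patterns (all points labelled `"cell"`).
#' @param window A [shade_window()], or `c(Sx, Sy)` for a `[0,Sx] x [0,Sy]`
#'   rectangle.
#' @param levels Optional declared set of types (so a pattern can be empty in
#'   a type that is still "present" in the study).
#' @return An object of class `point_pattern` with elements `x`, `y`,
#'   `type` (factor) and `window`.
#' @export
point_pattern <- function(x, y, type = NULL, window, levels = NULL) {
  window <- as_window(window)
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  if (length(x) && (any(!is.finite(x)) || any(!is.finite(y)))) {
    stopf("non-finite coordinates")
  }
  inside <- x >= window$xrange[1] & x <= window$xrange[2] &
    y >= window$yrange[1] & y <= window$yrange[2]
  if (length(x) && !all(inside)) {
    stopf("%d point(s) fall outside the window", sum(!inside))
  }
  if (is.null(type)) type <- rep("cell", length(x))
  if (length(type) == 1 && length(x) != 1) type <- rep(type, length(x))
  stopifnot(length(type) == length(x))
  type <- factor(as.character(type), levels = levels %||% sort(unique(as.character(type))))
  if (length(x) && anyNA(type)) stopf("types outside the declared level set")
  structure(list(x = x, y = y, type = type, window = window),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern: %d points, window [%g, %g] x [%g, %g] um\n",
              length(x$x), x$window$xrange[1], x$window$xrange[2],
              x$window$yrange[1], x$window$yrange[2]))
  if (length(x$x)) print(table(x$type))
  invisible(x)
}

#' Number of points in a pattern
#' @param pp A `point_pattern`.
#' @param type Optional type label to count.
#' @return Integer count.
#' @export
n_points <- function(pp, type = NULL) {
  stopifnot(inherits(pp, "point_pattern"))
  if (is.null(type)) length(pp$x) else sum(pp$type == type)
}

#' Extract the sub-pattern of one type
#' @param pp A multitype `point_pattern`.
#' @param type Type label to keep.
#' @return A single-type `point_pattern` (same window).
#' @export
subset_type <- function(pp, type) {
  stopifnot(inherits(pp, "point_pattern"))
  keep <- pp$type == type
  point_pattern(pp$x[keep], pp$y[keep], rep(type, sum(keep)), pp$window)
}

coords_matrix <- function(pp) cbind(x = pp$x, y = pp$y)

same_window <- function(a, b, tol = 1e-9) {
  max(abs(a$xrange - b$xrange), abs(a$yrange - b$yrange)) <= tol
}

#' Study hierarchy: images nested in patients nested in cohorts
#'
#' @param image_id Character/integer vector of image identifiers (unique).
#' @param patient_id Patient identifier per image.
#' @param group_id Cohort identifier per image; must be constant within
#'   patient.
#' @return A `study_design` data frame with factor columns and attributes
#'   `patients` (patient -> cohort map) and `cohorts`.
#' @export
study_design <- function(image_id, patient_id, group_id) {
  stopifnot(length(image_id) == length(patient_id),
            length(image_id) == length(group_id))
  image_id <- as.character(image_id)
  if (anyDuplicated(image_id)) stopf("duplicated image ids")
  d <- data.frame(image_id = image_id,
                  patient_id = as.character(patient_id),
                  group_id = as.character(group_id),
                  stringsAsFactors = FALSE)
  map <- unique(d[, c("patient_id", "group_id")])
  if (anyDuplicated(map$patient_id)) {
    stopf("a patient maps to more than one cohort")
  }
  structure(d, class = c("study_design", "data.frame"),
            patients = map, cohorts = sort(unique(d$group_id)))
}

# integer (0-based) index maps used by the sampler
design_indices <- function(meta, image_ids) {
  meta <- meta[match(image_ids, meta$image_id), , drop = FALSE]
  if (anyNA(meta$image_id)) stopf("images missing from the study design")
  patients <- unique(meta$patient_id)
  cohorts <- sort(unique(meta$group_id))
  pat_of_img <- match(meta$patient_id, patients) - 1L
  coh_of_pat <- match(attr_group(meta, patients), cohorts) - 1L
  list(patients = patients, cohorts = cohorts,
       pat = pat_of_img, coh = coh_of_pat)
}

attr_group <- function(meta, patients) {
  meta$group_id[match(patients, meta$patient_id)]
}
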