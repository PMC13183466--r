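#' Regions of interest
#'
#' Lightweight ROI constructors used for the stimulus-indicator region and
#' for bouton/background fluorescence measurements. Coordinates are pixel
#' centers, 1-based, `x` = column and `y` = row. A pixel belongs to a
#' polygon when its center lies inside (even-odd rule; boundary pixels
#' follow the half-open convention of the ray-casting test).
#'
#' @param center Numeric `(x, y)` center.
#' @param radius Disk radius in pixels.
#' @param radii Numeric `(rx, ry)` ellipse semi-axes.
#' @param xmin,xmax,ymin,ymax Rectangle bounds (inclusive).
#' @param xs,ys Polygon vertex coordinates.
#' @return An object of class `roi`.
#' @name roi
NULL

#' @rdname roi
#' @export
roi_disk <- function(center, radius) {
  stopifnot(length(center) == 2, radius > 0)
  structure(list(type = "disk", center = as.numeric(center),
                 radius = as.numeric(radius)), class = "roi")
}

#' @rdname roi
#' @export
roi_ellipse <- function(center, radii) {
  stopifnot(length(center) == 2, length(radii) == 2, all(radii > 0))
  structure(list(type = "ellipse", center = as.numeric(center),
                 radii = as.numeric(radii)), class = "roi")
}

#' @rdname roi
#' @export
roi_rect <- function(xmin, xmax, ymin, ymax) {
  stopifnot(xmin <= xmax, ymin <= ymax)
  structure(list(type = "rect", xmin = xmin, xmax = xmax,
                 ymin = ymin, ymax = ymax), class = "roi")
}

#' @rdname roi
#' @export
roi_polygon <- function(xs, ys) {
  stopifnot(length(xs) == length(ys), length(xs) >= 3)
  structure(list(type = "polygon", xs = as.numeric(xs), ys = as.numeric(ys)),
            class = "roi")
}

#' Rasterize an ROI to a logical pixel mask
#'
#' @param roi An [roi] object, or a list of them (union).
#' @param dim Image dimensions `c(nrow, ncol)`.
#' @return Logical matrix of the given dimensions.
#' @export
roi_mask <- function(roi, dim) {
  if (is.list(roi) && !inherits(roi, "roi")) {
    m <- matrix(FALSE, dim[1], dim[2])
    for (r in roi) m <- m | roi_mask(r, dim)
    return(m)
  }
  stopifnot(inherits(roi, "roi"), length(dim) >= 2)
  nr <- dim[1]; nc <- dim[2]
  x <- matrix(rep(seq_len(nc), each = nr), nr, nc)  # column index
  y <- matrix(rep(seq_len(nr), nc), nr, nc)         # row index
  m <- switch(roi$type,
    disk = (x - roi$center[1])^2 + (y - roi$center[2])^2 <= roi$radius^2,
    ellipse = ((x - roi$center[1]) / roi$radii[1])^2 +
              ((y - roi$center[2]) / roi$radii[2])^2 <= 1,
    rect = x >= roi$xmin & x <= roi$xmax & y >= roi$ymin & y <= roi$ymax,
    polygon = matrix(points_in_polygon(as.vector(x), as.vector(y),
                                       roi$xs, roi$ys), nr, nc),
    stopf("unknown ROI type '%s'", roi$type))
  if (!any(m)) return(m)
  idx <- which(m, arr.ind = TRUE)
  if (min(idx) < 1 || max(idx[, 1]) > nr || max(idx[, 2]) > nc)
    stopf("ROI extends beyond image bounds")  # unreachable; kept for safety
  m
}

# even-odd ray casting, vectorized over query points
points_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read an ROI set from a JSON file
#'
#' The schema is a JSON object with arrays `bouton_rois` and
#' `background_rois`; each element has a `type` (`disk`, `ellipse`, `rect`,
#' `polygon`) plus the corresponding fields of the [roi] constructors.
#'
#' @param path JSON file path.
#' @return List with `bouton_rois` and `background_rois` (lists of [roi]).
#' @export
read_roi_set <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  parse1 <- function(s) {
    switch(s$type,
      disk = roi_disk(unlist(s$center), s$radius),
      ellipse = roi_ellipse(unlist(s$center), unlist(s$radii)),
      rect = roi_rect(s$xmin, s$xmax, s$ymin, s$ymax),
      polygon = roi_polygon(unlist(s$xs), unlist(s$ys)),
      stopf("unknown ROI type '%s' in %s", s$type, path))
  }
  list(bouton_rois = lapply(spec$bouton_rois, parse1),
       background_rois = lapply(spec$background_rois, parse1))
}
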