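#' Average-intensity projection of an image stack
#'
#' Collapses a multi-slice stack to a single image by the pixelwise
#' arithmetic mean, the projection used before ROI quantification of
#' confocal z-series.
#'
#' @param stack 3-D numeric array (`height x width x slices`), a list of
#'   matrices of identical size, or a single matrix (returned unchanged).
#' @return Numeric matrix.
#' @export
project_average <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (is.list(stack)) {
    d <- dim(stack[[1]])
    if (!all(vapply(stack, function(s) identical(dim(s), d), logical(1))))
      stopf("slices differ in shape")
    stack <- array(unlist(stack), c(d, length(stack)))
  }
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  if (dim(stack)[3] < 1) stopf("stack has no slices")
  rowMeans(stack, dims = 2)
}

#' Background-subtracted mean ROI fluorescence
#'
#' Mean intensity over the bouton ROIs minus the mean over background ROIs
#' placed adjacent to the terminal. By default bouton ROIs are pooled as a
#' pixel union before averaging; `per_roi = TRUE` averages each ROI first
#' and then averages the per-ROI means. A negative result (background
#' brighter than the boutons) is returned with a warning rather than an
#' error.
#'
#' @param image Numeric matrix (use [project_average()] first for stacks).
#' @param rois List with `bouton_rois` and `background_rois` (lists of
#'   [roi] objects), e.g. from [read_roi_set()].
#' @param per_roi Average per ROI before pooling (default `FALSE`).
#' @return Background-subtracted mean gray level.
#' @export
roi_background_subtracted_mean <- function(image, rois, per_roi = FALSE) {
  stopifnot(is.matrix(image))
  if (length(rois$bouton_rois) < 1 || length(rois$background_rois) < 1)
    stopf("need at least one bouton ROI and one background ROI")
  mean_of <- function(roi_list) {
    if (per_roi) {
      mean(vapply(roi_list, function(r) {
        m <- roi_mask(r, dim(image))
        if (!any(m)) stopf("an ROI covers no pixels")
        mean(image[m])
      }, numeric(1)))
    } else {
      m <- roi_mask(roi_list, dim(image))
      if (!any(m)) stopf("ROI union covers no pixels")
      mean(image[m])
    }
  }
  val <- mean_of(rois$bouton_rois) - mean_of(rois$background_rois)
  if (val < 0)
    warnf("background exceeds bouton signal (%.3g); check ROI placement", val)
  val
}

#' Mitochondrial content of a terminal
#'
#' Background-subtracted mitochondrial-channel fluorescence divided by
#' background-subtracted cytosolic-channel fluorescence, measured over the
#' same bouton ROIs in two registered channels. The ratio normalizes for
#' expression level and optical path, so it is invariant to any gain applied
#' equally to both channels.
#'
#' @param cyto_image,mito_image Registered single images or stacks of the
#'   cytosolic and mitochondrial channels (stacks are average-projected).
#' @param rois ROI set as in [roi_background_subtracted_mean()].
#' @param per_roi Passed through.
#' @return List (`mito_content_result`): `mito_signal`, `cyto_signal`,
#'   `content`.
#' @export
mitochondrial_content <- function(cyto_image, mito_image, rois,
                                  per_roi = FALSE) {
  cyto_image <- project_average(cyto_image)
  mito_image <- project_average(mito_image)
  if (!identical(dim(cyto_image), dim(mito_image)))
    stopf("channels differ in shape: %s vs %s",
          paste(dim(cyto_image), collapse = "x"),
          paste(dim(mito_image), collapse = "x"))
  cyto <- roi_background_subtracted_mean(cyto_image, rois, per_roi)
  mito <- roi_background_subtracted_mean(mito_image, rois, per_roi)
  if (cyto <= 0)
    stopf("cytosolic signal is not positive (%.3g); the content ratio is undefined", cyto)
  structure(list(mito_signal = mito, cyto_signal = cyto,
                 content = mito / cyto),
            class = "mito_content_result")
}

#' @export
print.mito_content_result <- function(x, ...) {
  cat(sprintf("<mito_content_result> mito %.4g / cyto %.4g = content %.4g\n",
              x$mito_signal, x$cyto_signal, x$content))
  invisible(x)
}

#' Percent reduction of mitochondrial content versus control
#'
#' `100 * (1 - mean(test) / mean(control))`, computed over per-terminal
#' content values.
#'
#' @param test,control Numeric vectors of content values, or lists of
#'   `mito_content_result` objects.
#' @return Percent reduction (positive = loss relative to control).
#' @export
percent_reduction <- function(test, control) {
  as_contents <- function(x) {
    if (is.numeric(x)) return(x)
    vapply(x, function(r) r$content, numeric(1))
  }
  test <- as_contents(test); control <- as_contents(control)
  if (length(test) == 0 || length(control) == 0) stopf("empty group")
  mc <- mean(control)
  if (mc <= 0) stopf("control mean content must be > 0")
  100 * (1 - mean(test) / mc)
}

#' Read a single- or multi-page TIFF as a stack
#'
#' @param path TIFF file path.
#' @param scale Multiply the (0-1 normalized) pixel values back to gray
#'   levels; default 65535 matching 16-bit acquisitions.
#' @return 3-D array `height x width x pages`.
#' @export
read_tiff_stack <- function(path, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  flat <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # first channel of RGB pages
    p * scale
  })
  array(unlist(flat), c(dim(flat[[1]]), length(flat)))
}
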