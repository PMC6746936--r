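# Raster and small numeric helpers shared across modules.
#
# Image convention (documented once, asserted in tests): pixel matrices are
# row-major with row 1 at the TOP of the image (y-down in files). Mechanics
# works in y-up millimetre coordinates; `pixel_centers()` performs the flip.

#' Pixel-center coordinates of a pixel matrix in y-up mm
#'
#' @param dim_img integer c(nrow, ncol)
#' @param spacing_mm pixel spacing in mm
#' @return list with `x`, `y` vectors (length ncol / nrow): x of column
#'   centers, y (y-up) of row centers; row 1 maps to the largest y.
#' @keywords internal
pixel_centers <- function(dim_img, spacing_mm) {
  nr <- dim_img[1]; nc <- dim_img[2]
  list(
    x = (seq_len(nc) - 0.5) * spacing_mm,
    y = (nr - seq_len(nr) + 0.5) * spacing_mm
  )
}

#' Count 4-connected components of a logical mask
#'
#' Vectorised flood fill: seeds one foreground pixel, repeatedly dilates the
#' reached set within the mask until fixed point, then repeats on any
#' remainder. Intended for masks up to a few hundred pixels per side.
#'
#' @param mask logical matrix
#' @return integer number of 4-connected components (0 for an empty mask)
#' @keywords internal
count_components <- function(mask) {
  mask <- mask & !is.na(mask)
  remaining <- mask
  n_comp <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  while (any(remaining)) {
    n_comp <- n_comp + 1L
    seed <- which(remaining)[1L]
    reached <- matrix(FALSE, nr, nc)
    reached[seed] <- TRUE
    repeat {
      grown <- reached
      grown[-1, ] <- grown[-1, ] | reached[-nr, ]
      grown[-nr, ] <- grown[-nr, ] | reached[-1, ]
      grown[, -1] <- grown[, -1] | reached[, -nc]
      grown[, -nc] <- grown[, -nc] | reached[, -1]
      grown <- grown & remaining
      if (identical(grown, reached)) break
      reached <- grown
    }
    remaining <- remaining & !reached
  }
  n_comp
}

#' Principal axis of a pixel set (PCA direction of pixel centers)
#'
#' @param mask logical matrix selecting the pixels
#' @param spacing_mm pixel spacing
#' @return unit 2-vector (x, y in y-up mm frame), oriented with positive y
#'   when possible
#' @keywords internal
principal_axis <- function(mask, spacing_mm) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2L) stop("mask has fewer than 2 pixels; no axis defined")
  cc <- pixel_centers(dim(mask), spacing_mm)
  pts <- cbind(cc$x[idx[, 2]], cc$y[idx[, 1]])
  v <- eigen(stats::cov(pts), symmetric = TRUE)$vectors[, 1]
  if (v[2] < 0 || (v[2] == 0 && v[1] < 0)) v <- -v
  v / sqrt(sum(v^2))
}

#' @keywords internal
stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0 (got %g)", name, x))
  invisible(x)
}
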