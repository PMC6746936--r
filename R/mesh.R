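# Constant-thickness planar mesh built on the pixel grid. The femur plate is
# meshed as a structured grid of square 4-node quadrilaterals aligned with the
# image pixels and clipped to the segmentation mask, so every element maps
# deterministically to its closest pixel.

#' Equivalent plate thickness from the femoral neck width
#'
#' The plate thickness is chosen so the rectangular plate cross section
#' (thickness t by width w) matches a circular cross section of diameter w at
#' the femoral neck. Matching the area gives t = pi*w/4; matching the second
#' moment about the out-of-plane axis gives t = 3*pi*w/16. A constant
#' thickness cannot satisfy both at once, so the default is their mean; both
#' pure matches remain selectable.
#'
#' @param neck_width_w femoral neck width in mm (> 0)
#' @param method `"mean"` (default), `"area"` or `"inertia"`
#' @return plate thickness in mm
#' @export
plate_thickness <- function(neck_width_w, method = c("mean", "area", "inertia")) {
  method <- match.arg(method)
  stopifnot_scalar_num(neck_width_w, "neck_width_w", positive = TRUE)
  t_area <- pi * neck_width_w / 4
  t_inertia <- 3 * pi * neck_width_w / 16
  switch(method, area = t_area, inertia = t_inertia,
         mean = (t_area + t_inertia) / 2)
}

#' Build a pixel-aligned quadrilateral mesh on a segmentation mask
#'
#' Elements are squares of side `k * spacing_mm` where `k` rounds
#' `target_elem_size_mm / spacing_mm` (k = 1 for the default 0.5 mm spacing
#' and element size, i.e. one element per pixel). Node coordinates are in mm,
#' y-up, with the origin at the bottom-left image corner.
#'
#' @param femur_mask logical matrix (single 4-connected component)
#' @param spacing_mm pixel spacing in mm
#' @param target_elem_size_mm target element side length (default 0.5 mm)
#' @param thickness_t uniform plate thickness in mm
#' @return object of class `planar_mesh`: `nodes` (n x 2 mm), `elems`
#'   (m x 4 node indices, counter-clockwise from bottom-left), `thickness_t`,
#'   `elem_size_mm`, `elem_pixel` (linear index of each element's source
#'   pixel), `dim_img`, `spacing_mm`
#' @export
build_mesh <- function(femur_mask, spacing_mm, target_elem_size_mm = 0.5,
                       thickness_t = 1) {
  if (!is.logical(femur_mask) || !is.matrix(femur_mask))
    stop("femur_mask must be a logical matrix")
  stopifnot_scalar_num(spacing_mm, "spacing_mm", positive = TRUE)
  stopifnot_scalar_num(thickness_t, "thickness_t", positive = TRUE)
  k <- max(1L, as.integer(round(target_elem_size_mm / spacing_mm)))
  h <- k * spacing_mm
  if (h < 0.5 * target_elem_size_mm || h > 2 * target_elem_size_mm)
    stop(sprintf("achievable element size %g mm outside [0.5, 2] x target %g mm",
                 h, target_elem_size_mm))
  nr <- nrow(femur_mask); nc <- ncol(femur_mask)
  nbr <- nr %/% k; nbc <- nc %/% k          # block grid (bottom rows kept)
  if (nbr < 1L || nbc < 1L) stop("mask smaller than one element")

  # block (ib from bottom, jb) covers image rows (nr - ib*k + 1):(nr - (ib-1)*k)
  # and columns ((jb-1)*k + 1):(jb*k); included if > half its pixels are bone
  inc <- matrix(FALSE, nbr, nbc)
  cnt <- matrix(0L, nbr, nbc)
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    rows <- nr - (seq_len(nbr)) * k + di
    cols <- (seq_len(nbc) - 1L) * k + dj
    cnt <- cnt + femur_mask[rows, cols, drop = FALSE]
  }
  inc <- cnt > (k * k) / 2
  if (!any(inc)) stop("mask contains no elements")
  ncomp <- count_components(inc)
  if (ncomp != 1L)
    stop(sprintf("mask has %d connected components; expected 1", ncomp))

  # nodes at block corners; keep only nodes touching an included element
  node_id <- matrix(0L, nbr + 1L, nbc + 1L)
  eidx <- which(inc, arr.ind = TRUE)        # (ib, jb)
  ib <- eidx[, 1]; jb <- eidx[, 2]
  corner <- cbind(ib, jb, ib, jb + 1L, ib + 1L, jb + 1L, ib + 1L, jb)
  used <- unique(rbind(corner[, 1:2], corner[, 3:4], corner[, 5:6], corner[, 7:8]))
  node_id[used] <- seq_len(nrow(used))
  nodes <- cbind(x = (used[, 2] - 1L) * h, y = (used[, 1] - 1L) * h)

  elems <- cbind(node_id[corner[, 1:2]], node_id[corner[, 3:4]],
                 node_id[corner[, 5:6]], node_id[corner[, 7:8]])

  # representative pixel: center pixel of the block (its "closest pixel")
  ctr_row <- nr - (ib - 1L) * k - ((k + 1L) %/% 2L) + 1L
  ctr_col <- (jb - 1L) * k + (k + 1L) %/% 2L
  elem_pixel <- (ctr_col - 1L) * nr + ctr_row

  structure(list(nodes = nodes, elems = elems, thickness_t = thickness_t,
                 elem_size_mm = h, elem_pixel = elem_pixel,
                 elem_block = cbind(ib = ib, jb = jb),
                 dim_img = c(nr, nc), spacing_mm = spacing_mm),
            class = "planar_mesh")
}

#' Element centroids of a planar mesh
#' @param mesh a `planar_mesh`
#' @return m x 2 matrix of centroid coordinates (mm, y-up)
#' @export
element_centroids <- function(mesh) {
  x <- matrix(mesh$nodes[t(mesh$elems), 1], ncol = 4, byrow = TRUE)
  y <- matrix(mesh$nodes[t(mesh$elems), 2], ncol = 4, byrow = TRUE)
  cbind(rowMeans(x), rowMeans(y))
}

# Boundary nodes: nodes on edges owned by exactly one element.
mesh_boundary_nodes <- function(mesh) {
  e <- mesh$elems
  edges <- rbind(e[, c(1, 2)], e[, c(2, 3)], e[, c(3, 4)], e[, c(4, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  once <- names(which(table(key) == 1L))
  unique(as.integer(unlist(strsplit(once, " "))))
}

# Map each element to the value of a per-pixel field at its source pixel.
elem_pixel_values <- function(mesh, field_matrix) {
  if (!identical(dim(field_matrix), as.integer(mesh$dim_img)) &&
      !identical(dim(field_matrix), mesh$dim_img))
    stop("field matrix dimensions do not match the mesh's source image")
  field_matrix[mesh$elem_pixel]
}

#' @export
print.planar_mesh <- function(x, ...) {
  cat(sprintf(paste0("planar mesh: %d nodes, %d quadrilateral elements ",
                     "(%.3g mm), thickness %.3g mm\n"),
              nrow(x$nodes), nrow(x$elems), x$elem_size_mm, x$thickness_t))
  invisible(x)
}
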