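# Linear-elastic plane-stress finite elements: 4-node bilinear quadrilaterals
# with 2x2 Gauss quadrature, sparse assembly, optional grounding springs and a
# rigid-link hinge (distal nodes slaved to a pinned master free only in
# rotation). Strains are reported at element centroids.

# Plane-stress constitutive matrix for unit E.
d_hat_plane_stress <- function(nu) {
  matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3) / (1 - nu^2)
}

# Shape-function derivatives of the bilinear quad at (xi, eta).
q4_dshape <- function(xi, eta) {
  rbind(c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)),
        c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi))) / 4
}

# B matrix (3 x 8) at a quadrature point for element node coords (4 x 2).
q4_b_matrix <- function(coords, xi, eta) {
  dn <- q4_dshape(xi, eta)
  jac <- dn %*% coords
  dnxy <- solve(jac, dn)
  b <- matrix(0, 3, 8)
  b[1, seq(1, 8, 2)] <- dnxy[1, ]
  b[2, seq(2, 8, 2)] <- dnxy[2, ]
  b[3, seq(1, 8, 2)] <- dnxy[2, ]
  b[3, seq(2, 8, 2)] <- dnxy[1, ]
  list(b = b, detj = det(jac))
}

# Unit-modulus element stiffness (8 x 8) for given geometry and Poisson ratio.
q4_unit_stiffness <- function(coords, nu) {
  dh <- d_hat_plane_stress(nu)
  gp <- 1 / sqrt(3)
  k <- matrix(0, 8, 8)
  for (xi in c(-gp, gp)) for (eta in c(-gp, gp)) {
    bd <- q4_b_matrix(coords, xi, eta)
    if (bd$detj <= 0) stop("degenerate element (non-positive Jacobian)")
    k <- k + t(bd$b) %*% dh %*% bd$b * bd$detj
  }
  k
}

# Element dof table: node i -> dofs (2i-1, 2i).
elem_dofs <- function(elems) {
  ed <- matrix(0L, nrow(elems), 8L)
  ed[, c(1, 3, 5, 7)] <- 2L * elems - 1L
  ed[, c(2, 4, 6, 8)] <- 2L * elems
  ed
}

# TRUE when every element is a translate of the first (pixel-aligned grids).
elements_congruent <- function(mesh) {
  elems <- mesh$elems
  xs <- matrix(mesh$nodes[t(elems), 1], nrow = 4)
  ys <- matrix(mesh$nodes[t(elems), 2], nrow = 4)
  dxs <- sweep(xs, 2, xs[1, ])
  dys <- sweep(ys, 2, ys[1, ])
  max(abs(dxs - dxs[, 1]), abs(dys - dys[, 1])) < 1e-9
}

# Sparse global stiffness. Exploits congruent elements (the pixel-aligned
# meshes built here): one unit stiffness scaled per element by E * t.
assemble_stiffness <- function(mesh, e_per_element, nu) {
  if (any(e_per_element <= 0)) {
    bad <- which(e_per_element <= 0)
    stop(sprintf("non-positive modulus on %d element(s), e.g. element %d",
                 length(bad), bad[1]))
  }
  elems <- mesh$elems
  ne <- nrow(elems)
  coords1 <- mesh$nodes[elems[1, ], , drop = FALSE]
  congruent <- elements_congruent(mesh)
  edof <- elem_dofs(elems)
  idx_a <- rep(1:8, times = 8)
  idx_b <- rep(1:8, each = 8)
  scale <- e_per_element * mesh$thickness_t
  if (congruent) {
    k_hat <- q4_unit_stiffness(coords1, nu)
    xval <- tcrossprod(scale, as.vector(k_hat))   # ne x 64
  } else {
    xval <- matrix(0, ne, 64)
    for (i in seq_len(ne)) {
      ki <- q4_unit_stiffness(mesh$nodes[elems[i, ], , drop = FALSE], nu)
      xval[i, ] <- scale[i] * as.vector(ki)
    }
  }
  ndof <- 2L * nrow(mesh$nodes)
  Matrix::sparseMatrix(i = as.vector(edof[, idx_a]),
                       j = as.vector(edof[, idx_b]),
                       x = as.vector(xval), dims = c(ndof, ndof))
}

#' Solve a plane-stress problem on a planar mesh
#'
#' Low-level solver used both by the sideways-fall driver
#' ([assemble_and_solve()]) and directly by verification problems (patch
#' test, cantilever). Supports nodal forces, fixed dofs, diagonal grounding
#' springs and one rigid-link group slaved to a pinned master node carrying a
#' single rotational dof.
#'
#' @param mesh a `planar_mesh`
#' @param materials a `material_field`, or a list with `e` (per-element MPa)
#'   and `nu`
#' @param forces numeric vector of nodal forces, length `2 * n_nodes`
#'   (x dof of node i at position 2i-1, y at 2i), in N
#' @param fixed_dofs integer vector of dof indices with zero prescribed
#'   displacement
#' @param springs optional numeric vector (length `2 * n_nodes`) of grounding
#'   spring stiffnesses (N/mm) added to the diagonal
#' @param rigid_link optional list with `nodes` (integer vector) and `master`
#'   (length-2 xy, mm): listed nodes move rigidly about the pinned master,
#'   which retains only the rotation dof
#' @return list with `u` (dof vector, mm), `displacements` (n x 2), `strains`
#'   (m x 3: exx, eyy, gxy at centroids), `principal` (m x 2: e1 >= e3),
#'   `theta` (hinge rotation, rad, or NA), `reactions` (list: `springs`,
#'   `hinge`, each an xy force in N), `f_ext_total`, `residual_norm`
#' @export
fe_solve <- function(mesh, materials, forces, fixed_dofs = integer(),
                     springs = NULL, rigid_link = NULL) {
  stopifnot(inherits(mesh, "planar_mesh"))
  e_vec <- materials$e
  nu <- materials$nu
  if (is.null(e_vec) || is.null(nu)) stop("materials must provide 'e' and 'nu'")
  if (length(e_vec) == 1L) e_vec <- rep(e_vec, nrow(mesh$elems))
  if (length(e_vec) != nrow(mesh$elems))
    stop("materials$e length does not match the element count")
  ndof <- 2L * nrow(mesh$nodes)
  if (length(forces) != ndof) stop("forces must have length 2 * n_nodes")

  k_struct <- assemble_stiffness(mesh, e_vec, nu)
  k_full <- k_struct
  if (!is.null(springs)) {
    if (length(springs) != ndof) stop("springs must have length 2 * n_nodes")
    k_full <- k_full + Matrix::Diagonal(ndof, springs)
  }

  slave_dofs <- integer()
  theta_col <- FALSE
  if (!is.null(rigid_link)) {
    sn <- rigid_link$nodes
    if (!length(sn)) stop("rigid_link$nodes is empty")
    slave_dofs <- as.integer(rbind(2L * sn - 1L, 2L * sn))
    theta_col <- TRUE
  }
  elim <- unique(c(fixed_dofs, slave_dofs))
  free <- setdiff(seq_len(ndof), elim)
  nfree <- length(free)
  nq <- nfree + as.integer(theta_col)
  if (nq == 0L) stop("no unknowns left after constraints")

  ti <- free; tj <- seq_len(nfree); tx <- rep(1, nfree)
  if (theta_col) {
    sn <- rigid_link$nodes
    dx <- mesh$nodes[sn, 1] - rigid_link$master[1]
    dy <- mesh$nodes[sn, 2] - rigid_link$master[2]
    ti <- c(ti, 2L * sn - 1L, 2L * sn)
    tj <- c(tj, rep(nq, 2L * length(sn)))
    tx <- c(tx, -dy, dx)
  }
  tmat <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(ndof, nq))

  k_red <- Matrix::forceSymmetric(Matrix::crossprod(tmat, k_full %*% tmat))
  f_red <- as.numeric(Matrix::crossprod(tmat, forces))
  q <- tryCatch({
    ch <- Matrix::Cholesky(k_red, perm = TRUE, LDL = FALSE)
    as.numeric(Matrix::solve(ch, f_red))
  }, error = function(e) stop(
    "singular system (insufficient constraints): ",
    conditionMessage(e), call. = FALSE))
  # rigid-body modes can slip through a numerically indefinite factorisation
  res_red <- k_red %*% q - f_red
  fscale <- max(sqrt(sum(f_red^2)), 1e-30)
  if (sqrt(sum(res_red^2)) / fscale > 1e-6 || any(!is.finite(q)))
    stop("singular system (insufficient constraints): residual too large")
  u <- as.numeric(tmat %*% q)

  # centroid strains; congruent fast path via a single B matrix
  edof <- elem_dofs(mesh$elems)
  elems <- mesh$elems
  u_elem <- matrix(u[t(edof)], nrow = 8)           # 8 x ne
  if (elements_congruent(mesh)) {
    b0 <- q4_b_matrix(mesh$nodes[elems[1, ], , drop = FALSE], 0, 0)$b
    strains <- t(b0 %*% u_elem)
  } else {
    strains <- matrix(0, nrow(elems), 3)
    for (i in seq_len(nrow(elems))) {
      bi <- q4_b_matrix(mesh$nodes[elems[i, ], , drop = FALSE], 0, 0)$b
      strains[i, ] <- bi %*% u_elem[, i]
    }
  }
  colnames(strains) <- c("exx", "eyy", "gxy")

  princ <- principal_strains(strains)

  f_int <- as.numeric(k_struct %*% u)
  spring_r <- c(0, 0)
  if (!is.null(springs)) {
    sf <- -springs * u
    spring_r <- c(sum(sf[seq(1, ndof, 2)]), sum(sf[seq(2, ndof, 2)]))
  }
  hinge_r <- c(0, 0)
  if (length(elim)) {
    rr <- f_int[elim] - forces[elim]
    xsel <- elim %% 2L == 1L
    hinge_r <- c(sum(rr[xsel]), sum(rr[!xsel]))
  }
  res <- f_int[free] - forces[free]
  if (!is.null(springs)) res <- res + (springs * u)[free]
  fext <- c(sum(forces[seq(1, ndof, 2)]), sum(forces[seq(2, ndof, 2)]))

  list(u = u,
       displacements = cbind(u[seq(1, ndof, 2)], u[seq(2, ndof, 2)]),
       strains = strains, principal = princ,
       theta = if (theta_col) q[nq] else NA_real_,
       reactions = list(springs = spring_r, hinge = hinge_r),
       f_ext_total = fext,
       residual_norm = sqrt(sum(res^2)))
}

#' Principal strains of 2D engineering strain states
#'
#' @param strains numeric vector `c(exx, eyy, gxy)` or an m x 3 matrix
#'   (engineering shear gxy = 2 * exy)
#' @return m x 2 matrix with columns `e1` (max) and `e3` (min), `e1 >= e3`
#' @export
principal_strains <- function(strains) {
  if (is.null(dim(strains))) strains <- matrix(strains, ncol = 3)
  if (ncol(strains) != 3) stop("strains must have 3 columns (exx, eyy, gxy)")
  if (any(!is.finite(strains))) stop("non-finite strain entries")
  m <- (strains[, 1] + strains[, 2]) / 2
  r <- sqrt(((strains[, 1] - strains[, 2]) / 2)^2 + (strains[, 3] / 2)^2)
  cbind(e1 = m + r, e3 = m - r)
}

#' Sideways-fall load case
#'
#' @param impact_force_F impact force magnitude in N
#' @param force_angle_deg force inclination, degrees counter-clockwise from
#'   the axis perpendicular to the shaft (default 30)
#' @param head_spring_total total grounding spring stiffness at the femoral
#'   head in N/mm (default 10000), split evenly over the head boundary nodes
#'   in both in-plane directions
#' @param arc_fraction fraction of the full circle of the lateral trochanteric
#'   boundary over which the impact force is distributed (default 0.35)
#' @return object of class `load_case`
#' @export
load_case <- function(impact_force_F, force_angle_deg = 30,
                      head_spring_total = 10000, arc_fraction = 0.35) {
  stopifnot_scalar_num(impact_force_F, "impact_force_F", positive = TRUE)
  stopifnot_scalar_num(head_spring_total, "head_spring_total", positive = TRUE)
  if (arc_fraction <= 0 || arc_fraction > 1)
    stop("arc_fraction must lie in (0, 1]")
  structure(list(impact_force_F = impact_force_F,
                 force_angle_deg = force_angle_deg,
                 head_spring_total = head_spring_total,
                 arc_fraction = arc_fraction),
            class = "load_case")
}

# Node sets for the sideways-fall boundary conditions, derived from the
# anatomical region labels (1 head, 2 neck, 3 trochanter, 4 intertroch,
# 5 shaft) of the source image.
fall_node_sets <- function(mesh, regions) {
  elem_region <- elem_pixel_values(mesh, regions)
  bnodes <- mesh_boundary_nodes(mesh)
  head_nodes <- intersect(bnodes, unique(as.vector(mesh$elems[elem_region == 1L, ])))
  troch_nodes <- intersect(bnodes, unique(as.vector(mesh$elems[elem_region == 3L, ])))
  if (!length(head_nodes)) stop("no head boundary nodes found in region mask")
  if (!length(troch_nodes)) stop("no trochanteric boundary nodes found in region mask")
  ymin <- min(mesh$nodes[, 2])
  distal_nodes <- which(mesh$nodes[, 2] <= ymin + 1e-9)
  list(elem_region = elem_region, head = head_nodes, troch = troch_nodes,
       distal = distal_nodes)
}

#' Assemble and solve the sideways-fall plane-stress problem
#'
#' Grounds the femoral head through springs, slaves the distal edge to a
#' pinned master node free only in rotation, distributes the impact force
#' over a lateral arc of the trochanteric boundary inclined 30 degrees
#' counter-clockwise from the shaft-perpendicular axis, and returns nodal
#' displacements and element-centroid strains. The shaft axis is fitted from
#' the shaft region of the label image (head up, medial side left).
#'
#' @param mesh a `planar_mesh`
#' @param materials a `material_field`
#' @param load a [load_case()]
#' @param regions integer matrix of anatomical region labels on the source
#'   image grid (1 head, 2 neck, 3 trochanter, 4 intertrochanter, 5 shaft)
#' @return the [fe_solve()] result, plus `node_sets`, `force_dir` and
#'   `elem_region`
#' @export
assemble_and_solve <- function(mesh, materials, load, regions) {
  stopifnot(inherits(load, "load_case"))
  ns <- fall_node_sets(mesh, regions)
  ndof <- 2L * nrow(mesh$nodes)

  shaft_axis <- if (any(regions == 5L))
    principal_axis(regions == 5L, mesh$spacing_mm) else c(0, 1)
  perp <- c(-shaft_axis[2], shaft_axis[1])       # medial-pointing normal
  th <- load$force_angle_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  f_dir <- as.numeric(rot %*% perp)

  # lateral arc of the trochanteric boundary around its most lateral point
  tn <- ns$troch
  ctr <- colMeans(mesh$nodes[tn, , drop = FALSE])
  ang <- atan2(mesh$nodes[tn, 2] - ctr[2], mesh$nodes[tn, 1] - ctr[1])
  keep <- abs(ang) <= load$arc_fraction * pi
  if (any(keep)) tn <- tn[keep]

  forces <- numeric(ndof)
  per_node <- load$impact_force_F / length(tn)
  forces[2L * tn - 1L] <- forces[2L * tn - 1L] + per_node * f_dir[1]
  forces[2L * tn] <- forces[2L * tn] + per_node * f_dir[2]

  springs <- numeric(ndof)
  k_node <- load$head_spring_total / length(ns$head)
  springs[2L * ns$head - 1L] <- k_node
  springs[2L * ns$head] <- k_node

  master <- c(mean(mesh$nodes[ns$distal, 1]), min(mesh$nodes[, 2]))
  sol <- fe_solve(mesh, materials, forces, springs = springs,
                  rigid_link = list(nodes = ns$distal, master = master))
  sol$node_sets <- list(head = ns$head, troch_loaded = tn, distal = ns$distal)
  sol$force_dir <- f_dir
  sol$elem_region <- ns$elem_region
  sol
}
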