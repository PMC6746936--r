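# Verification problems for the plane-stress solver.

square_patch <- function(n = 20, E = 1000, nu = 0.3, t = 2, sigma = 5) {
  mask <- matrix(TRUE, n, n)
  mesh <- build_mesh(mask, 0.5, 0.5, thickness_t = t)
  L <- n * 0.5
  right <- which(abs(mesh$nodes[, 1] - L) < 1e-9)
  left <- which(abs(mesh$nodes[, 1]) < 1e-9)
  f <- numeric(2 * nrow(mesh$nodes))
  ys <- mesh$nodes[right, 2]
  wgt <- ifelse(ys < 1e-9 | ys > L - 1e-9, 0.5, 1) * 0.5 * t * sigma
  f[2 * right - 1] <- wgt
  corner <- which(abs(mesh$nodes[, 1]) < 1e-9 & abs(mesh$nodes[, 2]) < 1e-9)
  list(mesh = mesh, f = f,
       fixed = c(2 * left - 1, 2 * corner),
       materials = list(e = E, nu = nu), sigma = sigma, E = E, nu = nu)
}

test_that("patch test: uniform traction produces the exact uniform strain field", {
  pp <- square_patch()
  sol <- fe_solve(pp$mesh, pp$materials, pp$f, fixed_dofs = pp$fixed)
  exx_exact <- pp$sigma / pp$E
  eyy_exact <- -pp$nu * pp$sigma / pp$E
  expect_lt(max(abs(sol$strains[, 1] - exx_exact)) / exx_exact, 1e-10)
  expect_lt(max(abs(sol$strains[, 2] - eyy_exact)) / abs(eyy_exact), 1e-10)
  expect_lt(max(abs(sol$strains[, 3])), 1e-10 * exx_exact)
})

test_that("doubling the modulus halves displacements (linearity)", {
  pp <- square_patch()
  u1 <- fe_solve(pp$mesh, list(e = 1000, nu = 0.3), pp$f, fixed_dofs = pp$fixed)$u
  u2 <- fe_solve(pp$mesh, list(e = 2000, nu = 0.3), pp$f, fixed_dofs = pp$fixed)$u
  expect_equal(u1, 2 * u2, tolerance = 1e-10)
})

test_that("cantilever tip deflection matches shear-corrected beam theory within 2%", {
  mask <- matrix(TRUE, 20, 200)               # 100 x 10 mm strip at 0.5 mm
  mesh <- build_mesh(mask, 0.5, 0.5, thickness_t = 2)
  E <- 10000; nu <- 0.3; P <- 10
  left <- which(abs(mesh$nodes[, 1]) < 1e-9)
  right <- which(abs(mesh$nodes[, 1] - 100) < 1e-9)
  f <- numeric(2 * nrow(mesh$nodes))
  ys <- mesh$nodes[right, 2]
  w <- ifelse(ys < 1e-9 | ys > 10 - 1e-9, 0.5, 1); w <- w / sum(w)
  f[2 * right] <- -P * w
  sol <- fe_solve(mesh, list(e = E, nu = nu), f,
                  fixed_dofs = c(2 * left - 1, 2 * left))
  tip <- right[which.min(abs(ys - 5))]
  I <- 2 * 10^3 / 12; A <- 2 * 10; G <- E / (2 * (1 + nu))
  d_ref <- -(P * 100^3 / (3 * E * I) + 1.2 * P * 100 / (G * A))
  expect_lt(abs(sol$displacements[tip, 2] - d_ref) / abs(d_ref), 0.02)
})

test_that("principal strains match brute-force eigen decomposition", {
  expect_equal(principal_strains(c(0.001, -0.001, 0)),
               cbind(e1 = 0.001, e3 = -0.001))
  expect_equal(principal_strains(c(0, 0, 0.002)),
               cbind(e1 = 0.001, e3 = -0.001))
  for (a in c(-0.004, 0, 0.003))
    expect_equal(unname(principal_strains(c(a, a, 0))), matrix(a, 1, 2))
  set.seed(12)
  for (i in 1:1000) {
    s <- stats::rnorm(3, sd = 0.01)
    got <- principal_strains(s)
    ref <- eigen_principal(s[1], s[2], s[3])
    expect_lt(max(abs(got - rbind(ref))), 1e-12)
  }
})

test_that("sideways-fall solve balances applied force against reactions", {
  ph <- generate_femur_image(test_params(), noise_sd = 100, seed = 21)
  res <- solve_phantom(ph)
  fext <- res$sol$f_ext_total
  rtot <- res$sol$reactions$springs + res$sol$reactions$hinge
  expect_lt(sqrt(sum((fext + rtot)^2)) / sqrt(sum(fext^2)), 1e-8)
  expect_equal(sqrt(sum(fext^2)), 5300, tolerance = 1e-9)
})

test_that("solution rotates with a rigid rotation of the whole model", {
  mask <- matrix(TRUE, 6, 30)
  mesh <- build_mesh(mask, 1, 1, thickness_t = 2)
  left <- which(abs(mesh$nodes[, 1]) < 1e-9)
  right <- which(abs(mesh$nodes[, 1] - 30) < 1e-9)
  f <- numeric(2 * nrow(mesh$nodes))
  f[2 * right] <- -1
  fixed <- c(2 * left - 1, 2 * left)
  sol <- fe_solve(mesh, list(e = 500, nu = 0.3), f, fixed_dofs = fixed)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  mesh_rot <- mesh
  mesh_rot$nodes <- mesh$nodes %*% t(R)
  f_rot <- as.numeric(R %*% matrix(f, 2))      # stays dof-interleaved
  sol_rot <- fe_solve(mesh_rot, list(e = 500, nu = 0.3), f_rot,
                      fixed_dofs = fixed)
  u_expect <- as.numeric(R %*% t(sol$displacements))
  expect_equal(sol_rot$u, u_expect, tolerance = 1e-8)
})

test_that("unconstrained or inconsistent systems raise errors", {
  mask <- matrix(TRUE, 4, 4)
  mesh <- build_mesh(mask, 1, 1, 1)
  f <- numeric(2 * nrow(mesh$nodes)); f[1] <- 1
  suppressWarnings(
    expect_error(fe_solve(mesh, list(e = 100, nu = 0.3), f), "singular"))
  expect_error(fe_solve(mesh, list(e = c(100, -5), nu = 0.3), f),
               "length does not match")
  expect_error(fe_solve(mesh, list(e = rep(-5, nrow(mesh$elems)), nu = 0.3), f),
               "non-positive modulus")
})
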