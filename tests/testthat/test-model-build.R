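test_that("plate thickness matches the circular-section closed forms", {
  expect_equal(plate_thickness(32, "area"), pi * 32 / 4, tolerance = 1e-12)
  expect_equal(plate_thickness(32, "inertia"), 3 * pi * 32 / 16,
               tolerance = 1e-12)
  expect_equal(plate_thickness(32, "mean"),
               (pi * 32 / 4 + 3 * pi * 32 / 16) / 2, tolerance = 1e-12)
  expect_error(plate_thickness(0), "> 0")
})

test_that("a square mask meshes into the exact structured grid", {
  mask <- matrix(TRUE, 20, 20)                 # 10 x 10 mm at 0.5 mm
  mesh <- build_mesh(mask, 0.5, 0.5, thickness_t = 1)
  expect_equal(nrow(mesh$elems), 400)
  expect_equal(mesh$elem_size_mm, 0.5)
  expect_equal(nrow(mesh$nodes), 441)
  # every element is a CCW unit square of side 0.5
  n1 <- mesh$nodes[mesh$elems[, 1], ]; n3 <- mesh$nodes[mesh$elems[, 3], ]
  expect_true(all(abs((n3 - n1) - 0.5) < 1e-12))
})

test_that("mesh covers the phantom mask and rejects disconnected masks", {
  ph <- generate_femur_image(test_params())
  sp <- ph$image$spacing_mm
  mesh <- build_mesh(ph$femur_mask, sp, sp, 20)
  area_mesh <- nrow(mesh$elems) * mesh$elem_size_mm^2
  area_mask <- sum(ph$femur_mask) * sp^2
  expect_lt(abs(area_mesh - area_mask) / area_mask, 0.02)
  two <- matrix(FALSE, 10, 10); two[2:3, 2:3] <- TRUE; two[7:8, 7:8] <- TRUE
  expect_error(build_mesh(two, 1, 1, 1), "2 connected components")
})

test_that("element centroids coincide with their source pixel centers", {
  ph <- generate_femur_image(test_params())
  sp <- ph$image$spacing_mm
  mesh <- build_mesh(ph$femur_mask, sp, sp, 20)
  cen <- element_centroids(mesh)
  nr <- mesh$dim_img[1]
  row <- ((mesh$elem_pixel - 1L) %% nr) + 1L
  col <- ((mesh$elem_pixel - 1L) %/% nr) + 1L
  px <- (col - 0.5) * sp
  py <- (nr - row + 0.5) * sp
  half_diag <- sp * sqrt(2) / 2
  expect_true(all(sqrt((cen[, 1] - px)^2 + (cen[, 2] - py)^2) <= half_diag + 1e-12))
})

test_that("density chain closed forms hold", {
  expect_equal(abmd_to_volumetric(0.8, 20), 0.4)
  expect_equal(abmd_to_volumetric(0, 20), 0)
  expect_equal(abmd_to_volumetric(1.2, 18.84956), 1.2 / 1.884956,
               tolerance = 1e-6)
  expect_equal(volumetric_to_apparent(0.4, 0.6), 0.4 / 0.6)
  expect_equal(volumetric_to_apparent(0.7, 1.0), 0.7)
  expect_equal(volumetric_to_apparent(0), 0)
  expect_error(volumetric_to_apparent(0.4, 0), "ash_fraction")
})

test_that("the density-modulus power law evaluates and switches branches", {
  expect_equal(morgan_modulus(1.0), 6850, tolerance = 1e-10)
  expect_equal(morgan_modulus(0.20), 15010 * 0.20^2.18, tolerance = 1e-10)
  # the low branch applies at the boundary density
  expect_equal(morgan_modulus(0.28), 15010 * 0.28^2.18, tolerance = 1e-10)
  expect_gt(morgan_modulus(0.2801), morgan_modulus(0.28) - 300) # high branch above
  expect_error(morgan_modulus(-0.1), ">= 0")
  rho <- seq(0.01, 2, by = 0.01)
  e <- morgan_modulus(rho)
  low <- rho <= 0.28
  expect_true(all(diff(e[low]) > 0))
  expect_true(all(diff(e[!low]) > 0))
})

test_that("modulus binning keeps at most n bins and respects medians", {
  expect_equal(bin_moduli(rep(1234, 5))$e, rep(1234, 5))
  singles <- seq(100, 3500, by = 100)          # one value per bin
  expect_equal(bin_moduli(singles)$e, singles)
  hand <- bin_moduli(c(100, 110, 3500))
  expect_equal(hand$e, c(105, 105, 3500))
  expect_equal(hand$bin_id, c(1L, 1L, 35L))
  set.seed(99)
  for (i in 1:20) {
    e_raw <- stats::runif(200, 50, 12000)
    b <- bin_moduli(e_raw)
    expect_lte(length(unique(b$e)), 35)
    expect_true(all(abs(b$e - e_raw) <= b$bin_width + 1e-9))
  }
})

test_that("material field is monotone in gray before binning", {
  ph <- generate_femur_image(test_params(), noise_sd = 120, seed = 8)
  line <- truth_line(ph)
  bmd <- apply_calibration(ph$image, line, ph$femur_mask)
  mesh <- build_mesh(ph$femur_mask, 1, 1, plate_thickness(33))
  mat <- material_field(mesh, bmd)
  grays <- ph$image$pixels[mesh$elem_pixel]
  ord <- order(grays)
  expect_true(all(diff(mat$e_raw[ord]) >= -1e-9))
  expect_lte(length(unique(mat$e)), 35)
})
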