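test_that("same seed reproduces the image bit for bit, nearby seeds differ", {
  p <- test_params()
  a <- generate_femur_image(p, noise_sd = 200, seed = 42)
  b <- generate_femur_image(p, noise_sd = 200, seed = 42)
  c <- generate_femur_image(p, noise_sd = 200, seed = 43)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("noiseless grays are exactly affine in the true BMD", {
  ph <- generate_femur_image(test_params(), noise_sd = 0)
  tr <- ph$truth$gray_to_bmd_line
  fg <- which(ph$femur_mask)
  predicted <- (ph$truth$true_bmd_map[fg] - tr$intercept) / tr$slope
  expect_equal(max(abs(ph$image$pixels[fg] - predicted)), 0)
  expect_true(all(ph$image$pixels[!ph$femur_mask] == 0))
})

test_that("neck-shaft angle measured on the generated mask matches the parameter", {
  for (nsa in c(120, 135)) {
    ph <- generate_femur_image(test_params(neck_shaft_angle_deg = nsa))
    sp <- ph$image$spacing_mm
    # oracle: PCA axes of the neck ROI and of the shaft region pixels
    axis_of <- function(sel) {
      idx <- which(sel, arr.ind = TRUE)
      pts <- cbind(idx[, 2] * sp, -idx[, 1] * sp)
      v <- eigen(cov(pts), symmetric = TRUE)$vectors[, 1]
      v / sqrt(sum(v^2))
    }
    v_neck <- axis_of(ph$roi == 1L)
    v_shaft <- axis_of(ph$regions == 5L)
    between <- acos(min(abs(sum(v_neck * v_shaft)), 1)) * 180 / pi
    expect_lt(abs((180 - between) - nsa), 2)
  }
})

test_that("emitted ROI means equal mask-wise means of the truth map exactly", {
  ph <- generate_femur_image(test_params(), noise_sd = 150, seed = 7)
  for (k in 1:3) {
    nm <- c("neck", "trochanter", "intertrochanter")[k]
    expect_identical(ph$truth$roi_mean_bmd[[nm]],
                     mean(ph$truth$true_bmd_map[ph$roi == k]))
  }
  expect_true(all(ph$roi == 0 | ph$femur_mask))        # ROIs inside the femur
  expect_true(all(table(ph$roi[ph$roi > 0]) > 0))
})

test_that("generated neck width matches a brute-force minimum-width scan", {
  p <- test_params(neck_width_mm = 30)
  ph <- generate_femur_image(p)
  sp <- ph$image$spacing_mm
  phi <- (p$neck_shaft_angle_deg - 90) * pi / 180
  d <- c(-cos(phi), sin(phi))
  idx <- which(ph$roi == 1L, arr.ind = TRUE)
  pts <- cbind(idx[, 2] * sp, (nrow(ph$roi) - idx[, 1]) * sp)
  t_ax <- pts %*% d
  perp <- pts %*% c(-d[2], d[1])
  widths <- tapply(perp, round((t_ax - min(t_ax)) / sp),
                   function(v) max(v) - min(v) + sp)
  expect_lt(abs(min(widths) - p$neck_width_mm), sp + 1e-9)
})

test_that("degenerate geometries are rejected with a message", {
  expect_error(femur_shape_params(neck_width_mm = 50, head_radius_mm = 24),
               "degenerate geometry")
  expect_error(femur_shape_params(hip_axis_length_mm = 40),
               "degenerate geometry")
  expect_error(generate_femur_image(test_params(), noise_sd = -1), "noise_sd")
})

test_that("cohort generation writes readable patient directories", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(4, seed = 11, dir = dir, spacing_mm = 1.0)
  expect_length(co$patients, 4)
  pdirs <- list.dirs(dir, recursive = FALSE)
  expect_length(pdirs, 4)
  b <- read_patient(pdirs[1])
  expect_s3_class(b, "patient_bundle")
  expect_identical(dim(b$image$pixels), dim(co$patients[[1]]$image$pixels))
  expect_true(file.exists(file.path(dir, "hsa.csv")))
  expect_true(file.exists(file.path(dir, "patients.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
})

test_that("cohort bookkeeping: effect drivers recorded, seeds change tables", {
  expect_error(generate_cohort(2), "cohort statistics undefined")
  co1 <- generate_cohort(6, seed = 5, spacing_mm = 1.0, write_images = FALSE,
                         effect_spec = list(coefficients = c(NSA = 1, NN_BR = 1)))
  expect_setequal(co1$truth$drivers, c("NSA", "NN_BR"))
  expect_length(co1$truth$rf_hat_true, 6)
  co2 <- generate_cohort(6, seed = 6, spacing_mm = 1.0, write_images = FALSE)
  expect_false(identical(co1$hsa$NN_BR, co2$hsa$NN_BR))
  expect_error(
    generate_cohort(3, spacing_mm = 1.0, write_images = FALSE,
                    effect_spec = list(coefficients = c(NOPE = 1))),
    "not in HSA table")
})
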