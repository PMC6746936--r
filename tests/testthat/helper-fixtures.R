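# Shared fixtures. Test phantoms use 1 mm spacing (quarter the pixel count of
# the 0.5 mm default) except where the check is about the default element
# size itself.

test_params <- function(...) {
  femur_shape_params(image_spacing_mm = 1.0, ...)
}

# calibration line taken straight from a phantom's synthesis truth
truth_line <- function(phantom) {
  tr <- phantom$truth$gray_to_bmd_line
  structure(list(intercept = tr$intercept, slope = tr$slope,
                 fraction = tr$fraction),
            class = "calibration_line")
}

# solve one phantom end to end with package defaults except mesh spacing
solve_phantom <- function(phantom, impact_F = 5300) {
  line <- truth_line(phantom)
  bmd <- apply_calibration(phantom$image, line, phantom$femur_mask)
  mesh <- build_mesh(phantom$femur_mask, phantom$image$spacing_mm,
                     phantom$image$spacing_mm,
                     plate_thickness(phantom$truth$params$neck_width_mm))
  mat <- material_field(mesh, bmd)
  sol <- assemble_and_solve(mesh, mat, load_case(impact_F), phantom$regions)
  list(mesh = mesh, mat = mat, sol = sol)
}

# independent brute-force oracles ------------------------------------------

# principal strains by explicit 2x2 eigen decomposition
eigen_principal <- function(exx, eyy, gxy) {
  ev <- eigen(matrix(c(exx, gxy / 2, gxy / 2, eyy), 2, 2), symmetric = TRUE)
  sort(ev$values, decreasing = TRUE)
}

# VIF by explicit lm per column
brute_vif <- function(x) {
  x <- as.data.frame(x)
  vapply(seq_along(x), function(j) {
    fit <- stats::lm(x[[j]] ~ ., data = x[-j])
    1 / (1 - summary(fit)$r.squared)
  }, numeric(1))
}

# exhaustive AIC enumeration via normal equations, independent of aic_rank
brute_aic_rank <- function(x, y) {
  x <- scale(as.matrix(x))
  p <- ncol(x); n <- length(y)
  models <- list(); aics <- c()
  subsets <- unlist(lapply(seq_len(p), function(k)
    utils::combn(p, k, simplify = FALSE)), recursive = FALSE)
  for (s in subsets) {
    xm <- cbind(1, x[, s, drop = FALSE])
    beta <- solve(t(xm) %*% xm, t(xm) %*% y)
    rss <- sum((y - xm %*% beta)^2)
    aics <- c(aics, n * log(rss / n) + 2 * (length(s) + 2))
    models <- c(models, list(s))
  }
  w <- exp(-(aics - min(aics)) / 2); w <- w / sum(w)
  cum <- vapply(seq_len(p), function(j)
    sum(w[vapply(models, function(s) j %in% s, logical(1))]), numeric(1))
  stats::setNames(cum, colnames(x))
}
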