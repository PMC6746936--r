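# Cohort statistics: variance-inflation-factor collinearity filtering,
# exhaustive-subset AIC with cumulative Akaike weights ranking geometric
# predictors of the fracture-risk score, and a rank-correlation utility.

vif_one <- function(j, x) {
  xj <- x[, j]
  xo <- cbind(1, x[, -j, drop = FALSE])
  fit <- stats::lm.fit(xo, xj)
  rss <- sum(fit$residuals^2)
  tss <- sum((xj - mean(xj))^2)
  if (tss == 0) return(Inf)                 # constant column
  r2 <- 1 - rss / tss
  if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
}

#' Iterative VIF collinearity filter
#'
#' Computes each variable's variance inflation factor, VIF_j = 1/(1 - R^2_j)
#' from regressing variable j on all the others, and removes the
#' highest-VIF variable (ties broken alphabetically, so the result is
#' invariant to column order) until all VIFs are at or below the threshold.
#' Perfectly collinear columns have infinite VIF and leave first, with a
#' warning.
#'
#' @param x data.frame or matrix of numeric predictors (n rows, one column
#'   per variable; column names required)
#' @param threshold maximum acceptable VIF (default 10)
#' @return list with `retained` (character), `removed` (character, in removal
#'   order), `vif` (named numeric, final VIFs of the retained set)
#' @export
vif_filter <- function(x, threshold = 10) {
  x <- as.matrix(as.data.frame(x))
  if (is.null(colnames(x))) stop("predictor columns must be named")
  if (!is.numeric(x)) stop("predictors must be numeric")
  removed <- character()
  while (ncol(x) > 1L) {
    v <- vapply(seq_len(ncol(x)), vif_one, numeric(1), x = x)
    names(v) <- colnames(x)
    if (max(v) <= threshold) break
    worst <- v[v == max(v)]
    drop_name <- sort(names(worst))[1]
    if (is.infinite(v[[drop_name]]))
      warning(sprintf("'%s' is perfectly collinear (infinite VIF); removed",
                      drop_name))
    removed <- c(removed, drop_name)
    x <- x[, setdiff(colnames(x), drop_name), drop = FALSE]
  }
  v <- if (ncol(x) > 1L) {
    out <- vapply(seq_len(ncol(x)), vif_one, numeric(1), x = x)
    stats::setNames(out, colnames(x))
  } else stats::setNames(1, colnames(x))
  list(retained = colnames(x), removed = removed, vif = v)
}

#' Exhaustive-subset AIC ranking with cumulative Akaike weights
#'
#' Fits every non-empty subset of the predictors as a linear model of the
#' response (intercept always included, predictors z-scored), scores each
#' model with AIC = n*ln(RSS/n) + 2*(k + 2) where k is the number of
#' predictors (intercept and error variance counted as parameters), converts
#' AIC differences into Akaike weights w_i = exp(-Delta_i/2) / sum, and ranks
#' each variable by the cumulative weight of the models containing it.
#'
#' @param x data.frame or matrix of predictors (p <= 15)
#' @param y numeric response (the per-patient RF^)
#' @param aicc use the small-sample corrected AICc instead of plain AIC
#' @return object of class `aic_ranking`: `variables` (data.frame: variable,
#'   cum_weight, sorted descending), `models` (data.frame: model, k, aic,
#'   delta, weight), `n`, `aicc`
#' @export
aic_rank <- function(x, y, aicc = FALSE) {
  x <- as.matrix(as.data.frame(x))
  if (is.null(colnames(x))) stop("predictor columns must be named")
  p <- ncol(x)
  if (p > 15L)
    stop("p > 15: exhaustive enumeration infeasible; pre-filter (e.g. vif_filter)")
  n <- length(y)
  if (nrow(x) != n) stop("x and y sizes differ")
  if (any(!is.finite(y))) stop("missing response values are not allowed")
  xs <- scale(x)
  if (any(!is.finite(xs))) stop("constant predictor column cannot be z-scored")

  n_models <- 2L^p - 1L
  aic <- numeric(n_models)
  kk <- integer(n_models)
  labels <- character(n_models)
  contains <- matrix(FALSE, n_models, p)
  for (m in seq_len(n_models)) {
    sel <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) != 0L)
    contains[m, sel] <- TRUE
    fit <- stats::lm.fit(cbind(1, xs[, sel, drop = FALSE]), y)
    rss <- sum(fit$residuals^2)
    k <- length(sel)
    kpar <- k + 2L                            # + intercept + error variance
    a <- n * log(rss / n) + 2 * kpar
    if (aicc) a <- a + 2 * kpar * (kpar + 1) / (n - kpar - 1)
    aic[m] <- a
    kk[m] <- k
    labels[m] <- paste(colnames(x)[sel], collapse = "+")
  }
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  cum <- as.numeric(crossprod(contains, w))
  ord <- order(cum, decreasing = TRUE)
  structure(list(
    variables = data.frame(variable = colnames(x)[ord], cum_weight = cum[ord],
                           row.names = NULL),
    models = data.frame(model = labels, k = kk, aic = aic, delta = delta,
                        weight = w, row.names = NULL),
    n = n, aicc = aicc), class = "aic_ranking")
}

#' Spearman rank correlation with a t-approximation p value
#'
#' Ranks use average ranks for ties. The p value comes from the
#' t-approximation t = rho * sqrt((n-2)/(1-rho^2)); for small samples a
#' permutation p value is available.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @param p_method `"t"` (default) or `"permutation"`
#' @param n_perm number of permutations when `p_method = "permutation"`
#' @return list with `rho` and `p`
#' @export
spearman_rho <- function(x, y, p_method = c("t", "permutation"),
                         n_perm = 10000L) {
  p_method <- match.arg(p_method)
  n <- length(x)
  if (length(y) != n || n < 3L) stop("x and y must have equal length >= 3")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("constant input: Spearman's rho undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (p_method == "t") {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    ge <- 0L
    for (b in seq_len(n_perm))
      ge <- ge + (abs(stats::cor(rx, sample(ry))) >= abs(rho) - 1e-12)
    p <- (1 + ge) / (n_perm + 1)
  }
  list(rho = rho, p = p)
}

#' Rank HSA geometry against the fracture-risk score
#'
#' Formula-interface front end: filters the predictors for collinearity with
#' [vif_filter()], then ranks the retained variables with [aic_rank()].
#'
#' @param formula model formula, e.g. `rf_hat ~ .`
#' @param data data.frame holding the response and the HSA variables
#' @param vif_threshold VIF cutoff (default 10)
#' @param aicc use small-sample AICc
#' @return object of class `hsa_ranking`: `ranking` (an `aic_ranking`),
#'   `vif` (the [vif_filter()] result), `response` (name)
#' @export
rank_hsa <- function(formula, data, vif_threshold = 10, aicc = FALSE) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- mf[, -1, drop = FALSE]
  x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  vf <- vif_filter(x, threshold = vif_threshold)
  keep <- vf$retained
  if (length(keep) > 15L) {
    warning("more than 15 variables passed the VIF filter; ",
            "keeping the 15 least collinear for the exhaustive enumeration")
    keep <- names(sort(vf$vif))[1:15]
  }
  rk <- aic_rank(x[, keep, drop = FALSE], y, aicc = aicc)
  structure(list(ranking = rk, vif = vf,
                 response = deparse(formula[[2]])),
            class = "hsa_ranking")
}

#' @export
print.aic_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("exhaustive AIC%s ranking: %d models over %d variables (n = %d)\n",
              if (x$aicc) "c" else "", nrow(x$models), nrow(x$variables), x$n))
  print(utils::head(x$variables, n), row.names = FALSE)
  invisible(x)
}

#' @export
print.hsa_ranking <- function(x, ...) {
  cat(sprintf("HSA ranking against %s\n", x$response))
  if (length(x$vif$removed))
    cat("removed as collinear:", paste(x$vif$removed, collapse = ", "), "\n")
  print(x$ranking)
  invisible(x)
}

#' @export
summary.hsa_ranking <- function(object, ...) {
  cat(sprintf("%d of %d variables retained after VIF filtering (max VIF %.2f)\n",
              length(object$vif$retained),
              length(object$vif$retained) + length(object$vif$removed),
              max(object$vif$vif[is.finite(object$vif$vif)])))
  print(object$ranking, n = nrow(object$ranking$variables))
  invisible(object)
}
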