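# Latitudinal sampling-bias analysis: 1-degree binning of occurrences and
# collections, rank correlations between the two curves, and generalized
# least squares with AR(1) errors plus AICc model selection over
# sampling-bias covariates (outcrop area, vegetation cover, slope).

#' Count records in 1-degree latitudinal bins
#'
#' Bins are half-open `[b, b + width)` on modern latitude; empty bins inside
#' the extent are reported with count 0.
#'
#' @param records Data frame with a `latitude` column (occurrences or
#'   collections).
#' @param bin_width Bin width in degrees. Default 1.
#' @param extent Optional `c(lo, hi)` covering the study extent (bins span
#'   `[lo, hi)`). Defaults to the span of the data. Records outside an
#'   explicit extent are dropped with a warning.
#' @return A tibble with columns `bin_floor` and `count`.
#' @export
bin_by_latitude <- function(records, bin_width = 1, extent = NULL) {
  if (!"latitude" %in% names(records)) abort("`records` lacks a `latitude` column.")
  lat <- records$latitude
  bad <- which(is.na(lat) | lat < -90 | lat > 90)
  if (length(bad) > 0) {
    abort(sprintf(
      "Invalid latitude in record(s) %s (value%s: %s).",
      paste(head(bad, 5), collapse = ", "),
      if (length(bad) > 1) "s" else "",
      paste(head(lat[bad], 5), collapse = ", ")
    ))
  }
  if (is.null(extent)) {
    extent <- c(
      floor(min(lat) / bin_width) * bin_width,
      floor(max(lat) / bin_width) * bin_width + bin_width
    )
  }
  outside <- lat < extent[1] | lat >= extent[2]
  if (any(outside)) {
    warn(sprintf("%d record(s) outside the extent [%g, %g) dropped.",
                 sum(outside), extent[1], extent[2]))
    lat <- lat[!outside]
  }
  floors <- seq(extent[1], extent[2] - bin_width, by = bin_width)
  idx <- floor((lat - extent[1]) / bin_width) + 1
  tibble(
    bin_floor = floors,
    count = as.integer(tabulate(idx, nbins = length(floors)))
  )
}

#' Rank correlations between two latitudinal series
#'
#' Spearman's rho and Kendall's tau-b (midranks under ties), with p-values
#' from the asymptotic approximations of [stats::cor.test()].
#'
#' @param a,b Numeric vectors of equal length (>= 3), e.g. the `count`
#'   columns of two [bin_by_latitude()] series on the same bins.
#' @return A one-row tibble: `rho`, `p_rho`, `tau`, `p_tau`, `n`.
#' @export
correlate_series <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) abort("Series must have equal length.")
  if (length(a) < 3) abort("Need at least 3 paired bins.")
  if (sd(a) == 0 || sd(b) == 0) {
    abort("zero variance: rank correlation is undefined for a constant series")
  }
  st <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
  kt <- suppressWarnings(cor.test(a, b, method = "kendall", exact = FALSE))
  tibble(
    rho = unname(st$estimate),
    p_rho = st$p.value,
    tau = unname(kt$estimate),
    p_tau = kt$p.value,
    n = length(a)
  )
}

# AR(1) whitening transform: maps y ~ N(Xb, sigma2 * R(phi)) to iid errors.
# First element scaled by sqrt(1 - phi^2); the log-determinant of the
# transform is log(1 - phi^2) / 2.
ar1_whiten <- function(v, phi) {
  n <- length(v)
  c(sqrt(1 - phi^2) * v[1], v[-1] - phi * v[-n])
}

# Profile log-likelihood pieces at fixed phi: whitened OLS for beta, closed
# form for the innovation variance.
ar1_profile <- function(phi, y, X) {
  n <- length(y)
  ys <- ar1_whiten(y, phi)
  Xs <- apply(X, 2, ar1_whiten, phi = phi)
  fit <- lm.fit(Xs, ys)
  rss <- sum(fit$residuals^2)
  ll <- -n / 2 * log(2 * pi * rss / n) - n / 2 + 0.5 * log(1 - phi^2)
  list(loglik = ll, beta = fit$coefficients, rss = rss, Xs = Xs, ys = ys)
}

#' Generalized least squares with AR(1) errors
#'
#' Maximum-likelihood fit of `y = X beta + e` where the errors follow a
#' stationary first-order autoregressive process in series order:
#' `Corr(e_i, e_j) = phi^|i-j|`, marginal variance `sigma2`. For each
#' candidate `phi` the model is whitened and `beta` solved by least squares;
#' `phi` is then chosen to maximize the profile log-likelihood on a bounded
#' search. ML (not REML) is used throughout so that models with different
#' fixed effects are comparable by AICc.
#'
#' The AICc parameter count `k` includes the fixed effects (with intercept),
#' `sigma2`, and `phi` (also when `phi` is held fixed, for comparability).
#'
#' @param data Data frame holding the response and covariates.
#' @param formula Model formula, e.g. `log(count + 1) ~ log(outcrop_km2)`.
#' @param phi Optional fixed AR(1) parameter in (-1, 1); `NULL` (default)
#'   estimates it by profile likelihood.
#' @param phi_bounds Search interval for `phi`. Default `c(-0.99, 0.99)`.
#' @return A `gls_ar1` object with elements `coefficients`, `phi`, `sigma2`
#'   (marginal error variance), `logLik`, `k`, `n`, `AICc`, `fitted`,
#'   `residuals`, `vcov`. Has [tidy()] and [glance()] methods.
#' @examples
#' d <- data.frame(x = 1:20, y = 2 + 0.5 * (1:20) + rnorm(20, sd = 0.3))
#' fit <- fit_gls_ar1(d, y ~ x)
#' glance(fit)
#' @export
fit_gls_ar1 <- function(data, formula, phi = NULL, phi_bounds = c(-0.99, 0.99)) {
  mf <- model.frame(formula, data = data)
  y <- as.numeric(model.response(mf))
  X <- model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p) abort("Design matrix is rank deficient.")
  if (n <= p + 1) abort("Too few observations for the number of parameters.")
  if (!is.null(phi)) {
    if (abs(phi) >= 1) abort("`phi` must lie in (-1, 1).")
    phi_hat <- phi
  } else {
    opt <- optimize(function(ph) ar1_profile(ph, y, X)$loglik,
                    interval = phi_bounds, maximum = TRUE, tol = 1e-9)
    # the profile can be maximized at the boundary of the search interval;
    # also compare phi = 0 so independence is recovered exactly when optimal
    cand <- c(opt$maximum, 0)
    lls <- purrr::map_dbl(cand, ~ ar1_profile(.x, y, X)$loglik)
    phi_hat <- cand[which.max(lls)]
  }
  prof <- ar1_profile(phi_hat, y, X)
  sigma2_innov <- prof$rss / n
  sigma2 <- sigma2_innov / (1 - phi_hat^2)
  k <- p + 2L
  aicc <- aicc_from_loglik(prof$loglik, k, n)
  xtx_inv <- chol2inv(chol(crossprod(prof$Xs)))
  fitted <- as.numeric(X %*% prof$beta)
  structure(
    list(
      coefficients = setNames(as.numeric(prof$beta), colnames(X)),
      phi = phi_hat,
      phi_fixed = !is.null(phi),
      sigma2 = sigma2,
      logLik = prof$loglik,
      k = k,
      n = n,
      AICc = aicc,
      fitted = fitted,
      residuals = y - fitted,
      vcov = sigma2_innov * xtx_inv,
      formula = formula
    ),
    class = "gls_ar1"
  )
}

#' @export
print.gls_ar1 <- function(x, ...) {
  cat("<gls_ar1> ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  phi = %.4f%s, sigma2 = %.4g, logLik = %.4f, AICc = %.4f (k = %d, n = %d)\n",
              x$phi, if (x$phi_fixed) " (fixed)" else "", x$sigma2,
              x$logLik, x$AICc, x$k, x$n))
  print(x$coefficients)
  invisible(x)
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`; `Inf` when `n <= k + 1`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations.
#' @return AICc value.
#' @export
aicc_from_loglik <- function(loglik, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AICc_i - min(AICc)`.
#'
#' @param aicc Numeric vector of AICc values.
#' @return Numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(aicc) {
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' AICc model selection over covariate subsets
#'
#' Fits [fit_gls_ar1()] by maximum likelihood to every additive subset of
#' the candidate covariates (plus the intercept-only null model when
#' `include_null`), and ranks models by AICc. Reports delta-AICc, Akaike
#' weights, and the likelihood-ratio pseudo-R-squared
#' `1 - exp(-(2/n) (logL_model - logL_null))` (0 for the null model by
#' construction). Rows with missing values in the response or any candidate
#' covariate are dropped listwise before fitting.
#'
#' @param data Data frame of aligned per-bin series.
#' @param response Name of the response column. Supply it already on the
#'   scale to be modelled (e.g. `log1p` of a count).
#' @param covariates Character vector of candidate covariate column names.
#' @param include_null Include the intercept-only model. Default `TRUE`.
#' @param max_models Cap on the number of candidate models (2^m subsets).
#' @return A `gls_model_selection` object: a ranked tibble (`model`, `k`,
#'   `logLik`, `AICc`, `delta_AICc`, `weight`, `pseudo_R2`) with the fitted
#'   objects attached as attribute `fits`.
#' @export
model_selection <- function(data, response, covariates, include_null = TRUE,
                            max_models = 256) {
  stopifnot(is.character(response), length(response) == 1)
  if (length(covariates) < 1) abort("Provide at least one candidate covariate.")
  miss <- setdiff(c(response, covariates), names(data))
  if (length(miss) > 0) {
    abort(paste0("Columns not in `data`: ", paste(miss, collapse = ", ")))
  }
  n_models <- 2^length(covariates) - !include_null
  if (n_models > max_models) {
    abort(sprintf(
      "%d candidate models exceed the cap of %d; reduce the covariate set.",
      n_models, max_models
    ))
  }
  used <- data[, c(response, covariates), drop = FALSE]
  complete <- stats::complete.cases(used)
  if (any(!complete)) {
    warn(sprintf("%d row(s) with missing values dropped listwise.", sum(!complete)))
  }
  used <- used[complete, , drop = FALSE]

  subsets <- purrr::flatten(purrr::map(
    seq_along(covariates),
    ~ utils::combn(covariates, .x, simplify = FALSE)
  ))
  if (include_null) subsets <- c(list(character(0)), subsets)

  null_fit <- fit_gls_ar1(used, reformulate("1", response))
  n <- null_fit$n
  fits <- purrr::map(subsets, function(vars) {
    if (length(vars) == 0) null_fit else fit_gls_ar1(used, reformulate(vars, response))
  })
  tab <- tibble(
    model = purrr::map_chr(subsets, ~ if (length(.x) == 0) "(null)" else paste(.x, collapse = " + ")),
    k = purrr::map_int(fits, ~ .x$k),
    logLik = purrr::map_dbl(fits, ~ .x$logLik),
    AICc = purrr::map_dbl(fits, ~ .x$AICc),
    pseudo_R2 = purrr::map_dbl(fits, ~ max(0, 1 - exp(-(2 / n) * (.x$logLik - null_fit$logLik))))
  )
  tab$delta_AICc <- tab$AICc - min(tab$AICc)
  tab$weight <- akaike_weights(tab$AICc)
  ord <- order(tab$AICc)
  tab <- tab[ord, c("model", "k", "logLik", "AICc", "delta_AICc", "weight", "pseudo_R2")]
  structure(
    list(table = tab, fits = setNames(fits, purrr::map_chr(subsets, paste, collapse = "+"))[ord],
         response = response, n = n),
    class = "gls_model_selection"
  )
}

#' @export
print.gls_model_selection <- function(x, ...) {
  cat(sprintf("<gls_model_selection> response: %s, n = %d bins\n", x$response, x$n))
  print(x$table, ...)
  invisible(x)
}
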