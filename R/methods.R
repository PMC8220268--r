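# broom-style tidiers for the package's result objects.

#' @rdname tidy.gls_ar1
#' @method tidy pbc_resample
#' @export
tidy.pbc_resample <- function(x, ...) {
  tibble(replicate = seq_len(x$n_reps), value = x$values)
}

#' @rdname tidy.gls_ar1
#' @method glance pbc_resample
#' @export
glance.pbc_resample <- function(x, ...) {
  dplyr::bind_cols(
    tibble(label = x$label, observed = x$observed, n_reps = x$n_reps),
    x$summary,
    tibble(seed = x$seed %||% NA_integer_)
  )
}

#' @rdname tidy.gls_ar1
#' @method tidy pbc_rarefaction
#' @export
tidy.pbc_rarefaction <- function(x, ...) x$curve

#' @rdname tidy.gls_ar1
#' @method glance pbc_rarefaction
#' @export
glance.pbc_rarefaction <- function(x, ...) {
  tibble(observed = x$observed, mu = x$mu,
         min_level = min(x$curve$level), max_level = max(x$curve$level),
         seed = x$seed %||% NA_integer_)
}

#' @rdname tidy.gls_ar1
#' @method tidy pbc_permutation
#' @export
tidy.pbc_permutation <- function(x, ...) {
  tibble(replicate = seq_along(x$null_values), null_value = x$null_values)
}

#' @rdname tidy.gls_ar1
#' @method glance pbc_permutation
#' @export
glance.pbc_permutation <- function(x, ...) {
  tibble(
    observed = x$observed, p_value = x$p_value,
    alternative = x$alternative, n_reps = x$n_reps,
    null_mean = mean(x$null_values), null_sd = sd(x$null_values),
    mu = x$mu, seed = x$seed %||% NA_integer_
  )
}

#' Tidiers for package result objects
#'
#' [generics::tidy()] and [generics::glance()] methods: `tidy()` returns the
#' per-term / per-replicate / per-level detail as a tibble; `glance()`
#' returns a one-row model or distribution summary.
#'
#' @param x A fitted `gls_ar1`, a `gls_model_selection` table, or a
#'   resampling result (`pbc_resample`, `pbc_rarefaction`,
#'   `pbc_permutation`, `pbc_subsample`).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy gls_ar1
#' @export
tidy.gls_ar1 <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  est <- x$coefficients
  tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * stats::pnorm(abs(unname(est / se)), lower.tail = FALSE)
  )
}

#' @rdname tidy.gls_ar1
#' @method glance gls_ar1
#' @export
glance.gls_ar1 <- function(x, ...) {
  tibble(
    logLik = x$logLik, AICc = x$AICc, phi = x$phi, sigma2 = x$sigma2,
    k = x$k, nobs = x$n
  )
}

#' @rdname tidy.gls_ar1
#' @method tidy gls_model_selection
#' @export
tidy.gls_model_selection <- function(x, ...) x$table

#' @rdname tidy.gls_ar1
#' @method glance gls_model_selection
#' @export
glance.gls_model_selection <- function(x, ...) {
  best <- x$table[1, ]
  tibble(
    best_model = best$model, AICc = best$AICc, weight = best$weight,
    pseudo_R2 = best$pseudo_R2, n_models = nrow(x$table), nobs = x$n
  )
}

#' @rdname tidy.gls_ar1
#' @method tidy pbc_subsample
#' @export
tidy.pbc_subsample <- function(x, ...) {
  tibble(replicate = seq_len(x$distribution$n_reps),
         value = x$distribution$values)
}

#' @rdname tidy.gls_ar1
#' @method glance pbc_subsample
#' @export
glance.pbc_subsample <- function(x, ...) {
  dplyr::bind_cols(
    tibble(removal_fraction = x$removal_fraction,
           band_min = x$lat_band[1], band_max = x$lat_band[2],
           n_band_taxa = x$n_band_taxa,
           observed = x$distribution$observed),
    x$distribution$summary
  )
}
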