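# broom-style tidiers for the package's fitted/result objects.

#' Tidy a GS/IS regression fit
#'
#' One row per model term, via [broom::tidy()] on the underlying `lm`.
#'
#' @param x A `mite_gsis` object.
#' @param ... Passed to [broom::tidy()].
#' @return A tibble of term estimates.
#' @export
tidy.mite_gsis <- function(x, ...) {
  broom::tidy(x$model, ...)
}

#' Glance at a GS/IS regression fit
#'
#' @param x A `mite_gsis` object.
#' @param ... Unused.
#' @return A one-row tibble: `r.squared`, `p.value`, `slope`, `intercept`,
#'   `n_families`, `n_outliers`.
#' @export
glance.mite_gsis <- function(x, ...) {
  tibble(
    r.squared = x$r_squared, p.value = x$p_value,
    slope = x$slope, intercept = x$intercept,
    n_families = nrow(x$data), n_outliers = length(x$outlier_families)
  )
}

#' Tidy a family diversity result
#'
#' @param x A `mite_diversity` object.
#' @param ... Unused.
#' @return A tibble with one row per pairwise comparison (`k`).
#' @export
tidy.mite_diversity <- function(x, ...) {
  tibble(family = x$family_name, k = x$k_values)
}

#' Glance at a family diversity result
#'
#' @param x A `mite_diversity` object.
#' @param ... Unused.
#' @return A one-row tibble: `family`, `n_members`, `n_pairs`, `k_mean`,
#'   `modality`, `n_peaks`.
#' @export
glance.mite_diversity <- function(x, ...) {
  tibble(
    family = x$family_name, n_members = x$n_members,
    n_pairs = length(x$k_values), k_mean = x$k_mean,
    modality = x$modality, n_peaks = length(x$peaks)
  )
}
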