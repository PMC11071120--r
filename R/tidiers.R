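# broom-style accessors for fitted objects.

#' Tidy a fitted expression model
#'
#' @param x A `regdom_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `location`, `estimate` (the intercept appears as
#'   term `(Intercept)` with location `NA`).
#' @export
tidy.regdom_fit <- function(x, ...) {
  bind_rows(
    tibble(term = "(Intercept)", location = NA_character_,
           estimate = x$intercept),
    tibble(term = x$feature_names,
           location = unname(x$location),
           estimate = unname(x$coefficients))
  )
}

#' One-row model summary
#'
#' @param x A `regdom_fit`.
#' @param ... Unused.
#' @return Tibble `n_features`, `n_genes`, `rse`, `cv_rse`, `aic`,
#'   `pearson_r`.
#' @export
glance.regdom_fit <- function(x, ...) {
  tibble(n_features = length(x$feature_names), n_genes = x$n,
         rse = x$rse, cv_rse = x$cv_rse, aic = x$aic,
         pearson_r = x$pearson_r)
}

#' Tidy an RC ensemble
#'
#' @param x A `regdom_ensemble`.
#' @param ... Unused.
#' @return The ensemble as a plain tibble (per-run coefficients unnested
#'   into `run`/`rc` columns).
#' @export
tidy.regdom_ensemble <- function(x, ...) {
  as_tibble(x) |>
    mutate(run = list(seq_len(attr(x, "n_runs") %||% length(x$rcs[[1]])))) |>
    tidyr::unnest(c("rcs", "run")) |>
    rename(rc = "rcs")
}

#' One-row ensemble summary
#'
#' @param x A `regdom_ensemble`.
#' @param ... Unused.
#' @return Tibble `n_features`, `n_runs`, `mean_rse`, `mean_cv_rse`,
#'   `pearson_r`, `n_significant` (NA before [test_rc_significance()]).
#' @export
glance.regdom_ensemble <- function(x, ...) {
  tibble(n_features = nrow(x),
         n_runs = attr(x, "n_runs"),
         mean_rse = attr(x, "mean_rse"),
         mean_cv_rse = attr(x, "mean_cv_rse"),
         pearson_r = attr(x, "pooled_pearson_r"),
         n_significant = if ("significant" %in% names(x)) {
           sum(x$significant)
         } else {
           NA_integer_
         })
}
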