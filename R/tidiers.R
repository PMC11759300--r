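# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a factor model's rotated loadings
#'
#' @param x A `muscle_factor_model`.
#' @param ... Unused.
#' @return Tibble with `factor`, `feature`, `loading` (all 48 x K cells).
#' @export
tidy.muscle_factor_model <- function(x, ...) {
  out <- tibble::as_tibble(as.table(x$loadings), .name_repair = "minimal")
  names(out) <- c("feature", "factor", "loading")
  dplyr::select(out, "factor", "feature", "loading")
}

#' One-row summary of a factor model
#'
#' @param x A `muscle_factor_model`.
#' @param ... Unused.
#' @return Tibble: `n_factors`, `chisq`, `df`, `p.value`,
#'   `cumulative_variance`, `n_obs`.
#' @export
glance.muscle_factor_model <- function(x, ...) {
  tibble::tibble(
    n_factors = x$n_factors, chisq = x$fit$chisq, df = x$fit$df,
    p.value = x$fit$p.value, cumulative_variance = x$cumulative_variance,
    n_obs = x$n_obs
  )
}

#' Tidy a mixed-effects disease model
#'
#' Stacks the fixed-effect F tests and the per-level ALS-vs-control
#' contrasts.
#'
#' @param x A `muscle_lme`.
#' @param ... Unused.
#' @return Tibble with `type` (`"anova"` / `"contrast"`), `term`,
#'   `statistic`, `p.value`, `adj.p.value`.
#' @export
tidy.muscle_lme <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(type = "anova", term = x$anova$effect,
                   statistic = x$anova$statistic,
                   p.value = x$anova$p.value, adj.p.value = NA_real_),
    tibble::tibble(type = "contrast", term = x$contrasts$level,
                   statistic = x$contrasts$statistic,
                   p.value = x$contrasts$p.value,
                   adj.p.value = x$contrasts$adj.p.value)
  )
}

#' One-row summary of a mixed-effects disease model
#'
#' @param x A `muscle_lme`.
#' @param ... Unused.
#' @return Tibble: `feature`, `r2.marginal`, `r2.conditional`.
#' @export
glance.muscle_lme <- function(x, ...) {
  tibble::tibble(feature = x$feature,
                 r2.marginal = unname(x$r2["marginal"]),
                 r2.conditional = unname(x$r2["conditional"]))
}

#' Tidy a stepwise mixed model
#'
#' @param x A `muscle_stepwise_lme`.
#' @param ... Unused.
#' @return Coefficient tibble of the final REML fit.
#' @export
tidy.muscle_stepwise_lme <- function(x, ...) x$coefficients

#' One-row summary of a stepwise mixed model
#'
#' @param x A `muscle_stepwise_lme`.
#' @param ... Unused.
#' @return Tibble: `outcome`, `n_selected`, `r2.marginal`,
#'   `r2.conditional`.
#' @export
glance.muscle_stepwise_lme <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, n_selected = length(x$selected),
                 r2.marginal = unname(x$r2["marginal"]),
                 r2.conditional = unname(x$r2["conditional"]))
}

#' Tidy a classifier report
#'
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @return Per-repeat metric tibble.
#' @export
tidy.classifier_report <- function(x, ...) x$per_repeat

#' One-row summary of a classifier report
#'
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @return Tibble: `algorithm`, `auc`, `f1`, `precision`, `recall`.
#' @export
glance.classifier_report <- function(x, ...) x$metrics
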