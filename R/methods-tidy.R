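#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trait imputation model
#'
#' One row per feature with its impurity importance.
#'
#' @param x A `trait_model`.
#' @param ... Unused.
#' @return Tibble with `feature` and `importance`.
#' @export
tidy.trait_model <- function(x, ...) {
  imp <- x$forest$variable.importance
  if (is.null(imp)) imp <- stats::setNames(rep(NA_real_, length(x$features)),
                                           x$features)
  tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' One-row summary of a trait imputation model
#'
#' @param x A `trait_model`.
#' @param ... Unused.
#' @return Tibble with the trait name, training size, tree count and
#'   held-out R^2.
#' @export
glance.trait_model <- function(x, ...) {
  tibble::tibble(trait = x$trait, n_train = x$n_train,
                 num_trees = x$num_trees,
                 r_squared_holdout = x$r_squared_holdout)
}

#' Per-pixel results of a scenario run
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return The per-dive-pixel economics tibble.
#' @export
tidy.scenario_result <- function(x, ...) x$pixels

#' One-row aggregate summary of a scenario run
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return One-row tibble of aggregates plus the biological summaries.
#' @export
glance.scenario_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(policy = x$policy, fee_usd = x$fee),
    x$summary,
    tibble::tibble(
      biomass_mean_pct_change = x$biomass$mean_pct_change,
      biodiversity_delta_score = x$biodiversity$delta_score
    )
  )
}

#' Per-run outcomes of a Monte-Carlo ensemble
#'
#' @param x A `dive_monte_carlo`.
#' @param ... Unused.
#' @return Per-run, per-policy outcomes tibble.
#' @export
tidy.dive_monte_carlo <- function(x, ...) x$runs

#' Ensemble summary of a Monte-Carlo run
#'
#' @param x A `dive_monte_carlo`.
#' @param ... Unused.
#' @return One-row tibble of ensemble statistics.
#' @export
glance.dive_monte_carlo <- function(x, ...) x$summary
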