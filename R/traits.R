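#' Aggregate multiple empirical trait observations for one species
#'
#' Species with trait values from several studies are summarised by the
#' geometric mean, the conventional aggregate for positive, right-skewed
#' life-history traits.
#'
#' @param values Positive numeric vector of trait observations.
#' @return Geometric mean.
#' @export
aggregate_empirical_trait <- function(values) {
  if (length(values) == 0 || any(!is.finite(values) | values <= 0)) {
    stop("trait values must be a nonempty set of positive numbers",
         call. = FALSE)
  }
  exp(mean(log(values)))
}

#' Adult movement radius from home range
#'
#' Treats the home range (km^2) as the area of a circle, so adults can
#' redistribute within radius `zeta = sqrt(home_range / pi)` km of their
#' pixel.
#'
#' @param home_range_km2 Home range in km^2 (>= 0).
#' @return Radius in km.
#' @export
adult_radius <- function(home_range_km2) {
  if (any(home_range_km2 < 0, na.rm = TRUE)) {
    stop("home range must be nonnegative", call. = FALSE)
  }
  sqrt(home_range_km2 / pi)
}

#' Larval dispersal kernel spread from pelagic larval duration
#'
#' Empirical relationship between the Gaussian larval-kernel spread sigma
#' (km) and the pelagic larval duration (days):
#' `sigma = 1.33 * sqrt(pi / 2) * PLD^1.3`.
#'
#' @param pld_days Pelagic larval duration in days (>= 0).
#' @return Kernel spread sigma in km.
#' @export
larval_sigma <- function(pld_days) {
  if (any(pld_days < 0, na.rm = TRUE)) {
    stop("PLD must be nonnegative", call. = FALSE)
  }
  1.33 * sqrt(pi / 2) * pld_days^1.3
}

trait_features <- function() {
  c("r", "k", "length_cm", "trophic_level", "movement_keyword", "range_km2")
}

#' Fit a random-forest trait imputation model
#'
#' Regresses the log of a positive trait (home range or pelagic larval
#' duration) on life-history features: intrinsic growth rate, carrying
#' capacity, body length, trophic level, the ordered movement keyword and
#' geographic range size. A held-out split reports out-of-sample R^2 on the
#' log scale.
#'
#' @param training Data frame containing the feature columns and the trait.
#' @param trait Name of the trait column (positive values).
#' @param seed Seed controlling both the held-out split and the forest.
#' @param num_trees Number of trees (default 500).
#' @param holdout Fraction of rows held out for the R^2 estimate.
#' @param mtry Features tried per split; the default uses all of them,
#'   which suits the small, strongly informative feature set.
#' @param min_node_size Minimal terminal node size (default 3).
#' @return A `trait_model` object; see [predict.trait_model()],
#'   [tidy.trait_model()] and [glance.trait_model()].
#' @export
fit_trait_model <- function(training, trait, seed = 1L, num_trees = 500,
                            holdout = 0.25, mtry = NULL,
                            min_node_size = 3) {
  if (is.null(mtry)) mtry <- length(trait_features())
  feats <- trait_features()
  assert_cols(training, c(feats, trait), "training")
  training <- training[is.finite(training[[trait]]) & training[[trait]] > 0, ]
  if (nrow(training) < 10) {
    stop("need at least 10 complete training rows", call. = FALSE)
  }
  dat <- training[, feats]
  dat$.log_trait <- log(training[[trait]])

  withr::with_seed(as.integer(seed), {
    n <- nrow(dat)
    n_test <- max(2, round(holdout * n))
    test_idx <- sample.int(n, n_test)
    fit_part <- ranger::ranger(
      dependent.variable.name = ".log_trait", data = dat[-test_idx, ],
      num.trees = num_trees, seed = as.integer(seed), mtry = mtry,
      min.node.size = min_node_size
    )
    pred <- stats::predict(fit_part, dat[test_idx, ])$predictions
    y <- dat$.log_trait[test_idx]
    ss_res <- sum((y - pred)^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    # final model uses all rows
    fit <- ranger::ranger(
      dependent.variable.name = ".log_trait", data = dat,
      num.trees = num_trees, seed = as.integer(seed), mtry = mtry,
      min.node.size = min_node_size, importance = "impurity"
    )
  })
  structure(
    list(forest = fit, trait = trait, features = feats,
         r_squared_holdout = r2, n_train = nrow(dat), num_trees = num_trees,
         constant = if (stats::var(dat$.log_trait) == 0) exp(dat$.log_trait[1]) else NULL),
    class = "trait_model"
  )
}

#' Predict trait values for new stocks
#'
#' @param object A [fit_trait_model()] fit.
#' @param newdata Data frame with the feature columns.
#' @param ... Unused.
#' @return Numeric vector of trait predictions on the natural scale.
#' @export
predict.trait_model <- function(object, newdata, ...) {
  assert_cols(newdata, object$features, "newdata")
  if (!is.null(object$constant)) {
    return(rep(object$constant, nrow(newdata)))
  }
  exp(stats::predict(object$forest, newdata[, object$features])$predictions)
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf(
    "<trait_model> %s ~ %d features, %d trees, n = %d, held-out R^2 = %.3f\n",
    x$trait, length(x$features), x$num_trees, x$n_train, x$r_squared_holdout
  ))
  invisible(x)
}

#' Resolve dispersal traits for every stock
#'
#' Empirical trait values take priority where a stock is flagged
#' `is_empirical`; all other stocks get model predictions. Elasmobranchs
#' have no pelagic larval stage: their PLD and sigma are `NA` and their
#' larval settlement is natal-pixel-only. Stocks that can be neither
#' observed nor predicted are dropped with a warning.
#'
#' @param stocks Stock table with feature columns, `is_empirical`,
#'   `is_elasmobranch` and (for empirical stocks) `home_range_km2` /
#'   `pld_days`.
#' @param hr_model,pld_model [fit_trait_model()] fits for home range and
#'   PLD; `pld_model` may be `NULL` when every non-elasmobranch stock is
#'   empirical.
#' @return Tibble with `stock_id`, `home_range_km2`, `zeta_km`, `pld_days`,
#'   `sigma_km`, `hr_provenance` and `pld_provenance`
#'   (`"empirical"`/`"predicted"`).
#' @export
resolve_traits <- function(stocks, hr_model, pld_model = NULL) {
  assert_cols(stocks, c("stock_id", "is_empirical", "is_elasmobranch"),
              "stocks")
  n <- nrow(stocks)
  col_or_na <- function(nm) {
    if (nm %in% names(stocks)) stocks[[nm]] else rep(NA_real_, n)
  }
  hr <- rep(NA_real_, n)
  hr_prov <- rep("predicted", n)
  emp <- stocks$is_empirical & is.finite(col_or_na("home_range_km2"))
  hr[emp] <- stocks$home_range_km2[emp]
  hr_prov[emp] <- "empirical"
  need <- !emp
  if (any(need)) {
    if (is.null(hr_model)) {
      stop("hr_model required to predict home ranges", call. = FALSE)
    }
    hr[need] <- predict(hr_model, stocks[need, ])
  }

  pld <- rep(NA_real_, n)
  pld_prov <- rep(NA_character_, n)
  fish <- !stocks$is_elasmobranch
  emp_pld <- fish & stocks$is_empirical & is.finite(col_or_na("pld_days"))
  pld[emp_pld] <- stocks$pld_days[emp_pld]
  pld_prov[emp_pld] <- "empirical"
  need_pld <- fish & !emp_pld
  if (any(need_pld)) {
    if (is.null(pld_model)) {
      stop("pld_model required to predict PLD", call. = FALSE)
    }
    pld[need_pld] <- predict(pld_model, stocks[need_pld, ])
    pld_prov[need_pld] <- "predicted"
  }

  ok <- is.finite(hr) & (stocks$is_elasmobranch | is.finite(pld))
  if (any(!ok)) {
    warning(sprintf("dropping %d stock(s) without resolvable traits",
                    sum(!ok)), call. = FALSE)
  }
  tibble::tibble(
    stock_id = stocks$stock_id,
    home_range_km2 = hr,
    zeta_km = adult_radius(hr),
    pld_days = pld,
    sigma_km = ifelse(stocks$is_elasmobranch, NA_real_, larval_sigma(pld)),
    natal_only = stocks$is_elasmobranch,
    hr_provenance = hr_prov,
    pld_provenance = pld_prov
  )[ok, ]
}

#' Adult-movement matrix for one stock
#'
#' Adults redistribute uniformly over the pixels of the stock's range whose
#' centroids lie within the movement radius `zeta` of the source pixel
#' (always including the source itself), so every row sums to exactly 1. A
#' radius smaller than the pixel spacing yields the identity matrix.
#'
#' @param range_ids Pixel ids of the stock range.
#' @param zeta_km Movement radius in km.
#' @param dist_km Distance matrix over (at least) the range pixels, dimnames
#'   = pixel ids, as from [pixel_distances()].
#' @return Row-stochastic matrix, rows = source pixels, dimnames = range ids.
#' @export
build_movement_matrix <- function(range_ids, zeta_km, dist_km) {
  ids <- as.character(range_ids)
  d <- dist_km[ids, ids, drop = FALSE]
  within <- d <= max(zeta_km, 0)
  diag(within) <- TRUE
  m <- within / rowSums(within)
  dimnames(m) <- list(ids, ids)
  m
}

#' Larval dispersal matrix for one stock
#'
#' A Gaussian kernel `rho(d) = exp(-d^2 / (2 sigma^2)) / (2 pi sigma^2)`
#' (per km^2) evaluated at centroid distances, multiplied by the destination
#' pixel area and restricted to the stock range. Rows are renormalised to 1
#' by default so larval output is conserved on coarse grids; with
#' `renormalize = FALSE` the raw discretisation is returned (rows then need
#' not sum to 1, larvae may be lost offshore). `sigma = 0` or
#' `natal_only = TRUE` gives natal-pixel-only settlement (identity rows).
#'
#' @param range_ids Pixel ids of the stock range.
#' @param sigma_km Kernel spread in km.
#' @param dist_km Distance matrix with pixel-id dimnames.
#' @param area_km2 Destination pixel areas: scalar or vector along
#'   `range_ids`.
#' @param renormalize Renormalise each source row to sum to 1 (default TRUE).
#' @param natal_only All larvae settle in the natal pixel (elasmobranchs).
#' @return Matrix of settlement proportions, rows = source pixels.
#' @export
build_larval_matrix <- function(range_ids, sigma_km, dist_km, area_km2 = 2500,
                                renormalize = TRUE, natal_only = FALSE) {
  ids <- as.character(range_ids)
  n <- length(ids)
  if (natal_only || is.na(sigma_km) || sigma_km == 0) {
    m <- diag(1, n)
    dimnames(m) <- list(ids, ids)
    return(m)
  }
  d <- dist_km[ids, ids, drop = FALSE]
  kern <- exp(-d^2 / (2 * sigma_km^2)) / (2 * pi * sigma_km^2)
  m <- sweep(kern, 2, rep_len(area_km2, n), `*`)
  if (renormalize) m <- m / rowSums(m)
  dimnames(m) <- list(ids, ids)
  m
}

#' Persist a dispersal matrix in sparse triplet (coordinate) text form
#'
#' @param m Matrix with pixel-id dimnames.
#' @param path Output CSV path (`source_id, dest_id, value`; zeros omitted).
#' @return `path`, invisibly.
#' @export
write_dispersal_matrix <- function(m, path) {
  idx <- which(m != 0, arr.ind = TRUE)
  readr::write_csv(tibble::tibble(
    source_id = rownames(m)[idx[, 1]],
    dest_id = colnames(m)[idx[, 2]],
    value = m[idx]
  ), path)
  invisible(path)
}

#' Read a dispersal matrix written by [write_dispersal_matrix()]
#'
#' @param path CSV path in triplet form.
#' @return Dense matrix with pixel-id dimnames.
#' @export
read_dispersal_matrix <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(tr, c("source_id", "dest_id", "value"), "dispersal matrix")
  ids <- sort(unique(c(tr$source_id, tr$dest_id)))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(match(tr$source_id, ids), match(tr$dest_id, ids))] <- tr$value
  m
}
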