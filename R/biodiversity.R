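#' Species persistence under partial removal of abatable impacts
#'
#' Persistence is a concave, monotone-increasing function of the protected
#' fraction `p` of a species' range:
#' `persistence = (1 - q * (1 - p) - u)^z`,
#' where `q` is the abatable-impact fraction (the share of the species'
#' threat removable by full protection, e.g. fishing), `u` an optional
#' unabatable-impact share (nutrient pollution, warming; default 0) and `z`
#' a concavity exponent (default 0.25). With `u = 0` and full protection the
#' persistence is 1. The base is clamped at 0 before exponentiation.
#'
#' @param p Protected fraction of the species range, in `[0, 1]`.
#' @param q Abatable-impact fraction, in `[0, 1]`.
#' @param z Concavity exponent (> 0).
#' @param u Unabatable-impact share, in `[0, 1]` (default 0).
#' @return Persistence in `[0, 1]`; vectorised over `p`, `q`, `u`.
#' @export
species_persistence <- function(p, q, z = 0.25, u = 0) {
  assert_fraction(p, "protected fraction p")
  assert_fraction(q, "abatable fraction q")
  assert_fraction(u, "unabatable share u")
  stopifnot(z > 0)
  pmax(1 - q * (1 - p) - u, 0)^z
}

#' Assign normalized per-species weights from taxon aggregate weights
#'
#' Within each taxon, species share the taxon's aggregate weight uniformly,
#' so realized per-taxon aggregates equal the table entries exactly. Species
#' whose taxon is absent from the table are mapped to `"other"`.
#'
#' @param species Species table with `species_id` and `taxon_group`.
#' @param taxon_weights Taxon weight table (default
#'   [default_taxon_weights()]); aggregate weights must sum to 1.
#' @return `species` with a `weight` column; weights over taxa present sum
#'   to the summed table weight of those taxa, renormalised to 1 overall.
#' @export
assign_species_weights <- function(species,
                                   taxon_weights = default_taxon_weights()) {
  assert_cols(species, c("species_id", "taxon_group"), "species")
  if (abs(sum(taxon_weights$aggregate_weight) - 1) > 1e-9) {
    stop("taxon aggregate weights must sum to 1", call. = FALSE)
  }
  taxon <- ifelse(species$taxon_group %in% taxon_weights$taxon_group,
                  species$taxon_group, "other")
  agg <- taxon_weights$aggregate_weight[match(taxon, taxon_weights$taxon_group)]
  counts <- table(taxon)
  w <- agg / as.numeric(counts[taxon])
  species$weight <- w / sum(w)
  species
}

#' Protected fraction of each species' range
#'
#' Only fully/highly protected pixels count toward the protected fraction,
#' matching the premise that the modelled benefits are unique to full/high
#' protection.
#'
#' @param species_ranges Long tibble `species_id`, `pixel_id`.
#' @param protected_ids Pixel ids under full/high protection in the
#'   scenario.
#' @return Tibble `species_id`, `protected_fraction`.
#' @export
species_protected_fraction <- function(species_ranges, protected_ids) {
  species_ranges |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      protected_fraction = mean(.data$pixel_id %in% protected_ids),
      .groups = "drop"
    )
}

#' Weighted biodiversity-persistence score for a protection scenario
#'
#' The score is the weighted sum over species of persistence under the
#' scenario's fully/highly protected pixel set: 1 means every species is
#' free from abatable and unabatable threats. An empty species set scores 0.
#'
#' @param species Species table with `species_id`, `taxon_group`,
#'   `abatable_fraction`, optionally `unabatable_fraction` and precomputed
#'   `weight`.
#' @param species_ranges Long range table `species_id`, `pixel_id`.
#' @param protected_ids Fully/highly protected pixel ids.
#' @param z Persistence exponent (default 0.25).
#' @param taxon_weights Taxon table used when `species` lacks a `weight`
#'   column.
#' @return Scalar score in `[0, 1]`.
#' @export
biodiversity_score <- function(species, species_ranges, protected_ids,
                               z = 0.25,
                               taxon_weights = default_taxon_weights()) {
  if (nrow(species) == 0) return(0)
  if (!"weight" %in% names(species)) {
    species <- assign_species_weights(species, taxon_weights)
  }
  pf <- species_protected_fraction(species_ranges, protected_ids)
  p <- pf$protected_fraction[match(species$species_id, pf$species_id)]
  p[is.na(p)] <- 0
  u <- if ("unabatable_fraction" %in% names(species)) {
    species$unabatable_fraction
  } else {
    rep(0, nrow(species))
  }
  pers <- species_persistence(p, species$abatable_fraction, z = z, u = u)
  sum(species$weight * pers)
}
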