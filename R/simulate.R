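#' Configuration for the synthetic trait-table generator
#'
#' The generator emulates the statistical structure of a FishBase-style
#' trait extraction for the staple farmed species: four taxonomic groups
#' (finfish, crustaceans, molluscs, algae) with group-specific trait
#' distributions — low trophic level for algae and molluscs, large
#' fecundities and wide latitudinal ranges for finfish, wide nutrient and
#' salinity tolerances for the extractive (non-fed) groups — and trait
#' missingness concentrated in the non-fish groups.  Sizes default to 54
#' species split across the four groups in roughly the proportions of
#' the top-farmed species lists.
#'
#' Fecundity, maximum size, and geographic range are log-normal (strictly
#' positive, right-skewed); growth rate, trophic level, macronutrient
#' density, and the tolerance-range traits are normal with clamping to
#' their plausible domains; all location parameters are shifted by
#' per-taxon offsets scaled by `effect_size`.
#'
#' @param n_species named integer vector: species per taxon.
#' @param effect_size multiplier on the per-taxon location offsets.  1
#'   (default) gives the group separation the generator treats as
#'   realistic; 0 makes all taxa exchangeable (identical trait
#'   distributions), which is the null configuration for calibration
#'   checks.
#' @param missingness named per-taxon probability that any one trait
#'   value is missing.  Set a single number to share it across taxa.
#' @return a `synthetic_config` list with a `traits` element holding the
#'   per-trait distribution parameters (editable before generation).
#' @export
synthetic_config <- function(n_species = c(finfish = 27, crustaceans = 9,
                                           molluscs = 11, algae = 7),
                             effect_size = 1,
                             missingness = c(finfish = 0.03,
                                             crustaceans = 0.12,
                                             molluscs = 0.12,
                                             algae = 0.20)) {
  taxa <- c("finfish", "crustaceans", "molluscs", "algae")
  if (is.null(names(n_species)) || !setequal(names(n_species), taxa))
    stop("n_species must be named over the four taxa", call. = FALSE)
  if (any(n_species < 0)) stop("n_species must be non-negative", call. = FALSE)
  if (length(missingness) == 1L)
    missingness <- stats::setNames(rep(missingness, 4), taxa)
  if (!setequal(names(missingness), taxa))
    stop("missingness must be named over the four taxa", call. = FALSE)
  if (any(missingness < 0 | missingness > 1))
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(effect_size) || effect_size < 0)
    stop("effect_size must be non-negative", call. = FALSE)

  off <- function(finfish, crustaceans, molluscs, algae)
    c(finfish = finfish, crustaceans = crustaceans, molluscs = molluscs,
      algae = algae)
  # dist: sampling family; base: location; scale: sd (per taxon allowed);
  # offsets: taxon shifts on the location (log scale for lognormal);
  # clamp: plausible domain the draws are clipped to.
  traits <- list(
    trophic_level = list(dist = "normal", base = 2.5,
                         scale = off(0.8, 0.3, 0.3, 0.3),
                         offsets = off(0.7, 0.3, -0.5, -1.5),
                         clamp = c(1, 5.5), units = "unitless (1-5)"),
    vbgf_k = list(dist = "normal", base = 0.45, scale = 0.18,
                  offsets = off(0.15, 0.10, -0.10, -0.15),
                  clamp = c(0.02, 3), units = "1/yr"),
    max_size = list(dist = "lognormal", base = log(40), scale = 0.8,
                    offsets = off(0.4, -0.6, -0.9, 0.6),
                    clamp = c(0.5, 5000), units = "cm"),
    fecundity = list(dist = "lognormal", base = log(1e5), scale = 1.5,
                     offsets = off(1.5, 1.0, 0.5, -2.0),
                     clamp = c(1, 1e9), units = "eggs"),
    macronutrient_density = list(dist = "normal", base = 0.30, scale = 0.10,
                                 offsets = off(0.05, 0.00, 0.10, 0.15),
                                 clamp = c(0.01, 1),
                                 units = "fraction of recommended intake"),
    nitrate_range = list(dist = "normal", base = 20, scale = 6,
                         offsets = off(0, -2, 7, 10),
                         clamp = c(0.5, 80), units = "umol/L"),
    phosphate_range = list(dist = "normal", base = 2, scale = 0.6,
                           offsets = off(0, -0.2, 0.7, 1.0),
                           clamp = c(0.05, 10), units = "umol/L"),
    salinity_range = list(dist = "normal", base = 15, scale = 5,
                          offsets = off(0, 2, 5, 5),
                          clamp = c(0.5, 40), units = "psu"),
    po2_range = list(dist = "normal", base = 5, scale = 1.5,
                     offsets = off(0, 0, 1.5, 1.0),
                     clamp = c(0.2, 15), units = "mg/L"),
    ph_range = list(dist = "normal", base = 1.5, scale = 0.5,
                    offsets = off(0, 0, 0.4, 0.5),
                    clamp = c(0.05, 6), units = "pH units"),
    latitudinal_range = list(dist = "normal", base = 30, scale = 10,
                             offsets = off(8, 5, 0, -8),
                             clamp = c(1, 90), units = "degrees"),
    geographic_range = list(dist = "lognormal", base = log(5), scale = 0.8,
                            offsets = off(0.5, 0.3, 0, -0.6),
                            clamp = c(0.01, 500),
                            units = "million km^2")
  )
  structure(list(n_species = n_species, effect_size = effect_size,
                 missingness = missingness, traits = traits),
            class = "synthetic_config")
}

#' Generate a synthetic species-by-trait table
#'
#' Draws one species record per row according to the configured per-taxon
#' trait distributions, then masks each trait cell independently with the
#' taxon's missingness probability.  Fully reproducible under `seed`.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed fixing the whole table.
#' @return data frame with `species_id`, `taxon`, and one numeric column
#'   per configured trait (`NA` = missing).
#' @export
generate_table <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(as.integer(seed))
  taxa <- rep(names(config$n_species), times = config$n_species)
  n <- length(taxa)
  if (n == 0) stop("config generates zero species", call. = FALSE)
  out <- data.frame(
    species_id = sprintf("sp_%03d", seq_len(n)),
    taxon = taxa, stringsAsFactors = FALSE)
  for (id in names(config$traits)) {
    tr <- config$traits[[id]]
    loc <- tr$base + config$effect_size * tr$offsets[taxa]
    scale <- if (length(tr$scale) > 1) tr$scale[taxa] else tr$scale
    v <- if (tr$dist == "lognormal") stats::rlnorm(n, loc, scale)
         else stats::rnorm(n, loc, scale)
    v <- pmin(pmax(v, tr$clamp[1]), tr$clamp[2])
    miss <- stats::runif(n) < config$missingness[taxa]
    v[miss] <- NA_real_
    out[[id]] <- unname(v)
  }
  out
}

#' The shipped default rulebook
#'
#' A complete, schema-valid rulebook covering all synthetic traits and
#' all three indices, reconstructed from the directional trait-goal
#' relationships the assessment framework rests on: fast growth
#' (VBGF K), large size, high fecundity, and high macronutrient density
#' favour food-security potential; wide nitrate, phosphate, salinity,
#' oxygen, and pH tolerance favours both food-security (high-density
#' rearing) and climate (resilience) potential; high trophic level
#' penalizes climate potential (feed-efficiency proxy) and biodiversity
#' potential; high fecundity and fast growth penalize biodiversity
#' potential (escape/invasion risk), as do wide latitudinal and
#' geographic ranges.  Positive linkages map each trait category to the
#' same potential category; inverted linkages reverse the order (a
#' very-high trait value concludes low potential), so a species with
#' extreme fecundity lands in the very-high food set and the low
#' biodiversity set simultaneously.
#'
#' All rules use the default weight 0.5, firing threshold 0.2, and
#' defuzzification indices 1/25/75/100; membership functions come from
#' the quantile recipe (fuzziness 0.5) fitted to the scored table.
#'
#' @return a validated [rulebook()].
#' @export
default_rulebook <- function() {
  link <- list(
    # trait -> list of c(index, direction)
    vbgf_k = list(c("F", "+"), c("B", "-")),
    max_size = list(c("F", "+")),
    fecundity = list(c("F", "+"), c("B", "-")),
    macronutrient_density = list(c("F", "+")),
    trophic_level = list(c("C", "-"), c("B", "-")),
    nitrate_range = list(c("F", "+"), c("C", "+")),
    phosphate_range = list(c("F", "+"), c("C", "+")),
    salinity_range = list(c("F", "+"), c("C", "+")),
    po2_range = list(c("F", "+"), c("C", "+")),
    ph_range = list(c("F", "+"), c("C", "+")),
    latitudinal_range = list(c("B", "-")),
    geographic_range = list(c("B", "-"))
  )
  units <- vapply(synthetic_config()$traits, `[[`, character(1), "units")
  traits <- lapply(names(link), function(id)
    trait_definition(id, units = units[[id]],
                     linked_indices = vapply(link[[id]], `[`, character(1), 1),
                     fuzziness = 0.5))
  rev_cat <- stats::setNames(rev(FCB_CATEGORIES), FCB_CATEGORIES)
  rules <- do.call(rbind, lapply(names(link), function(id)
    do.call(rbind, lapply(link[[id]], function(li)
      data.frame(trait_id = id, premise = FCB_CATEGORIES, index = li[1],
                 conclusion = if (li[2] == "+") FCB_CATEGORIES
                              else unname(rev_cat[FCB_CATEGORIES]),
                 weight = 0.5, stringsAsFactors = FALSE)))))
  rulebook(traits, rules)
}
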