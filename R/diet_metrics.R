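#' Maintenance-metabolism parameters
#'
#' Parameters of the exponential maintenance-metabolism model
#' `Jm = jm0 * exp(d * t) * W`: `jm0` is the mass-specific maintenance cost at
#' 0 deg C and `d` the temperature coefficient for biomass assimilation. The
#' defaults are the values used throughout the analysis (0.003 and 0.68). Jm
#' is carried in abstract "model units": only ratios and orderings of Jm are
#' interpreted downstream.
#'
#' @param jm0 Mass-specific maintenance cost at 0 deg C; > 0.
#' @param d Temperature coefficient (per deg C).
#' @return List with elements `jm0`, `d`, class `metabolism_params`.
#' @export
metabolism_params <- function(jm0 = 0.003, d = 0.68) {
  stopifnot(is.numeric(jm0), length(jm0) == 1, jm0 > 0,
            is.numeric(d), length(d) == 1, is.finite(d))
  structure(list(jm0 = jm0, d = d), class = "metabolism_params")
}

#' Maintenance metabolism of a fish
#'
#' `Jm = jm0 * exp(d * t) * W`, exponential in water temperature `t` (deg C)
#' and linear in fish mass `W` (g). Vectorised over mass and temperature.
#'
#' @param mass_g Fish mass in g; > 0.
#' @param temp_C Water temperature in deg C.
#' @param params A [metabolism_params()].
#' @return Numeric vector of Jm values (model units).
#' @export
maintenance_metabolism <- function(mass_g, temp_C,
                                   params = metabolism_params()) {
  stopifnot(inherits(params, "metabolism_params"))
  if (any(!is.finite(mass_g)) || any(mass_g <= 0)) {
    stop("mass_g must be positive and finite")
  }
  params$jm0 * exp(params$d * temp_C) * mass_g
}

#' Instantaneous ration
#'
#' Ratio of total stomach-content wet mass to fish body mass; a dimensionless
#' stomach-fullness proxy. Zero for a fish with no prey rows (only reachable
#' before exclusions).
#'
#' @param prey_weights_g Numeric vector of prey wet weights (g) for one fish.
#' @param mass_g Fish mass (g); > 0.
#' @return Scalar IR.
#' @export
instantaneous_ration <- function(prey_weights_g, mass_g) {
  if (!is.finite(mass_g) || mass_g <= 0) stop("mass_g must be positive")
  sum(prey_weights_g) / mass_g
}

#' Energy ration
#'
#' Stomach-content energy per gram of fish: each prey mass is multiplied by
#' its taxon's energy density (kJ/g wet mass), summed, and divided by fish
#' mass. Units kJ per g fish.
#'
#' @param prey_weights_g Prey wet weights (g) for one fish.
#' @param taxa Taxon label per prey row.
#' @param energy An [energy_table()].
#' @param mass_g Fish mass (g); > 0.
#' @param warn Warn when a default density is substituted.
#' @return Scalar ER (kJ per g fish).
#' @export
energy_ration <- function(prey_weights_g, taxa, energy, mass_g, warn = TRUE) {
  if (!is.finite(mass_g) || mass_g <= 0) stop("mass_g must be positive")
  stopifnot(length(prey_weights_g) == length(taxa))
  if (!length(prey_weights_g)) return(0)
  sum(prey_weights_g * energy_density(energy, taxa, warn = warn)) / mass_g
}

#' Diet composition and prey-importance indices
#'
#' For each group of fish (any combination of fish attributes such as `site`,
#' `year`, `length_bin`), computes per taxon: percent numeric composition
#' (%N, share of total prey counts), percent gravimetric composition (%G,
#' share of total prey weight), frequency of occurrence (F, proportion of
#' stomachs in the group containing the taxon, in `[0, 1]`), the Index of
#' Relative Importance `IRI = F * (%N + %G)` in `[0, 200]`, and %IRI (IRI
#' normalised to sum 100 within the group).
#'
#' Prey life stages are summed within taxon unless `stage_resolved = TRUE`,
#' in which case (taxon, life stage) pairs are treated as distinct columns.
#'
#' @param ds A post-exclusion `diet_dataset`.
#' @param by Character vector of fish columns to group by (default `"site"`).
#'   `"length_bin"` may be included and is derived from fork length via
#'   [assign_length_bin()] with `scheme`.
#' @param scheme Length-bin scheme passed to [assign_length_bin()] when
#'   `by` includes `"length_bin"`.
#' @param stage_resolved Keep prey life stages separate.
#' @return Tibble with the grouping columns plus `taxon`, `n_stomachs`,
#'   `numeric_pct`, `gravimetric_pct`, `freq_occurrence`, `iri`, `iri_pct`.
#' @export
composition <- function(ds, by = "site", scheme = c("model", "ordination"),
                        stage_resolved = FALSE) {
  stopifnot(inherits(ds, "diet_dataset"))
  scheme <- match.arg(scheme)
  pooled <- length(by) == 0
  fish <- add_length_bin(ds$fish, by, scheme)
  if (pooled) {
    by <- ".all"
    fish$.all <- "all"
  }
  bad <- setdiff(by, names(fish))
  if (length(bad)) stop("unknown fish attribute(s): ", paste(bad, collapse = ", "))
  prey <- ds$prey
  if (!stage_resolved) {
    prey <- prey %>%
      group_by(.data$fish_id, .data$taxon) %>%
      summarise(count = sum(.data$count), weight_g = sum(.data$weight_g),
                .groups = "drop")
  } else {
    prey <- prey %>%
      mutate(taxon = paste(.data$taxon, .data$life_stage, sep = " | "))
  }
  joined <- prey %>%
    left_join(fish[, c("fish_id", by)], by = "fish_id")
  group_sizes <- fish %>% count(across(all_of(by)), name = "n_stomachs")
  empty_groups <- group_sizes %>%
    anti_join(joined %>% distinct(across(all_of(by))), by = by)
  if (nrow(empty_groups)) {
    stop("group(s) contain fish but no prey rows; apply exclusions first")
  }
  per_taxon <- joined %>%
    group_by(across(all_of(c(by, "taxon")))) %>%
    summarise(total_count = sum(.data$count),
              total_weight = sum(.data$weight_g),
              n_occ = dplyr::n_distinct(.data$fish_id),
              .groups = "drop")
  per_taxon %>%
    left_join(group_sizes, by = by) %>%
    group_by(across(all_of(by))) %>%
    mutate(numeric_pct = 100 * .data$total_count / sum(.data$total_count),
           gravimetric_pct = 100 * .data$total_weight / sum(.data$total_weight),
           freq_occurrence = .data$n_occ / .data$n_stomachs,
           iri = .data$freq_occurrence *
             (.data$numeric_pct + .data$gravimetric_pct),
           iri_pct = 100 * .data$iri / sum(.data$iri)) %>%
    ungroup() %>%
    arrange(across(all_of(by)), dplyr::desc(.data$iri_pct)) %>%
    select(all_of(if (pooled) character(0) else by), "taxon", "n_stomachs",
           "numeric_pct", "gravimetric_pct", "freq_occurrence", "iri",
           "iri_pct")
}

add_length_bin <- function(fish, by, scheme) {
  if ("length_bin" %in% by && !"length_bin" %in% names(fish)) {
    fish$length_bin <- as.character(
      assign_length_bin(fish$fork_length_mm, scheme))
  }
  fish
}

#' Per-fish foraging-score table
#'
#' Computes the three per-fish scores — instantaneous ration (IR), energy
#' ration (ER, kJ per g fish) and maintenance metabolism (Jm, model units) —
#' and joins the model covariates (site, month, year, length bin, mark status,
#' water temperature).
#'
#' @param ds A post-exclusion `diet_dataset`.
#' @param params A [metabolism_params()].
#' @param scheme Length-bin scheme for the `length_bin` covariate.
#' @return Tibble, one row per fish: `fish_id, site, year, month, length_bin,
#'   mark_status, water_temp_C, mass_g, ir, er, jm`.
#' @export
ration_table <- function(ds, params = metabolism_params(),
                         scheme = c("model", "ordination")) {
  stopifnot(inherits(ds, "diet_dataset"))
  scheme <- match.arg(scheme)
  fish <- ds$fish
  totals <- ds$prey %>%
    mutate(energy_kJ = .data$weight_g *
             energy_density(ds$energy, .data$taxon, warn = FALSE)) %>%
    group_by(.data$fish_id) %>%
    summarise(prey_weight_g = sum(.data$weight_g),
              prey_energy_kJ = sum(.data$energy_kJ), .groups = "drop")
  fish %>%
    left_join(totals, by = "fish_id") %>%
    mutate(prey_weight_g = dplyr::coalesce(.data$prey_weight_g, 0),
           prey_energy_kJ = dplyr::coalesce(.data$prey_energy_kJ, 0),
           length_bin = as.character(
             assign_length_bin(.data$fork_length_mm, scheme)),
           ir = .data$prey_weight_g / .data$mass_g,
           er = .data$prey_energy_kJ / .data$mass_g,
           jm = maintenance_metabolism(.data$mass_g, .data$water_temp_C,
                                       params)) %>%
    select("fish_id", "site", "year", "month", "length_bin", "mark_status",
           "water_temp_C", "mass_g", "ir", "er", "jm")
}

#' Stomach-fullness histograms
#'
#' Tallies the ordinal fullness categories (2 = emptier ... 6 = full) per
#' group; fish whose fullness was not categorised are tallied separately
#' under `missing` and excluded from the category counts.
#'
#' @param fish Tibble of fish records.
#' @param by Grouping column(s), default `"site"`.
#' @return Tibble with grouping columns, `category` (factor `2:6` plus
#'   `"missing"`) and `n`.
#' @export
fullness_histogram <- function(fish, by = "site") {
  fish <- as_tibble(fish)
  levels <- c(as.character(2:6), "missing")
  fish %>%
    mutate(category = factor(
      ifelse(is.na(.data$fullness_category), "missing",
             as.character(.data$fullness_category)),
      levels = levels)) %>%
    group_by(across(all_of(by)), .data$category, .drop = FALSE) %>%
    summarise(n = dplyr::n(), .groups = "drop")
}
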