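#' @importFrom dplyr %>% across all_of anti_join arrange bind_rows count distinct
#'   filter group_by left_join mutate n pull rename row_number select summarise
#'   ungroup
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

#' Monitoring sites of the estuarine sampling design
#'
#' The five fixed tidal-wetland monitoring sites, ordered from the river mouth
#' (Ilwaco Slough) upstream to Franz Lake.
#'
#' @return Character vector of the five site names.
#' @export
study_sites <- function() {
  c("Ilwaco Slough", "Welch Island", "Whites Island",
    "Campbell Slough", "Franz Lake")
}

fish_cols <- c("fish_id", "site", "year", "month", "fork_length_mm",
               "mass_g", "mark_status", "water_temp_C", "fullness_category")
prey_cols <- c("fish_id", "taxon", "life_stage", "count", "weight_g")
energy_cols <- c("taxon", "energy_density_kJ_per_g")

#' Construct an energy-density lookup table
#'
#' Maps prey taxa to wet-mass energy densities (kJ per g wet mass). Taxa not
#' listed fall back to `default_density` with a warning at lookup time, since
#' published per-taxon density tables are rarely complete for field diets.
#'
#' @param densities Named numeric vector, taxon -> kJ/g wet mass; all > 0.
#' @param default_density Positive fallback density for unlisted taxa.
#' @return An object of class `energy_table`.
#' @export
energy_table <- function(densities, default_density = 3.5) {
  densities <- unlist(densities)
  stopifnot(is.numeric(densities), !is.null(names(densities)),
            all(densities > 0), is.numeric(default_density),
            length(default_density) == 1, default_density > 0)
  structure(list(densities = densities, default_density = default_density),
            class = "energy_table")
}

#' @export
print.energy_table <- function(x, ...) {
  cat("<energy_table> ", length(x$densities), " taxa, default ",
      x$default_density, " kJ/g\n", sep = "")
  invisible(x)
}

#' Look up energy densities for taxa
#'
#' @param energy An [energy_table()].
#' @param taxa Character vector of taxon labels.
#' @param warn Warn when the default density is substituted.
#' @return Numeric vector of densities (kJ/g), same length as `taxa`.
#' @export
energy_density <- function(energy, taxa, warn = TRUE) {
  stopifnot(inherits(energy, "energy_table"))
  out <- unname(energy$densities[taxa])
  miss <- is.na(out)
  if (any(miss)) {
    if (warn) {
      warning("no energy density for taxa: ",
              paste(sort(unique(taxa[miss])), collapse = ", "),
              "; using default ", energy$default_density, " kJ/g")
    }
    out[miss] <- energy$default_density
  }
  out
}

#' Bundle fish, prey and energy tables into a validated dataset
#'
#' @param fish Tibble of fish records (one row per sampled fish) with columns
#'   `fish_id, site, year, month, fork_length_mm, mass_g, mark_status,
#'   water_temp_C, fullness_category`.
#' @param prey Tibble of prey items (one row per fish x taxon x life stage)
#'   with columns `fish_id, taxon, life_stage, count, weight_g`.
#' @param energy An [energy_table()].
#' @return An object of class `diet_dataset`: list with elements `fish`,
#'   `prey`, `energy`.
#' @export
diet_dataset <- function(fish, prey, energy) {
  ds <- structure(list(fish = as_tibble(fish), prey = as_tibble(prey),
                       energy = energy),
                  class = "diet_dataset")
  validate_dataset(ds)
  ds
}

#' @export
print.diet_dataset <- function(x, ...) {
  cat("<diet_dataset> ", nrow(x$fish), " fish, ", nrow(x$prey),
      " prey rows, ", length(unique(x$prey$taxon)), " taxa\n", sep = "")
  invisible(x)
}

#' Validate a diet dataset
#'
#' Checks schemas, referential integrity (every prey row resolves to a fish),
#' uniqueness of `fish_id` and of `(fish_id, taxon, life_stage)`, positivity of
#' lengths/masses/counts, month range 2-7 and the ordinal fullness scale 2-6
#' (missing allowed).
#'
#' @param ds A `diet_dataset`.
#' @return `ds`, invisibly; errors describe the first violated constraint.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "diet_dataset"))
  check_schema(ds$fish, fish_cols, "fish")
  check_schema(ds$prey, prey_cols, "prey")
  stopifnot(inherits(ds$energy, "energy_table"))
  fish <- ds$fish
  prey <- ds$prey
  if (anyDuplicated(fish$fish_id)) {
    stop("duplicate fish_id: ",
         paste(unique(fish$fish_id[duplicated(fish$fish_id)]), collapse = ", "))
  }
  if (nrow(fish)) {
    if (any(fish$fork_length_mm <= 0)) stop("fork_length_mm must be > 0")
    if (any(fish$mass_g <= 0)) stop("mass_g must be > 0")
    if (!all(fish$month %in% 2:7)) stop("month must be in 2..7 (Feb-Jul)")
    if (!all(fish$mark_status %in% c("marked", "unmarked"))) {
      stop("mark_status must be 'marked' or 'unmarked'")
    }
    fc <- fish$fullness_category
    if (!all(is.na(fc) | fc %in% 2:6)) {
      stop("fullness_category must be 2..6 or missing")
    }
  }
  if (nrow(prey)) {
    orphans <- setdiff(prey$fish_id, fish$fish_id)
    if (length(orphans)) {
      stop("prey rows reference unknown fish_id: ",
           paste(utils::head(sort(orphans), 10), collapse = ", "))
    }
    if (any(prey$count < 1)) stop("prey count must be >= 1")
    if (any(prey$weight_g < 0)) stop("prey weight_g must be >= 0")
    key <- paste(prey$fish_id, prey$taxon, prey$life_stage, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate (fish_id, taxon, life_stage) prey rows")
    }
  }
  invisible(ds)
}

check_schema <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Read a diet dataset from delimited text files
#'
#' Reads the three flat tables of the data model: fish records, prey items and
#' the taxon energy-density table, all comma-delimited UTF-8 with a header row
#' and empty fields for missing values. Taxa present in the prey table but
#' absent from the energy table are retained and reported via a message.
#'
#' @param fish_path,prey_path,energy_path Paths to `fish.csv`, `prey.csv`,
#'   `energy.csv`.
#' @param default_density Fallback energy density (kJ/g) for unlisted taxa.
#' @return A validated `diet_dataset`.
#' @export
read_dataset <- function(fish_path, prey_path, energy_path,
                         default_density = 3.5) {
  for (chk in list(list(fish_path, fish_cols, "fish"),
                   list(prey_path, prey_cols, "prey"),
                   list(energy_path, energy_cols, "energy"))) {
    hdr <- names(readr::read_csv(chk[[1]], n_max = 0,
                                 show_col_types = FALSE))
    check_schema(stats::setNames(data.frame(matrix(ncol = length(hdr),
                                                   nrow = 0)), hdr),
                 chk[[2]], chk[[3]])
  }
  fish <- readr::read_csv(fish_path, col_types = readr::cols(
    fish_id = "c", site = "c", year = "i", month = "i",
    fork_length_mm = "d", mass_g = "d", mark_status = "c",
    water_temp_C = "d", fullness_category = "i"), progress = FALSE)
  prey <- readr::read_csv(prey_path, col_types = readr::cols(
    fish_id = "c", taxon = "c", life_stage = "c",
    count = "i", weight_g = "d"), progress = FALSE)
  en <- readr::read_csv(energy_path, col_types = readr::cols(
    taxon = "c", energy_density_kJ_per_g = "d"), progress = FALSE)
  check_schema(fish, fish_cols, "fish")
  check_schema(prey, prey_cols, "prey")
  check_schema(en, energy_cols, "energy")
  energy <- energy_table(setNames(en$energy_density_kJ_per_g, en$taxon),
                         default_density = default_density)
  unlisted <- setdiff(unique(prey$taxon), names(energy$densities))
  if (length(unlisted)) {
    message("prey taxa without an energy density (default will be used): ",
            paste(sort(unlisted), collapse = ", "))
  }
  diet_dataset(fish, prey, energy)
}

#' Write a diet dataset to delimited text files
#'
#' Inverse of [read_dataset()]: writes `fish.csv`, `prey.csv` and `energy.csv`
#' into `dir`. Round-trips through [read_dataset()] on canonicalised tables.
#'
#' @param ds A `diet_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "diet_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("fish.csv", "prey.csv", "energy.csv"))
  readr::write_csv(ds$fish, paths[1], progress = FALSE)
  readr::write_csv(ds$prey, paths[2], progress = FALSE)
  readr::write_csv(tibble(taxon = names(ds$energy$densities),
                          energy_density_kJ_per_g = unname(ds$energy$densities)),
                   paths[3], progress = FALSE)
  invisible(paths)
}

#' Apply the standard analysis exclusions
#'
#' Removes (1) fish with empty stomachs (no prey rows) and (2) fish at or above
#' the fork-length cutoff. The cutoff defaults to 100 mm, read as
#' `fork_length_mm >= 100`: the largest retained length bin is labelled
#' 66-99 mm, so 99 mm is the last included integer length. Idempotent.
#'
#' @param ds A `diet_dataset`.
#' @param max_fork_length_mm Exclusive upper bound on retained fork length.
#' @return List with `dataset` (the filtered `diet_dataset`) and `report`, a
#'   tibble of per-rule removal counts (`empty_stomach`, `oversize`,
#'   `retained`).
#' @export
apply_exclusions <- function(ds, max_fork_length_mm = 100) {
  stopifnot(inherits(ds, "diet_dataset"))
  fish <- ds$fish
  has_prey <- fish$fish_id %in% ds$prey$fish_id
  oversize <- fish$fork_length_mm >= max_fork_length_mm
  keep <- has_prey & !oversize
  report <- tibble(
    rule = c("empty_stomach", "oversize", "retained"),
    n = c(sum(!has_prey), sum(oversize & has_prey), sum(keep)))
  out <- ds
  out$fish <- fish[keep, , drop = FALSE]
  out$prey <- ds$prey[ds$prey$fish_id %in% out$fish$fish_id, , drop = FALSE]
  if (!nrow(out$fish)) warning("all fish excluded; dataset is empty")
  list(dataset = out, report = report)
}

#' Assign fork lengths to length bins
#'
#' Two binning schemes are used in the analysis: the regression models use two
#' bins (30-65 mm, 66-99 mm) while the ordination uses three (30-59, 60-79,
#' 80-99 mm). Bins are inclusive of both printed endpoints; adjacent bins
#' partition `[30, 100)` with the cut between the upper printed endpoint and
#' the next bin's lower endpoint.
#'
#' @param fork_length_mm Numeric vector of fork lengths in `[30, 100)`.
#' @param scheme `"model"` (two bins) or `"ordination"` (three bins).
#' @return Factor of bin labels.
#' @export
assign_length_bin <- function(fork_length_mm,
                              scheme = c("model", "ordination")) {
  scheme <- match.arg(scheme)
  if (any(is.na(fork_length_mm)) ||
      any(fork_length_mm < 30 | fork_length_mm >= 100)) {
    stop("fork_length_mm outside [30, 100); apply exclusions first")
  }
  if (scheme == "model") {
    breaks <- c(30, 66, 100)
    labels <- c("30-65", "66-99")
  } else {
    breaks <- c(30, 60, 80, 100)
    labels <- c("30-59", "60-79", "80-99")
  }
  cut(fork_length_mm, breaks = breaks, labels = labels, right = FALSE)
}

#' Canonicalise taxon labels
#'
#' Case-insensitive canonicalisation with an optional alias map, so e.g.
#' "amphipoda" and "Amphipoda" collapse while genuinely distinct labels
#' ("unidentified dipterans" vs "Chironomidae") stay apart. An explicit
#' taxon-to-group mapping (see `inst/extdata/taxon_groups.csv`) supports
#' aggregation to coarser groups.
#'
#' @param taxa Character vector of raw labels.
#' @param aliases Optional two-column data frame `alias, canonical`.
#' @return Character vector of canonical labels.
#' @export
canonicalize_taxa <- function(taxa, aliases = NULL) {
  out <- trimws(taxa)
  if (!is.null(aliases)) {
    stopifnot(all(c("alias", "canonical") %in% names(aliases)))
    idx <- match(tolower(out), tolower(aliases$alias))
    hit <- !is.na(idx)
    out[hit] <- aliases$canonical[idx[hit]]
  }
  # collapse pure case variants of the same label onto the first-seen form
  canon <- tapply(out, tolower(out), function(x) x[1])
  as.character(canon[tolower(out)])
}

#' Aggregate prey taxa to coarser groups
#'
#' @param ds A `diet_dataset`.
#' @param groups Data frame with columns `taxon, group`; unlisted taxa keep
#'   their own label.
#' @return A `diet_dataset` whose prey taxa are the group labels (counts and
#'   weights summed within fish x group x life stage); the energy table is
#'   left unchanged.
#' @export
aggregate_taxa <- function(ds, groups) {
  stopifnot(inherits(ds, "diet_dataset"),
            all(c("taxon", "group") %in% names(groups)))
  prey <- ds$prey
  idx <- match(prey$taxon, groups$taxon)
  prey$taxon <- ifelse(is.na(idx), prey$taxon, groups$group[idx])
  prey <- prey %>%
    group_by(.data$fish_id, .data$taxon, .data$life_stage) %>%
    summarise(count = sum(.data$count), weight_g = sum(.data$weight_g),
              .groups = "drop")
  out <- ds
  out$prey <- prey
  validate_dataset(out)
  out
}
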