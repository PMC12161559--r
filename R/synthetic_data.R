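#' Per-site, per-month sampling design
#'
#' The per-cell fish counts of the five-site, February-July sampling design
#' (cells that were never sampled are absent). Cell values are internally
#' consistent with the per-site totals 40, 444, 455, 343 and 83 (grand total
#' 1365).
#'
#' @return Tibble: `site, month, n`.
#' @export
table1_design <- function() {
  sites <- study_sites()
  counts <- list(
    `Ilwaco Slough`   = c(`2` = 29, `3` = 5,  `4` = 6),
    `Welch Island`    = c(`2` = 25, `3` = 62, `4` = 79, `5` = 154, `6` = 98,
                          `7` = 26),
    `Whites Island`   = c(`2` = 5,  `3` = 44, `4` = 85, `5` = 186, `6` = 108,
                          `7` = 27),
    `Campbell Slough` = c(`2` = 4,  `3` = 8,  `4` = 27, `5` = 216, `6` = 75,
                          `7` = 13),
    `Franz Lake`      = c(`2` = 5,  `4` = 36, `5` = 42))
  bind_rows(lapply(sites, function(s) {
    tibble(site = s, month = as.integer(names(counts[[s]])),
           n = as.integer(unname(counts[[s]])))
  }))
}

#' Per-site length-bin and mark-status margins of the sampling design
#'
#' @return Tibble: `site, small, large, unmarked, marked` — counts of fish in
#'   the 30-65 mm and 66-99 mm model bins and by mark status.
#' @export
table1_margins <- function() {
  tibble(
    site = study_sites(),
    small = c(40L, 308L, 285L, 91L, 59L),
    large = c(0L, 136L, 170L, 252L, 24L),
    unmarked = c(40L, 383L, 400L, 180L, 62L),
    marked = c(0L, 61L, 55L, 163L, 21L))
}

default_taxa <- function() {
  c("Amphipoda:Americorophium", "Amphipoda:other", "Diptera:Chironomidae",
    "Diptera:other", "Cladocera:Daphnia", "Hemiptera:Corixidae",
    "Trichoptera", "Hymenoptera", "other")
}

default_profiles <- function() {
  taxa <- default_taxa()
  p <- rbind(
    `Ilwaco Slough`   = c(0.40, 0.06, 0.25, 0.12, 0.02, 0.04, 0.03, 0.03, 0.05),
    `Welch Island`    = c(0.45, 0.07, 0.18, 0.08, 0.10, 0.04, 0.02, 0.02, 0.04),
    `Whites Island`   = c(0.45, 0.07, 0.18, 0.08, 0.10, 0.04, 0.02, 0.02, 0.04),
    `Campbell Slough` = c(0.08, 0.02, 0.15, 0.08, 0.55, 0.04, 0.02, 0.02, 0.04),
    `Franz Lake`      = c(0.04, 0.02, 0.45, 0.20, 0.02, 0.08, 0.07, 0.07, 0.05))
  colnames(p) <- taxa
  150 * p  # Dirichlet concentrations; total 150 gives mild overdispersion
}

default_energy_densities <- function() {
  stats::setNames(
    c(4.0, 4.0, 3.0, 3.0, 2.0, 5.0, 5.0, 5.0, 3.0),
    default_taxa())
}

default_weight_model <- function() {
  tibble(
    taxon = default_taxa(),
    median_mg = c(5, 4, 1.5, 1.2, 0.15, 4, 5, 3, 2),
    sdlog = 0.6)
}

default_temperature_model <- function() {
  tibble(
    site = study_sites(),
    feb_C = c(4.4, 6.0, 6.5, 8.0, 10.9),
    jul_C = c(18.9, 21.0, 21.5, 23.3, 22.0))
}

#' Synthetic-dataset generator configuration
#'
#' Defaults emulate the five-site February-July estuarine design: per-cell
#' fish counts from [table1_design()], exact per-site length-bin and
#' mark-status margins from [table1_margins()], amphipod-dominated diets at
#' the three downstream sites, cladoceran-dominated diets at Campbell Slough
#' and dipteran-dominated diets at Franz Lake, and seasonal temperatures
#' rising linearly from the February range (4.4-10.9 deg C across sites) to
#' the July range (18.9-23.3 deg C).
#'
#' @param design Tibble `site, month, n` of target (non-empty) fish counts.
#' @param years Integer vector; each cell's count is spread across years as
#'   evenly as possible, remainder to the earliest years.
#' @param profiles Site-by-taxon matrix of Dirichlet concentrations; each
#'   stomach's taxon split is multinomial with probabilities drawn from the
#'   site's Dirichlet (Dirichlet-multinomial overdispersion).
#' @param weight_model Tibble `taxon, median_mg, sdlog`: per-item wet weight
#'   is lognormal with the given median (mg) and log-sd.
#' @param mean_count,count_dispersion Per-stomach total prey count is
#'   `1 + NegBin(mu = mean_count - 1, size = count_dispersion)` (so >= 1).
#' @param empty_stomach_rate Expected share of all generated fish that have
#'   empty stomachs (inserted on top of the design counts; default 18/1383).
#' @param fullness_missing_rate Share of fish whose fullness category is left
#'   uncategorised.
#' @param temperature_model Tibble `site, feb_C, jul_C` of seasonal endpoints.
#' @param temp_noise_sd SD (deg C) of the noise around the monthly mean.
#' @param margins Tibble from [table1_margins()]: exact per-site length-bin
#'   and mark-status counts, shuffled over each site's design fish.
#' @param mass_a,mass_b,mass_sdlog Length-mass model `W = a * L^b` (g, mm)
#'   with lognormal noise; defaults a = 1e-5, b = 3.
#' @param energy_densities Named vector taxon -> kJ/g wet mass.
#' @param default_density Fallback density for unlisted taxa.
#' @param chironomid_stage_split Probabilities of (larva, pupa,
#'   adult/emergent) for chironomid counts; other taxa get stage "unknown".
#' @param seed Integer root seed; the whole dataset is reproducible from it.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(design = table1_design(),
                             years = 2008:2021,
                             profiles = default_profiles(),
                             weight_model = default_weight_model(),
                             mean_count = 20,
                             count_dispersion = 2,
                             empty_stomach_rate = 18 / 1383,
                             fullness_missing_rate = 0.15,
                             temperature_model = default_temperature_model(),
                             temp_noise_sd = 1.0,
                             margins = table1_margins(),
                             mass_a = 1e-5, mass_b = 3.0, mass_sdlog = 0.08,
                             energy_densities = default_energy_densities(),
                             default_density = 3.5,
                             chironomid_stage_split = c(larva = 0.30,
                                                        pupa = 0.26,
                                                        `adult/emergent` = 0.44),
                             seed = 1L) {
  stopifnot(all(c("site", "month", "n") %in% names(design)),
            all(design$n >= 0), all(design$month %in% 2:7),
            all(profiles > 0), mean_count > 1, count_dispersion > 0,
            empty_stomach_rate >= 0, empty_stomach_rate < 1,
            fullness_missing_rate >= 0, fullness_missing_rate <= 1,
            temp_noise_sd >= 0, mass_a > 0, mass_b > 0,
            abs(sum(chironomid_stage_split) - 1) < 1e-9)
  unknown <- setdiff(design$site, rownames(profiles))
  if (length(unknown)) {
    stop("design references site(s) without a prey profile: ",
         paste(unknown, collapse = ", "))
  }
  unknown <- setdiff(design$site, temperature_model$site)
  if (length(unknown)) {
    stop("design references site(s) without temperature endpoints: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(
    design = as_tibble(design), years = as.integer(years),
    profiles = profiles, weight_model = as_tibble(weight_model),
    mean_count = mean_count, count_dispersion = count_dispersion,
    empty_stomach_rate = empty_stomach_rate,
    fullness_missing_rate = fullness_missing_rate,
    temperature_model = as_tibble(temperature_model),
    temp_noise_sd = temp_noise_sd, margins = as_tibble(margins),
    mass_a = mass_a, mass_b = mass_b, mass_sdlog = mass_sdlog,
    energy_densities = energy_densities, default_density = default_density,
    chironomid_stage_split = chironomid_stage_split,
    seed = as.integer(seed)), class = "generator_config")
}

# spread n across years as evenly as possible, remainder to earliest years
spread_years <- function(n, years) {
  ny <- length(years)
  base <- n %/% ny
  extra <- n %% ny
  rep(years, times = base + c(rep(1L, extra), rep(0L, ny - extra)))
}

#' Seasonal water temperatures
#'
#' Monthly mean temperature for a site is linear interpolation between its
#' configured February and July endpoints, plus seeded Gaussian noise.
#'
#' @param site,month Vectors (recycled to common length); months in 2..7.
#' @param cfg A [generator_config()].
#' @param seed Optional integer seed for the noise.
#' @return Numeric vector of temperatures (deg C).
#' @export
generate_temperatures <- function(site, month, cfg = generator_config(),
                                  seed = NULL) {
  if (any(!month %in% 2:7)) stop("month must be in 2..7")
  n <- max(length(site), length(month))
  site <- rep_len(site, n)
  month <- rep_len(month, n)
  tm <- cfg$temperature_model
  idx <- match(site, tm$site)
  if (any(is.na(idx))) {
    stop("no temperature endpoints for site(s): ",
         paste(unique(site[is.na(idx)]), collapse = ", "))
  }
  mean_t <- tm$feb_C[idx] + (month - 2) / 5 * (tm$jul_C[idx] - tm$feb_C[idx])
  draw <- function() mean_t + stats::rnorm(n, 0, cfg$temp_noise_sd)
  if (cfg$temp_noise_sd == 0) return(mean_t)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Flag temperatures exceeding a rearing threshold
#'
#' @param temp_C Numeric temperatures.
#' @param threshold_C Threshold (default 17.5 deg C, a recommended upper limit
#'   for Chinook rearing).
#' @return Logical vector.
#' @export
temperature_exceeds <- function(temp_C, threshold_C = 17.5) {
  temp_C > threshold_C
}

#' Generate a complete synthetic diet dataset
#'
#' Draws a full dataset (fish records, prey items, energy table) under the
#' configured design, plus the ground truth needed to recompute every
#' simulated quantity. Non-empty fish counts per (site, month) cell equal the
#' design exactly; empty-stomach fish are inserted on top at
#' `empty_stomach_rate`, so applying [apply_exclusions()] returns exactly the
#' design counts.
#'
#' @param cfg A [generator_config()].
#' @return List with `dataset` (a `diet_dataset`) and `truth`: list with
#'   `profiles` (expected per-site taxon proportions), `realized_proportions`
#'   (empirical per-site count shares), `fish_latent` (per-fish expected IR
#'   and ER), `n_empty`, and `seed`.
#' @export
generate_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::with_seed(cfg$seed, generate_dataset_impl(cfg))
}

generate_dataset_impl <- function(cfg) {
  design <- cfg$design
  taxa <- colnames(cfg$profiles)
  wm <- cfg$weight_model[match(taxa, cfg$weight_model$taxon), ]
  if (any(is.na(wm$median_mg))) stop("weight model missing taxa")

  # --- fish table -----------------------------------------------------------
  cells <- vector("list", nrow(design))
  extra_rate <- cfg$empty_stomach_rate / (1 - cfg$empty_stomach_rate)
  for (i in seq_len(nrow(design))) {
    n <- design$n[i]
    n_empty <- stats::rbinom(1, n, extra_rate)
    cells[[i]] <- tibble(
      site = design$site[i], month = design$month[i],
      year = c(spread_years(n, cfg$years),
               sample(cfg$years, n_empty, replace = TRUE)),
      empty = rep(c(FALSE, TRUE), c(n, n_empty)))
  }
  fish <- bind_rows(cells)
  n_fish <- nrow(fish)
  fish$fish_id <- sprintf("F%05d", seq_len(n_fish))

  # exact per-site length-bin and mark-status margins over the design fish;
  # empty extras drawn from the site proportions
  fish$small <- NA
  fish$mark_status <- NA_character_
  mg <- cfg$margins
  for (s in unique(fish$site)) {
    row <- mg[mg$site == s, ]
    idx <- which(fish$site == s & !fish$empty)
    have_margins <- nrow(row) == 1 && length(idx) == row$small + row$large &&
      length(idx) == row$unmarked + row$marked
    if (have_margins) {
      # exact margin counts, shuffled independently over the site's fish
      fish$small[idx] <- sample(rep(c(TRUE, FALSE), c(row$small, row$large)))
      fish$mark_status[idx] <-
        sample(rep(c("unmarked", "marked"), c(row$unmarked, row$marked)))
      p_small <- row$small / (row$small + row$large)
      p_unmarked <- row$unmarked / (row$unmarked + row$marked)
    } else {
      # design differs from the shipped margins: fall back to proportions
      p_small <- if (nrow(row) == 1) row$small / (row$small + row$large) else 0.5
      p_unmarked <- if (nrow(row) == 1)
        row$unmarked / (row$unmarked + row$marked) else 0.8
      fish$small[idx] <- stats::runif(length(idx)) < p_small
      fish$mark_status[idx] <- ifelse(stats::runif(length(idx)) < p_unmarked,
                                      "unmarked", "marked")
    }
    jdx <- which(fish$site == s & fish$empty)
    if (length(jdx)) {
      fish$small[jdx] <- stats::runif(length(jdx)) < p_small
      fish$mark_status[jdx] <- ifelse(stats::runif(length(jdx)) < p_unmarked,
                                      "unmarked", "marked")
    }
  }
  fish$fork_length_mm <- ifelse(fish$small,
                                stats::runif(n_fish, 30, 66),
                                stats::runif(n_fish, 66, 100))
  fish$mass_g <- cfg$mass_a * fish$fork_length_mm^cfg$mass_b *
    exp(stats::rnorm(n_fish, 0, cfg$mass_sdlog))
  fish$water_temp_C <- generate_temperatures(fish$site, fish$month, cfg)

  # --- prey table -----------------------------------------------------------
  nonempty <- which(!fish$empty)
  totals <- 1L + stats::rnbinom(length(nonempty),
                                mu = cfg$mean_count - 1,
                                size = cfg$count_dispersion)
  conc <- cfg$profiles[fish$site[nonempty], , drop = FALSE]
  g <- matrix(stats::rgamma(length(conc), shape = conc), nrow(conc))
  probs <- g / rowSums(g)
  counts <- matrix(0L, length(nonempty), length(taxa),
                   dimnames = list(NULL, taxa))
  for (f in seq_along(nonempty)) {
    counts[f, ] <- stats::rmultinom(1, totals[f], probs[f, ])
  }
  idx <- which(counts > 0, arr.ind = TRUE)
  prey <- tibble(
    fish_id = fish$fish_id[nonempty[idx[, 1]]],
    site = fish$site[nonempty[idx[, 1]]],
    taxon = taxa[idx[, 2]],
    count = counts[idx])
  # chironomid counts split over life stages; everything else "unknown"
  chiro <- prey$taxon == "Diptera:Chironomidae"
  split <- cfg$chironomid_stage_split
  if (any(chiro)) {
    stages <- t(vapply(prey$count[chiro],
                       function(k) drop(stats::rmultinom(1, k, split)),
                       numeric(length(split))))
    colnames(stages) <- names(split)
    base <- prey[chiro, ]
    expanded <- bind_rows(lapply(names(split), function(st) {
      keep <- stages[, st] > 0
      out <- base[keep, ]
      out$life_stage <- st
      out$count <- stages[keep, st]
      out
    }))
    rest <- prey[!chiro, ]
    rest$life_stage <- "unknown"
    prey <- bind_rows(rest, expanded)
  } else {
    prey$life_stage <- "unknown"
  }
  wrow <- match(prey$taxon, wm$taxon)
  prey$weight_g <- prey$count *
    exp(log(wm$median_mg[wrow]) +
          stats::rnorm(nrow(prey), 0, wm$sdlog[wrow])) / 1000
  prey <- prey %>%
    arrange(.data$fish_id, .data$taxon, .data$life_stage) %>%
    select("fish_id", "taxon", "life_stage", "count", "weight_g")
  prey$count <- as.integer(prey$count)

  # --- fullness from IR quantiles ------------------------------------------
  pw <- tapply(prey$weight_g, prey$fish_id, sum)
  ir <- rep(0, n_fish)
  ir[match(names(pw), fish$fish_id)] <- pw
  ir <- ir / fish$mass_g
  cat5 <- findInterval(ir, stats::quantile(ir[!fish$empty],
                                           probs = seq(0.2, 0.8, 0.2)),
                       left.open = TRUE) + 2L
  cat5[fish$empty] <- 2L
  cat5[stats::runif(n_fish) < cfg$fullness_missing_rate] <- NA_integer_
  fish$fullness_category <- cat5

  fish_tbl <- fish %>%
    select("fish_id", "site", "year", "month", "fork_length_mm", "mass_g",
           "mark_status", "water_temp_C", "fullness_category") %>%
    mutate(year = as.integer(.data$year), month = as.integer(.data$month))
  energy <- energy_table(cfg$energy_densities,
                         default_density = cfg$default_density)
  ds <- diet_dataset(fish_tbl, prey, energy)

  # --- ground truth ---------------------------------------------------------
  expected_p <- sweep(cfg$profiles, 1, rowSums(cfg$profiles), "/")
  realized <- prey %>%
    left_join(fish_tbl[, c("fish_id", "site")], by = "fish_id") %>%
    group_by(.data$site, .data$taxon) %>%
    summarise(count = sum(.data$count), .groups = "drop_last") %>%
    mutate(prop = .data$count / sum(.data$count)) %>%
    ungroup()
  mean_item_g <- wm$median_mg * exp(wm$sdlog^2 / 2) / 1000
  dens <- energy_density(energy, taxa, warn = FALSE)
  site_p <- expected_p[fish_tbl$site, , drop = FALSE]
  fish_latent <- tibble(
    fish_id = fish_tbl$fish_id,
    expected_ir = ifelse(fish$empty, 0, cfg$mean_count *
                           drop(site_p %*% mean_item_g) / fish_tbl$mass_g),
    expected_er = ifelse(fish$empty, 0, cfg$mean_count *
                           drop(site_p %*% (mean_item_g * dens)) /
                           fish_tbl$mass_g))
  truth <- list(profiles = expected_p, realized_proportions = realized,
                fish_latent = fish_latent, n_empty = sum(fish$empty),
                seed = cfg$seed)
  list(dataset = ds, truth = truth)
}

#' Simulate gamma log-link responses with known coefficients
#'
#' Draws `x_i ~ Gamma(shape = 1/alpha, scale = mu_i * alpha)` with
#' `log(mu_i) = X_i beta`, where `X` is the treatment-coded model matrix of
#' `design` (plus intercept). Supports parameter-recovery tests of
#' [fit_gamma_loglink()].
#'
#' @param n Number of draws; when `design` is given it is recycled to `n`
#'   rows.
#' @param beta Coefficient vector (intercept first, log scale).
#' @param alpha Gamma dispersion; > 0.
#' @param design Optional data frame of factor columns; `NULL` means
#'   intercept-only.
#' @param seed Optional integer seed.
#' @return Tibble: the design columns (if any), `mu`, and `response`.
#' @export
generate_gamma_responses <- function(n, beta, alpha, design = NULL,
                                     seed = NULL) {
  stopifnot(alpha > 0, n >= 1)
  if (is.null(design)) {
    design <- data.frame(row.names = seq_len(n))
    X <- matrix(1, n, 1)
  } else {
    design <- as.data.frame(lapply(design, rep_len, n))
    design[] <- lapply(design, function(col)
      if (is.character(col)) factor(col) else col)
    X <- stats::model.matrix(~., design)
  }
  if (ncol(X) != length(beta)) {
    stop("beta has length ", length(beta), " but the design matrix has ",
         ncol(X), " columns")
  }
  mu <- exp(drop(X %*% beta))
  draw <- function() stats::rgamma(n, shape = 1 / alpha, scale = mu * alpha)
  y <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- as_tibble(design)
  out$mu <- mu
  out$response <- y
  out
}
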