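#' Configuration for an end-to-end pipeline run
#'
#' Exactly one of `input_paths` (named list/vector with `fish`, `prey`,
#' `energy`) or `generator` (a [generator_config()]) must be supplied.
#'
#' @param input_paths Paths to the three input CSVs, or `NULL`.
#' @param generator A [generator_config()], or `NULL`.
#' @param out_dir Output directory for the run's delimited-text artifacts.
#' @param seed Root seed; stage seeds (generator, ANOSIM, NMDS restarts,
#'   species-vector permutations) are derived from it so stages can be re-run
#'   in isolation.
#' @param composition_by Grouping for the composition tables.
#' @param matrix_by Grouping for the diet matrix rows.
#' @param scheme Length-bin scheme for the diet matrix (`"ordination"` or
#'   `"model"`).
#' @param n_permutations Permutations for ANOSIM and species vectors.
#' @param nmds_restarts,nmds_max_iter NMDS settings.
#' @param model_specs Named list: response -> character vector of fixed
#'   factors; defaults to the standard three scores (IR/ER by site, month and
#'   length bin; Jm by site, month and mark status).
#' @param temp_threshold_C Temperature-exceedance threshold for the summary.
#' @return List of class `run_config`.
#' @export
run_config <- function(input_paths = NULL, generator = NULL,
                       out_dir = tempfile("dietrun"), seed = 1L,
                       composition_by = "site",
                       matrix_by = c("site", "year", "length_bin"),
                       scheme = c("ordination", "model"),
                       n_permutations = 199,
                       nmds_restarts = 4, nmds_max_iter = 200,
                       model_specs = list(
                         ir = c("site", "month", "length_bin"),
                         er = c("site", "month", "length_bin"),
                         jm = c("site", "month", "mark_status")),
                       temp_threshold_C = 17.5) {
  if (is.null(input_paths) == is.null(generator)) {
    stop("exactly one of input_paths / generator must be given")
  }
  scheme <- match.arg(scheme)
  structure(list(input_paths = input_paths, generator = generator,
                 out_dir = out_dir, seed = as.integer(seed),
                 composition_by = composition_by, matrix_by = matrix_by,
                 scheme = scheme, n_permutations = n_permutations,
                 nmds_restarts = nmds_restarts,
                 nmds_max_iter = nmds_max_iter, model_specs = model_specs,
                 temp_threshold_C = temp_threshold_C),
            class = "run_config")
}

#' Run the full stomach-content analysis pipeline
#'
#' Stages, in order: generate or read the dataset; apply exclusions;
#' per-group composition tables; per-fish foraging scores; diet matrix and
#' Bray-Curtis dissimilarities; NMDS with fitted species vectors; global and
#' pairwise ANOSIM plus SIMPER by site; gamma log-link models of each score
#' with year vs year-month blocking chosen by AICc, estimated marginal means
#' and pairwise effect sizes; fullness histograms; per-site monthly
#' temperature summary with threshold exceedances. All tables are written as
#' CSV into `cfg$out_dir` together with a JSON manifest (seed, stage row
#' counts, file checksums) that reproduces the run. A failure in the NMDS
#' stage is reported in the manifest without aborting the run.
#'
#' @param cfg A [run_config()].
#' @return List of class `run_report` with all stage outputs and the
#'   manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- cfg$seed + c(generator = 0L, anosim = 1L, nmds = 2L,
                        vectors = 3L, models = 4L)
  notes <- character(0)

  if (!is.null(cfg$generator)) {
    gen_cfg <- cfg$generator
    gen_cfg$seed <- seeds[["generator"]]
    gen <- generate_dataset(gen_cfg)
    ds <- gen$dataset
    truth <- gen$truth
  } else {
    ds <- read_dataset(cfg$input_paths[["fish"]], cfg$input_paths[["prey"]],
                       cfg$input_paths[["energy"]])
    truth <- NULL
  }
  n_in <- nrow(ds$fish)

  excl <- apply_exclusions(ds)
  ds <- excl$dataset

  comp <- composition(ds, by = cfg$composition_by)
  rations <- ration_table(ds)
  m <- diet_matrix(ds, by = cfg$matrix_by, scheme = cfg$scheme)
  groups <- attr(m, "groups")$site
  d <- bray_curtis(m)

  ord <- tryCatch(
    nmds(d, n_restarts = cfg$nmds_restarts, max_iter = cfg$nmds_max_iter,
         seed = seeds[["nmds"]]),
    error = function(e) {
      notes <<- c(notes, paste("nmds failed:", conditionMessage(e)))
      NULL
    })
  vectors <- if (!is.null(ord)) {
    fit_species_vectors(m, ord, n_permutations = cfg$n_permutations,
                        seed = seeds[["vectors"]])
  }

  global_anosim <- anosim(d, groups, n_permutations = cfg$n_permutations,
                          seed = seeds[["anosim"]])
  pair_tab <- pairwise_anosim(d, groups,
                              n_permutations = cfg$n_permutations,
                              seed = seeds[["anosim"]] + 100L)
  simper_tab <- simper(m, groups)

  models <- lapply(names(cfg$model_specs), function(resp) {
    factors <- cfg$model_specs[[resp]]
    fits <- lapply(c("year", "year_month"), function(bl) {
      tryCatch(fit_gamma_loglink(rations, resp, factors, blocking = bl),
               error = function(e) NULL)
    })
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) return(NULL)
    fit <- fits[[which.min(vapply(fits, aicc, numeric(1)))]]
    comparisons <- bind_rows(lapply(factors, function(f) {
      emm <- estimated_marginal_means(fit, f)
      cmp <- pairwise_comparisons(emm, fit)
      cmp$factor <- f
      cmp
    }))
    list(fit = fit, comparisons = comparisons)
  })
  names(models) <- names(cfg$model_specs)

  fullness <- fullness_histogram(ds$fish)
  temps <- ds$fish %>%
    group_by(.data$site, .data$month) %>%
    summarise(mean_temp_C = mean(.data$water_temp_C),
              n = dplyr::n(), .groups = "drop") %>%
    mutate(exceeds_threshold = temperature_exceeds(.data$mean_temp_C,
                                                   cfg$temp_threshold_C))

  comparison_tab <- bind_rows(lapply(names(models), function(resp) {
    if (is.null(models[[resp]])) return(NULL)
    out <- models[[resp]]$comparisons
    out$response <- resp
    out
  }))

  # write artifacts
  files <- list(
    exclusion_report.csv = excl$report,
    composition.csv = comp,
    rations.csv = rations,
    diet_matrix.csv = as_tibble(cbind(attr(m, "groups"),
                                      as.data.frame(unclass(m)))),
    anosim_pairwise.csv = pair_tab,
    simper.csv = simper_tab,
    model_comparisons.csv = comparison_tab,
    fullness.csv = fullness,
    temperatures.csv = temps)
  if (!is.null(ord)) {
    files$nmds_coordinates.csv <- as_tibble(cbind(attr(m, "groups"),
                                                  as.data.frame(ord$points)))
    files$species_vectors.csv <- vectors
  }
  for (nm in names(files)) {
    readr::write_csv(files[[nm]], file.path(cfg$out_dir, nm), progress = FALSE)
  }
  checksums <- tools::md5sum(file.path(cfg$out_dir, names(files)))
  names(checksums) <- names(files)

  manifest <- list(
    seed = cfg$seed, stage_seeds = as.list(seeds),
    n_fish_in = n_in,
    exclusions = stats::setNames(as.list(excl$report$n), excl$report$rule),
    n_groups = nrow(m), n_taxa = ncol(m),
    nmds_stress = if (!is.null(ord)) ord$stress else NA,
    global_anosim = list(r = global_anosim$statistic,
                         p = global_anosim$p_value),
    model_aicc = lapply(models, function(mo)
      if (is.null(mo)) NA else
        list(blocking = mo$fit$blocking, aicc = mo$fit$aicc)),
    notes = notes,
    files = as.list(checksums))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(dataset = ds, truth = truth, exclusions = excl$report,
                 composition = comp, rations = rations, diet_matrix = m,
                 nmds = ord, species_vectors = vectors,
                 global_anosim = global_anosim, pairwise_anosim = pair_tab,
                 simper = simper_tab, models = models,
                 fullness = fullness, temperatures = temps,
                 manifest = manifest),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", nrow(x$dataset$fish), " fish after exclusions, ",
      nrow(x$diet_matrix), " diet-matrix groups, global ANOSIM R = ",
      signif(x$global_anosim$statistic, 3), "\n", sep = "")
  invisible(x)
}

#' Design-table summary of a dataset
#'
#' Cross-tabulates a (post-exclusion) dataset the way the sampling-design
#' table is printed: site columns with per-month counts, a length-bin row, a
#' mark-status row and per-site totals; plus the headline shares (percent
#' unmarked, percent at the middle three sites).
#'
#' @param ds A `diet_dataset`.
#' @return List: `by_month` (month x site count matrix), `by_length_bin`
#'   (bin x site, model scheme), `by_mark` (status x site), `site_totals`,
#'   `grand_total`, `unmarked_total`, `unmarked_pct`, `middle_three_pct`.
#' @export
summarize_table1 <- function(ds) {
  stopifnot(inherits(ds, "diet_dataset"))
  fish <- ds$fish
  sites <- intersect(study_sites(), unique(fish$site))
  if (!length(sites)) sites <- unique(fish$site)
  site_f <- factor(fish$site, levels = sites)
  by_month <- table(month = factor(fish$month, levels = 2:7), site = site_f)
  bins <- assign_length_bin(fish$fork_length_mm, scheme = "model")
  by_length <- table(length_bin = bins, site = site_f)
  by_mark <- table(mark_status = factor(fish$mark_status,
                                        levels = c("unmarked", "marked")),
                   site = site_f)
  site_totals <- as.integer(table(site_f))
  names(site_totals) <- sites
  grand <- sum(site_totals)
  unmarked <- sum(fish$mark_status == "unmarked")
  middle <- intersect(c("Welch Island", "Whites Island", "Campbell Slough"),
                      sites)
  list(by_month = unclass(by_month),
       by_length_bin = unclass(by_length),
       by_mark = unclass(by_mark),
       site_totals = site_totals,
       grand_total = grand,
       unmarked_total = unmarked,
       unmarked_pct = if (grand) 100 * unmarked / grand else 0,
       middle_three_pct = if (grand)
         100 * sum(site_totals[middle]) / grand else 0)
}
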