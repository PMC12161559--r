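# Two-fish worked example: fish1 has taxon A (count 3, 0.03 g) and B (1,
# 0.01 g); fish2 has B (2, 0.06 g). Hand-worked IRI: A = 40, B = 120.
two_fish_dataset <- function() {
  fish <- tibble::tibble(
    fish_id = c("f1", "f2"), site = "Welch Island", year = 2019L, month = 5L,
    fork_length_mm = c(50, 60), mass_g = c(1, 2), mark_status = "unmarked",
    water_temp_C = 12, fullness_category = c(4L, NA))
  prey <- tibble::tibble(
    fish_id = c("f1", "f1", "f2"), taxon = c("A", "B", "B"),
    life_stage = "unknown", count = c(3L, 1L, 2L),
    weight_g = c(0.03, 0.01, 0.06))
  diet_dataset(fish, prey, energy_table(c(A = 4, B = 3)))
}

# small, fast generator config: two sites with contrasting profiles,
# a handful of fish per cell
small_generator_config <- function(seed = 1L, n_per_cell = 15L,
                                   empty_rate = 0.05) {
  design <- expand.grid(site = c("Welch Island", "Franz Lake"),
                        month = 4:6, stringsAsFactors = FALSE)
  design$n <- n_per_cell
  generator_config(design = tibble::as_tibble(design), years = 2019:2021,
                   empty_stomach_rate = empty_rate, seed = seed)
}

# brute-force ANOSIM p-value by enumerating every distinct label assignment
anosim_p_bruteforce <- function(d, groups) {
  n <- length(groups)
  lev <- unique(groups)
  stopifnot(length(lev) == 2)
  n1 <- sum(groups == lev[1])
  r_of <- function(lab) anosim(d, lab, n_permutations = 0)$statistic
  observed <- r_of(groups)
  picks <- utils::combn(n, n1, simplify = FALSE)
  stats <- vapply(picks, function(idx) {
    lab <- rep(lev[2], n)
    lab[idx] <- lev[1]
    r_of(lab)
  }, numeric(1))
  sum(stats >= observed - 1e-12) / length(stats)
}
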