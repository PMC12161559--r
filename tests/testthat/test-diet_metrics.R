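test_that("composition reproduces the hand-worked two-fish example", {
  comp <- composition(two_fish_dataset(), by = "site")
  a <- comp[comp$taxon == "A", ]
  b <- comp[comp$taxon == "B", ]
  expect_equal(a$numeric_pct, 50)
  expect_equal(a$gravimetric_pct, 30)
  expect_equal(a$freq_occurrence, 0.5)
  expect_equal(a$iri, 40)
  expect_equal(b$iri, 120)
  expect_equal(a$iri_pct, 25)
  expect_equal(b$iri_pct, 75)
})

test_that("a single taxon present in every stomach maxes out all indices", {
  ds <- two_fish_dataset()
  ds$prey <- ds$prey[ds$prey$taxon == "B", ]
  comp <- composition(ds, by = "site")
  expect_equal(comp$numeric_pct, 100)
  expect_equal(comp$gravimetric_pct, 100)
  expect_equal(comp$freq_occurrence, 1)
  expect_equal(comp$iri, 200)
  expect_equal(comp$iri_pct, 100)
})

test_that("composition percentages sum to 100 within every group", {
  gen <- generate_dataset(small_generator_config(seed = 5L))
  ds <- apply_exclusions(gen$dataset)$dataset
  comp <- composition(ds, by = c("site", "month"))
  sums <- dplyr::summarise(dplyr::group_by(comp, site, month),
                           n = sum(numeric_pct), g = sum(gravimetric_pct),
                           i = sum(iri_pct))
  expect_equal(sums$n, rep(100, nrow(sums)))
  expect_equal(sums$g, rep(100, nrow(sums)))
  expect_equal(sums$i, rep(100, nrow(sums)))
  expect_true(all(comp$freq_occurrence > 0 & comp$freq_occurrence <= 1))
  expect_true(all(comp$iri >= 0 & comp$iri <= 200))
})

test_that("IRI is invariant to splitting a prey row with counts/weights preserved", {
  ds <- two_fish_dataset()
  base <- composition(ds, by = "site")
  split <- ds
  row <- split$prey[1, ]
  split$prey <- dplyr::bind_rows(
    split$prey[-1, ],
    transform(row, count = 2L, weight_g = 0.02, life_stage = "larva"),
    transform(row, count = 1L, weight_g = 0.01, life_stage = "pupa"))
  comp2 <- composition(split, by = "site")
  expect_equal(dplyr::arrange(comp2, taxon)$iri,
               dplyr::arrange(base, taxon)$iri)
})

test_that("scaling one taxon's weights strictly increases its %G", {
  ds <- two_fish_dataset()
  before <- composition(ds, by = "site")
  ds$prey$weight_g[ds$prey$taxon == "A"] <-
    ds$prey$weight_g[ds$prey$taxon == "A"] * 3
  after <- composition(ds, by = "site")
  expect_gt(after$gravimetric_pct[after$taxon == "A"],
            before$gravimetric_pct[before$taxon == "A"])
})

test_that("pooled-group %N lies between the groups' separate %N values", {
  gen <- generate_dataset(small_generator_config(seed = 11L))
  ds <- apply_exclusions(gen$dataset)$dataset
  by_site <- composition(ds, by = "site")
  pooled <- composition(ds, by = character(0))
  for (tx in unique(pooled$taxon)) {
    vals <- by_site$numeric_pct[by_site$taxon == tx]
    if (length(vals) == 2) {
      pool <- pooled$numeric_pct[pooled$taxon == tx]
      expect_gte(pool, min(vals) - 1e-9)
      expect_lte(pool, max(vals) + 1e-9)
    }
  }
})

test_that("instantaneous and energy rations match hand arithmetic", {
  expect_equal(instantaneous_ration(c(0.06, 0.04), 10), 0.01)
  expect_equal(instantaneous_ration(numeric(0), 5), 0)
  expect_equal(instantaneous_ration(0.0123, 4.1), 0.003)
  expect_error(instantaneous_ration(0.1, 0), "positive")
  en <- energy_table(c(x = 4))
  expect_equal(energy_ration(0.05, "x", en, 10), 0.02)
  en2 <- energy_table(c(p = 5, q = 3))
  expect_equal(energy_ration(c(0.02, 0.03), c("p", "q"), en2, 2), 0.095)
  # equal densities factorise: ER = c * IR
  en3 <- energy_table(c(p = 2.5, q = 2.5))
  w <- c(0.017, 0.003, 0.04)
  expect_equal(energy_ration(w, c("p", "q", "p"), en3, 3.3),
               2.5 * instantaneous_ration(w, 3.3))
  expect_warning(energy_ration(0.01, "unknown_taxon", en, 1), "default")
})

test_that("maintenance metabolism matches its closed form and properties", {
  expect_identical(maintenance_metabolism(1, 0), 0.003)
  expect_equal(log(maintenance_metabolism(1, 1) / maintenance_metabolism(1, 0)),
               0.68)
  expect_equal(maintenance_metabolism(2, 10), 0.003 * exp(6.8) * 2)
  # linear in mass, increasing in temperature
  w <- c(0.5, 1, 2, 7)
  expect_equal(maintenance_metabolism(w, 13), w * maintenance_metabolism(1, 13))
  temps <- seq(-2, 25, by = 0.5)
  expect_true(all(diff(maintenance_metabolism(1, temps)) > 0))
  # custom parameters respected
  p <- metabolism_params(jm0 = 0.01, d = 0.068)
  expect_equal(maintenance_metabolism(3, 10, p), 0.01 * exp(0.68) * 3)
  expect_error(maintenance_metabolism(-1, 5), "positive")
})

test_that("uniform prey-weight scaling scales IR and ER, preserving IRI ranks", {
  gen <- generate_dataset(small_generator_config(seed = 8L))
  ds <- apply_exclusions(gen$dataset)$dataset
  rt1 <- ration_table(ds)
  comp1 <- composition(ds, by = "site")
  ds2 <- ds
  ds2$prey$weight_g <- ds2$prey$weight_g * 2.5
  rt2 <- ration_table(ds2)
  comp2 <- composition(ds2, by = "site")
  expect_equal(rt2$ir, 2.5 * rt1$ir)
  expect_equal(rt2$er, 2.5 * rt1$er)
  ord1 <- with(comp1, tapply(iri, list(site, taxon), sum))
  ord2 <- with(comp2, tapply(iri, list(site, taxon), sum))
  for (s in rownames(ord1)) {
    expect_equal(order(ord1[s, ]), order(ord2[s, ]))
  }
})

test_that("fullness histograms tally categories per site with missing separate", {
  fish <- two_fish_dataset()$fish
  fish$fullness_category <- c(2L, 2L)
  fish2 <- fish
  fish2$fish_id <- c("g1", "g2")
  fish2$fullness_category <- c(6L, NA)
  h <- fullness_histogram(dplyr::bind_rows(fish, fish2))
  expect_equal(h$n[h$category == "2"], 2L)
  expect_equal(h$n[h$category == "6"], 1L)
  expect_equal(h$n[h$category == "missing"], 1L)
  expect_equal(sum(h$n), 4L)
  # all-missing case
  fish$fullness_category <- NA_integer_
  h0 <- fullness_histogram(fish)
  expect_equal(h0$n[h0$category == "missing"], 2L)
  expect_equal(sum(h0$n), 2L)
})
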