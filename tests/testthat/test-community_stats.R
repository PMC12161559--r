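test_that("Bray-Curtis matches hand arithmetic and its boundary cases", {
  m <- rbind(a = c(1, 2, 3), b = c(2, 1, 3), c = c(1, 2, 3),
             d = c(0, 0, 4), e = c(5, 1, 0), z = c(0, 0, 0), z2 = c(0, 0, 0))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 2 / 12)
  expect_equal(d["a", "c"], 0)              # identical rows
  expect_equal(d["d", "e"], 1)              # disjoint supports
  expect_equal(d["z", "z2"], 0)             # two all-zero rows
  expect_equal(d, t(d))
  expect_equal(diag(d), setNames(rep(0, 7), rownames(m)))
  expect_true(all(d >= 0 & d <= 1))
  expect_error(bray_curtis(rbind(c(-1, 2))), "non-negative")
  # invariant to common positive rescaling of all rows
  expect_equal(bray_curtis(m * 7.3), d)
})

test_that("ANOSIM yields R = 1 under perfect separation and ~0 under the null", {
  # two tight clusters far apart
  set.seed(42)
  x <- rbind(matrix(rnorm(10, 0, 0.1), 5), matrix(rnorm(10, 50, 0.1), 5))
  d <- as.matrix(dist(x))
  g <- rep(c("a", "b"), each = 5)
  res <- anosim(d, g, n_permutations = 99, seed = 1)
  expect_equal(res$statistic, 1)
  expect_lte(res$p_value, 0.05)
  # structureless data: R centred near 0 over seeds
  rs <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      dd <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
      anosim(dd, sample(rep(c("a", "b"), each = 5)),
             n_permutations = 0)$statistic
    })
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
  expect_error(anosim(d, rep("a", 10)), "2 groups")
})

test_that("exact ANOSIM p equals brute-force enumeration over label assignments", {
  withr::with_seed(7, {
    d <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  })
  g <- rep(c("x", "y"), each = 3)
  ex <- anosim(d, g, exact = TRUE)
  expect_equal(ex$n_permutations, 20L)  # choose(6, 3) distinct assignments
  expect_equal(ex$p_value, anosim_p_bruteforce(d, g))
})

test_that("ANOSIM R is invariant to strictly monotone transforms", {
  withr::with_seed(13, {
    d <- as.matrix(dist(matrix(rnorm(24), 8, 3)))
  })
  g <- rep(c("a", "b"), 4)
  expect_equal(anosim(d, g, n_permutations = 0)$statistic,
               anosim(d^2, g, n_permutations = 0)$statistic)
})

test_that("pairwise ANOSIM applies Bonferroni and sees duplicated groups as null", {
  set.seed(3)
  base <- matrix(rnorm(16), 8, 2)
  x <- rbind(base, base + matrix(rnorm(16, 0, 0.05), 8, 2),
             matrix(rnorm(16, 30), 8, 2))
  d <- as.matrix(dist(x))
  g <- rep(c("dup1", "dup2", "far"), each = 8)
  tab <- pairwise_anosim(d, g, n_permutations = 199, seed = 5)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$p_bonferroni, pmin(1, 3 * tab$p_value))
  dup_r <- tab$r[tab$group1 == "dup1" & tab$group2 == "dup2"]
  expect_lt(abs(dup_r), 0.25)
  far_r <- tab$r[tab$group2 == "far"]
  expect_true(all(far_r > 0.9))
})

test_that("SIMPER contributions sum to the mean between-group dissimilarity", {
  for (s in 1:100) {
    withr::with_seed(s, {
      m <- matrix(runif(8 * 5), 8, 5,
                  dimnames = list(NULL, paste0("t", 1:5)))
      g <- rep(c("a", "b"), each = 4)
    })
    out <- simper(m, g, pair = c("a", "b"))
    d <- bray_curtis(m)
    between <- d[1:4, 5:8]
    expect_equal(sum(out$average), mean(between), tolerance = 1e-9)
    expect_true(all(diff(out$cum_pct) >= -1e-12))
  }
})

test_that("SIMPER head list isolates the taxa that drive the difference", {
  # groups differ only in Amphipoda and Diptera
  m <- rbind(c(60, 10, 15, 15), c(58, 12, 15, 15),
             c(10, 60, 15, 15), c(12, 58, 15, 15))
  colnames(m) <- c("Amphipoda", "Diptera", "Cladocera", "Hemiptera")
  g <- rep(c("down", "up"), each = 2)
  out <- simper(m, g)
  expect_setequal(out$taxon[out$in_head], c("Amphipoda", "Diptera"))
  # single-taxon matrix: that taxon carries 100%
  m1 <- cbind(only = c(10, 50, 90, 20))
  out1 <- simper(m1, g)
  expect_equal(out1$contrib_pct, 100)
})

test_that("species vectors recover an axis-aligned taxon and reject noise", {
  withr::with_seed(21, {
    coords <- matrix(rnorm(40), 20, 2)
  })
  m <- cbind(axis_taxon = coords[, 1],
             noise = withr::with_seed(22, rnorm(20)),
             flat = rep(1, 20))
  out <- fit_species_vectors(m, coords, n_permutations = 199, seed = 9)
  aligned <- out[out$taxon == "axis_taxon", ]
  expect_equal(aligned$r_squared, 1, tolerance = 1e-9)
  expect_equal(abs(aligned$axis1), 1, tolerance = 1e-6)
  expect_lte(aligned$p_value, 0.05)
  flat <- out[out$taxon == "flat", ]
  expect_equal(flat$r_squared, 0)
  expect_equal(flat$p_value, 1)
  # i.i.d.-noise taxon is rarely significant across seeds
  hits <- vapply(1:40, function(s) {
    y <- withr::with_seed(100 + s, rnorm(20))
    res <- fit_species_vectors(cbind(t = y), coords, n_permutations = 99,
                               seed = s)
    res$p_value <= 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.2)
})

test_that("diet matrix rows are %IRI compositions summing to 100", {
  gen <- generate_dataset(small_generator_config(seed = 17L))
  ds <- apply_exclusions(gen$dataset)$dataset
  m <- diet_matrix(ds, by = c("site", "month"))
  expect_true(all(abs(rowSums(m) - 100) < 1e-9))
  expect_true(all(m >= 0))
  expect_equal(nrow(attr(m, "groups")), nrow(m))
})
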