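#' Build a groups-by-taxa %IRI diet matrix
#'
#' Rows are groups (by default site x year x length bin), columns are taxa,
#' cells are %IRI values; each row sums to 100. This matrix feeds all
#' multivariate statistics (Bray-Curtis, NMDS, ANOSIM, SIMPER).
#'
#' @param ds A post-exclusion `diet_dataset`.
#' @param by Grouping fish attributes; default `c("site", "year",
#'   "length_bin")`.
#' @param scheme Length-bin scheme; the ordination conventionally uses the
#'   three-bin `"ordination"` scheme.
#' @return Numeric matrix with rownames `group1|group2|...`; attribute
#'   `groups` holds the grouping tibble (row-aligned).
#' @export
diet_matrix <- function(ds, by = c("site", "year", "length_bin"),
                        scheme = c("ordination", "model")) {
  scheme <- match.arg(scheme)
  comp <- composition(ds, by = by, scheme = scheme)
  wide <- comp %>%
    select(all_of(by), "taxon", "iri_pct") %>%
    tidyr::pivot_wider(names_from = "taxon", values_from = "iri_pct",
                       values_fill = 0)
  keys <- wide[, by, drop = FALSE]
  m <- as.matrix(wide[, setdiff(names(wide), by), drop = FALSE])
  rownames(m) <- do.call(paste, c(as.list(keys), sep = "|"))
  attr(m, "groups") <- keys
  m
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = sum_i |a_i - b_i| / sum_i (a_i + b_i)` between all row pairs of
#' a non-negative matrix; in `[0, 1]`, 0 for identical rows, 1 for disjoint
#' supports. Two all-zero rows get d = 0.
#'
#' @param m Non-negative numeric matrix (rows = samples, columns = taxa).
#' @return Symmetric dissimilarity matrix with zero diagonal, preserving row
#'   names.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("Bray-Curtis requires non-negative values")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  rs <- rowSums(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- rs[i] + rs[j]
      d[i, j] <- d[j, i] <-
        if (denom == 0) 0 else sum(abs(m[i, ] - m[j, ])) / denom
    }
  }
  d
}

# Midranks of the off-diagonal dissimilarities, returned as a symmetric matrix.
rank_dissimilarity <- function(d) {
  n <- nrow(d)
  ut <- upper.tri(d)
  r <- rank(d[ut])  # average ranks on ties
  rm <- matrix(0, n, n)
  rm[ut] <- r
  rm + t(rm)
}

anosim_stat <- function(rank_m, within) {
  n <- nrow(rank_m)
  ut <- upper.tri(rank_m)
  rb <- mean(rank_m[ut][!within])
  rw <- mean(rank_m[ut][within])
  (rb - rw) / (n * (n - 1) / 4)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group separation on a dissimilarity matrix.
#' All off-diagonal dissimilarities are ranked (average ranks on ties) and
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`,
#' in `[-1, 1]`. The p-value permutes group labels and uses the add-one
#' estimator `p = (1 + #{R* >= R}) / (1 + n_permutations)` so p is never 0.
#' With `exact = TRUE` all distinct label arrangements are enumerated instead
#' and `p = #{R* >= R} / #arrangements` (the observed arrangement included).
#'
#' @param d Symmetric dissimilarity matrix.
#' @param groups Group labels, one per row of `d`; at least two groups, at
#'   least one between-group pair.
#' @param n_permutations Number of random label permutations.
#' @param seed Optional integer seed for the permutations.
#' @param exact Enumerate all distinct label arrangements (feasible only for
#'   small n; capped at 200,000 arrangements).
#' @return List of class `anosim_result`: `statistic` (R), `p_value`,
#'   `n_permutations`, `exact`.
#' @export
anosim <- function(d, groups, n_permutations = 999, seed = NULL,
                   exact = FALSE) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  stopifnot(nrow(d) == length(groups))
  if (length(unique(groups)) < 2) stop("anosim needs >= 2 groups")
  n <- nrow(d)
  rank_m <- rank_dissimilarity(d)
  ut <- upper.tri(d)
  pair_i <- row(d)[ut]
  pair_j <- col(d)[ut]
  ranks <- rank_m[ut]
  scale <- n * (n - 1) / 4
  stat_for <- function(lab) {
    within <- lab[pair_i] == lab[pair_j]
    (mean(ranks[!within]) - mean(ranks[within])) / scale
  }
  observed <- stat_for(groups)
  if (exact) {
    perms <- multiset_permutations(groups, cap = 2e5)
    stats <- vapply(perms, stat_for, numeric(1))
    p <- sum(stats >= observed - 1e-12) / length(stats)
    return(structure(list(statistic = observed, p_value = p,
                          n_permutations = length(stats), exact = TRUE),
                     class = "anosim_result"))
  }
  run <- function() {
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      if (stat_for(sample(groups)) >= observed - 1e-12) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_permutations)
  }
  p <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(statistic = observed, p_value = p,
                 n_permutations = n_permutations, exact = FALSE),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat("ANOSIM R = ", signif(x$statistic, 4), ", p = ", signif(x$p_value, 4),
      if (x$exact) " (exact, " else " (", x$n_permutations,
      " permutations)\n", sep = "")
  invisible(x)
}

# All distinct permutations of a label multiset (cap guards combinatorial
# explosion).
multiset_permutations <- function(labels, cap = 2e5) {
  tab <- table(labels)
  n_distinct <- exp(lgamma(length(labels) + 1) - sum(lgamma(tab + 1)))
  if (n_distinct > cap) {
    stop("exact enumeration infeasible: ", round(n_distinct),
         " distinct arrangements")
  }
  recurse <- function(remaining) {
    if (sum(remaining) == 0) return(list(character(0)))
    out <- list()
    for (lab in names(remaining)[remaining > 0]) {
      rem <- remaining
      rem[lab] <- rem[lab] - 1
      out <- c(out, lapply(recurse(rem), function(p) c(lab, p)))
    }
    out
  }
  recurse(tab)
}

#' Pairwise ANOSIM with Bonferroni correction
#'
#' Runs [anosim()] on every pair of groups, subsetting and re-ranking the
#' dissimilarity submatrix for each pair; p-values are Bonferroni-adjusted by
#' multiplying by the number of pairs (capped at 1).
#'
#' @inheritParams anosim
#' @return Tibble: `group1, group2, r, p_value, p_bonferroni`.
#' @export
pairwise_anosim <- function(d, groups, n_permutations = 999, seed = NULL) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  levels <- unique(groups)
  if (length(levels) < 2) stop("need >= 2 groups")
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  seeds <- if (is.null(seed)) vector("list", length(pairs)) else
    as.list(seed + seq_along(pairs))
  rows <- Map(function(pr, s) {
    idx <- groups %in% pr
    res <- anosim(d[idx, idx, drop = FALSE], groups[idx],
                  n_permutations = n_permutations, seed = s)
    tibble(group1 = pr[1], group2 = pr[2], r = res$statistic,
           p_value = res$p_value)
  }, pairs, seeds)
  out <- bind_rows(rows)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out
}

#' Similarity percentages (SIMPER)
#'
#' Decomposes the average between-group Bray-Curtis dissimilarity into
#' per-taxon contributions. For each between-group row pair (a, b) the taxon
#' contribution is `|a_i - b_i| / sum_j (a_j + b_j)`; contributions are
#' averaged over all between-group pairs, so they sum exactly to the mean
#' between-group Bray-Curtis dissimilarity. The head list is the shortest
#' prefix of taxa, in descending contribution order, whose cumulative percent
#' reaches at least `cutoff` (the taxa driving the difference).
#'
#' @param m Non-negative groups-by-taxa matrix (e.g. a [diet_matrix()]).
#' @param groups Group labels per row of `m`.
#' @param pair Character vector of two group labels; `NULL` runs all pairs.
#' @param cutoff Cumulative-percent threshold for the head list (default 70).
#' @return Tibble: `group1, group2, taxon, average, contrib_pct, cum_pct,
#'   in_head`, ordered by descending contribution within pair.
#' @export
simper <- function(m, groups, pair = NULL, cutoff = 70) {
  m <- as.matrix(m)
  groups <- as.character(groups)
  stopifnot(nrow(m) == length(groups))
  pairs <- if (is.null(pair)) {
    utils::combn(unique(groups), 2, simplify = FALSE)
  } else {
    stopifnot(length(pair) == 2)
    list(pair)
  }
  bind_rows(lapply(pairs, function(pr) {
    a_rows <- which(groups == pr[1])
    b_rows <- which(groups == pr[2])
    if (!length(a_rows) || !length(b_rows)) {
      stop("empty group in pair ", pr[1], " vs ", pr[2])
    }
    contrib <- matrix(0, length(a_rows) * length(b_rows), ncol(m))
    k <- 0
    for (i in a_rows) for (j in b_rows) {
      k <- k + 1
      denom <- sum(m[i, ]) + sum(m[j, ])
      if (denom > 0) contrib[k, ] <- abs(m[i, ] - m[j, ]) / denom
    }
    avg <- colMeans(contrib)
    ord <- order(avg, decreasing = TRUE)
    pct <- if (sum(avg) > 0) 100 * avg / sum(avg) else avg
    cum <- cumsum(pct[ord])
    head_len <- if (any(cum >= cutoff)) which(cum >= cutoff)[1] else length(ord)
    tibble(group1 = pr[1], group2 = pr[2], taxon = colnames(m)[ord],
           average = avg[ord], contrib_pct = pct[ord], cum_pct = cum,
           in_head = seq_along(ord) <= head_len)
  }))
}

#' Fit taxon vectors onto an ordination
#'
#' For each taxon column, least-squares projection onto the NMDS coordinates:
#' direction (unit vector of the regression coefficients), squared multiple
#' correlation as association strength, and a permutation p-value obtained by
#' shuffling the taxon values over rows (add-one estimator). Taxa with
#' `p <= alpha` are flagged significant; constant columns get strength 0 and
#' p = 1.
#'
#' @param m Groups-by-taxa matrix, rows aligned with the ordination.
#' @param ord An [nmds()] result (or any matrix of coordinates).
#' @param n_permutations Number of row permutations.
#' @param seed Optional integer seed.
#' @param alpha Significance level for the flag.
#' @return Tibble: `taxon, axis1, axis2, ..., r_squared, p_value,
#'   significant`; the axis columns are the unit direction scaled by
#'   `sqrt(r_squared)` (arrow lengths comparable across taxa).
#' @export
fit_species_vectors <- function(m, ord, n_permutations = 999, seed = NULL,
                                alpha = 0.05) {
  coords <- if (inherits(ord, "nmds_result")) ord$points else as.matrix(ord)
  m <- as.matrix(m)
  stopifnot(nrow(m) == nrow(coords))
  xc <- scale(coords, center = TRUE, scale = FALSE)
  r2_of <- function(y) {
    yc <- y - mean(y)
    ss <- sum(yc^2)
    if (ss < 1e-300) return(NA_real_)
    fit <- stats::lm.fit(cbind(1, coords), y)
    1 - sum(fit$residuals^2) / ss
  }
  run <- function() {
    bind_rows(lapply(seq_len(ncol(m)), function(j) {
      y <- m[, j]
      r2 <- r2_of(y)
      k <- ncol(coords)
      if (is.na(r2)) {
        dir <- rep(0, k)
        r2 <- 0
        p <- 1
      } else {
        beta <- stats::lm.fit(cbind(1, xc), y - mean(y))$coefficients[-1]
        nrm <- sqrt(sum(beta^2))
        dir <- if (nrm > 0) beta / nrm else rep(0, k)
        hits <- 0L
        for (b in seq_len(n_permutations)) {
          r2p <- r2_of(sample(y))
          if (!is.na(r2p) && r2p >= r2 - 1e-12) hits <- hits + 1L
        }
        p <- (1 + hits) / (1 + n_permutations)
      }
      row <- tibble(taxon = colnames(m)[j], r_squared = r2, p_value = p,
                    significant = p <= alpha)
      axes <- as_tibble(as.list(setNames(dir * sqrt(r2),
                                         paste0("axis", seq_len(k)))))
      dplyr::bind_cols(row["taxon"], axes, row[-1])
    }))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
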