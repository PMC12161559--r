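# Pool-adjacent-violators: weighted isotonic (non-decreasing) regression of y.
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0) return(numeric(0))
  # block representation: value, weight, size
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    val[nb] <- y[i]; wt[nb] <- w[i]; sz[nb] <- 1L
    while (nb > 1L && val[nb - 1L] > val[nb]) {
      wsum <- wt[nb - 1L] + wt[nb]
      val[nb - 1L] <- (wt[nb - 1L] * val[nb - 1L] + wt[nb] * val[nb]) / wsum
      wt[nb - 1L] <- wsum
      sz[nb - 1L] <- sz[nb - 1L] + sz[nb]
      nb <- nb - 1L
    }
  }
  rep(val[seq_len(nb)], sz[seq_len(nb)])
}

# Kruskal stress-1 of a configuration against dissimilarity order `ord`
# (pairs sorted by dissimilarity, ties broken by configuration distance --
# Kruskal's primary approach). Returns stress and the disparities.
stress1 <- function(dhat, delta_order_key) {
  ord <- order(delta_order_key, dhat)
  dstar <- numeric(length(dhat))
  dstar[ord] <- pava(dhat[ord])
  s <- sqrt(sum((dhat - dstar)^2) / sum(dhat^2))
  list(stress = s, dstar = dstar)
}

#' Non-metric multidimensional scaling
#'
#' Kruskal-style NMDS: finds a k-dimensional configuration whose inter-point
#' distances are, as nearly as possible, a monotone function of the input
#' dissimilarities. Minimises Kruskal stress-1,
#' `sqrt(sum((dhat - dstar)^2) / sum(dhat^2))`, where `dhat` are configuration
#' distances and `dstar` their isotonic (pool-adjacent-violators) regression
#' on the dissimilarity ranks (primary tie treatment). Optimisation alternates
#' isotonic regression with a SMACOF-style majorisation update of the
#' configuration, accepting steps by step-halving so stress never increases
#' across accepted iterations. The first start is classical metric scaling
#' (`cmdscale`); further restarts add seeded jitter, and the best final stress
#' wins. The returned configuration is centred and rotated to principal axes,
#' so runs are comparable up to reflection.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`).
#' @param k Target dimension (default 2); requires `nrow(d) >= k + 1`.
#' @param n_restarts Random restarts beyond the metric-scaling start.
#' @param max_iter Maximum iterations per restart.
#' @param tol Convergence: relative stress change below `tol` stops a restart.
#' @param seed Optional integer seed for the restart jitter.
#' @return Object of class `nmds_result`: `points` (n x k), `stress`,
#'   `converged`, `n_restarts`, `stress_trace` (accepted-iteration stresses of
#'   the winning restart).
#' @export
nmds <- function(d, k = 2, n_restarts = 8, max_iter = 500, tol = 1e-6,
                 seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < k + 1) stop("need at least k + 1 points")
  if (any(abs(d - t(d)) > 1e-8)) stop("dissimilarity matrix must be symmetric")
  ut <- upper.tri(d)
  delta <- d[ut]
  if (sum(delta^2) == 0) stop("all dissimilarities are zero")

  run_one <- function(x0) {
    x <- x0
    dh <- as.matrix(stats::dist(x))[ut]
    st <- stress1(dh, delta)
    trace <- st$stress
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # majorisation (Guttman) update with dstar as disparities
      dm <- matrix(0, n, n)
      dm[ut] <- dh
      dm <- dm + t(dm)
      ds <- matrix(0, n, n)
      ds[ut] <- st$dstar
      ds <- ds + t(ds)
      ratio <- ifelse(dm > 1e-12, ds / dm, 0)
      b <- -ratio
      diag(b) <- -rowSums(b)
      x_target <- (b %*% x) / n
      step <- 1
      improved <- FALSE
      repeat {
        x_try <- x + step * (x_target - x)
        dh_try <- as.matrix(stats::dist(x_try))[ut]
        st_try <- stress1(dh_try, delta)
        if (st_try$stress <= st$stress + 1e-15) {
          improved <- st$stress - st_try$stress > 0
          rel <- (st$stress - st_try$stress) / max(st$stress, 1e-12)
          x <- x_try; dh <- dh_try; st <- st_try
          trace <- c(trace, st$stress)
          if (rel < tol) converged <- TRUE
          break
        }
        step <- step / 2
        if (step < 1e-6) break
      }
      if (converged || !improved) {
        converged <- converged || st$stress < 1e-12
        break
      }
    }
    list(x = x, stress = st$stress, converged = converged, trace = trace)
  }

  base <- suppressWarnings(stats::cmdscale(d, k = k))
  if (ncol(base) < k) {
    base <- cbind(base, matrix(0, n, k - ncol(base)))
  }
  scale0 <- max(stats::sd(as.vector(base)), 1e-3)
  run_all <- function() {
    best <- NULL
    for (r in seq_len(max(1, n_restarts))) {
      x0 <- if (r == 1) base else
        base + matrix(stats::rnorm(n * k, sd = 0.25 * scale0), n, k)
      res <- run_one(x0)
      if (is.null(best) || res$stress < best$stress) best <- res
    }
    best
  }
  best <- if (is.null(seed)) run_all() else withr::with_seed(seed, run_all())

  # centre and rotate to principal axes
  x <- scale(best$x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  x <- x %*% sv$v
  dimnames(x) <- list(rownames(d), paste0("axis", seq_len(k)))
  structure(list(points = x, stress = best$stress,
                 converged = best$converged, n_restarts = n_restarts,
                 stress_trace = best$trace),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat("<nmds_result> ", nrow(x$points), " points in ", ncol(x$points),
      " dims, stress-1 = ", signif(x$stress, 5),
      if (x$converged) "" else " (not converged)", "\n", sep = "")
  invisible(x)
}

#' Procrustes distance between two configurations
#'
#' Root-mean-square residual after optimally translating, rotating/reflecting
#' and rescaling `y` onto `x`. Used to compare NMDS solutions that are only
#' identified up to similarity transforms.
#'
#' @param x,y Matrices of identical dimension (rows aligned).
#' @return Scalar distance (0 when the configurations match exactly).
#' @export
procrustes_distance <- function(x, y) {
  x <- scale(as.matrix(x), center = TRUE, scale = FALSE)
  y <- scale(as.matrix(y), center = TRUE, scale = FALSE)
  x <- x / sqrt(sum(x^2))
  y <- y / sqrt(sum(y^2))
  sv <- svd(crossprod(x, y))
  sqrt(max(0, 1 - sum(sv$d)^2))
}
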