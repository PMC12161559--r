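#' Fit a gamma log-link regression of a foraging score
#'
#' Maximum-likelihood gamma regression with log link for the zero-bounded,
#' continuous, right-skewed per-fish scores (IR, ER, Jm). The gamma is
#' parameterised by mean `mu` and dispersion `alpha` (shape `1/alpha`, scale
#' `mu * alpha`, variance `alpha * mu^2`). Coefficients are fitted by
#' iteratively reweighted least squares; `alpha` by maximum likelihood given
#' the fitted means. Temporal blocking ("months nested within years" in the
#' original design) enters as fixed dummy blocks for year or year x month.
#' Aliased (rank-deficient) design columns — e.g. interactions requested for
#' site-month cells that were never sampled — are dropped with a message.
#'
#' @param data Data frame (e.g. a [ration_table()]) containing the response
#'   and all factor columns.
#' @param response Column name of the response; all values must be > 0.
#' @param factors Character vector of fixed-factor terms; elements may contain
#'   `:` for interactions (e.g. `c("site", "month", "site:month")`).
#' @param blocking `"year"` (default), `"year_month"` or `"none"`.
#' @return Object of class `gamma_fit`: `coefficients` (log scale), `alpha`,
#'   `vcov`, `fitted`, `log_lik`, `aicc`, `converged`, `iterations`,
#'   `dropped` (aliased column names), plus bookkeeping for marginal means.
#' @export
fit_gamma_loglink <- function(data, response, factors,
                              blocking = c("year", "year_month", "none")) {
  blocking <- match.arg(blocking)
  data <- as.data.frame(data)
  stopifnot(response %in% names(data), length(factors) >= 1)
  y <- data[[response]]
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("non-positive response in rows: ",
         paste(utils::head(which(!(is.finite(y) & y > 0)), 10), collapse = ", "))
  }
  # "1" denotes the intercept-only model
  base_vars <- setdiff(unique(unlist(strsplit(factors, ":", fixed = TRUE))), "1")
  block_terms <- switch(blocking,
    none = character(0),
    year = ".year_f",
    year_month = ".year_month_f")
  if (blocking == "year") {
    data$.year_f <- factor(data$year)
  } else if (blocking == "year_month") {
    data$.year_month_f <- factor(paste(data$year, data$month, sep = ":"))
  }
  missing_vars <- setdiff(base_vars, names(data))
  if (length(missing_vars)) {
    stop("factor column(s) not in data: ", paste(missing_vars, collapse = ", "))
  }
  for (v in base_vars) data[[v]] <- factor(data[[v]])
  fml <- stats::as.formula(
    paste("~", paste(c(factors, block_terms), collapse = " + ")))
  trm <- stats::terms(fml, data = data)
  X <- stats::model.matrix(trm, data)
  n <- nrow(X)

  # drop aliased columns
  qrx <- qr(X)
  dropped <- character(0)
  if (qrx$rank < ncol(X)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- colnames(X)[-keep]
    message("dropping ", length(dropped), " aliased design column(s): ",
            paste(utils::head(dropped, 8), collapse = ", "),
            if (length(dropped) > 8) ", ..." else "")
    X <- X[, sort(keep), drop = FALSE]
  }
  p <- ncol(X)

  # IRLS for gamma with log link: working weights are identically 1
  beta <- qr.coef(qr(X), log(y))
  eta <- drop(X %*% beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(100L)) {
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    beta_new <- qr.coef(qr(X), z)
    eta_new <- drop(X %*% beta_new)
    delta <- max(abs(beta_new - beta)) / max(1, max(abs(beta)))
    beta <- beta_new
    eta <- eta_new
    if (delta < 1e-12) { converged <- TRUE; break }
  }
  if (!converged) stop("IRLS did not converge in 100 iterations")
  mu <- exp(eta)

  # ML dispersion: shape k = 1/alpha solves log k - digamma(k) + 1 + C = 0,
  # C = mean(log(y/mu) - y/mu)  (<= -1, equality iff y == mu everywhere)
  cbar <- mean(log(y / mu) - y / mu)
  if (cbar >= -1 + 1e-12) {
    k <- 1e8  # degenerate: essentially no dispersion
  } else {
    f <- function(logk) {
      k <- exp(logk)
      log(k) - digamma(k) + 1 + cbar
    }
    k <- exp(stats::uniroot(f, c(-30, 30), tol = 1e-12)$root)
  }
  alpha <- 1 / k
  log_lik <- sum(stats::dgamma(y, shape = k, rate = k / mu, log = TRUE))
  vc <- alpha * chol2inv(chol(crossprod(X)))
  dimnames(vc) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  k_params <- p + 1  # beta plus alpha
  aicc_val <- if (n > k_params + 1) {
    -2 * log_lik + 2 * k_params + 2 * k_params * (k_params + 1) /
      (n - k_params - 1)
  } else NA_real_

  structure(list(
    coefficients = beta, alpha = alpha, vcov = vc, fitted = mu,
    log_lik = log_lik, aicc = aicc_val, converged = converged,
    iterations = iter, dropped = dropped, n = n, p = p,
    response = response, factors = factors, blocking = blocking,
    block_terms = block_terms, terms = trm,
    xlevels = lapply(stats::setNames(nm = c(base_vars, block_terms)),
                     function(v) levels(data[[v]])),
    model_frame = data[, c(base_vars, block_terms), drop = FALSE]),
    class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat("Gamma log-link fit: ", x$response, " ~ ",
      paste(x$factors, collapse = " + "),
      if (length(x$block_terms)) paste0(" + blocking(", x$blocking, ")"),
      "\n  n = ", x$n, ", alpha = ", signif(x$alpha, 4),
      ", logLik = ", signif(x$log_lik, 6),
      ", AICc = ", signif(x$aicc, 6), "\n", sep = "")
  invisible(x)
}

#' @export
logLik.gamma_fit <- function(object, ...) {
  structure(object$log_lik, df = object$p + 1, class = "logLik")
}

#' @export
vcov.gamma_fit <- function(object, ...) object$vcov

#' @export
coef.gamma_fit <- function(object, ...) object$coefficients

#' Corrected Akaike information criterion
#'
#' `AICc = -2*logLik + 2k + 2k(k+1)/(n-k-1)` with `k` counting the regression
#' coefficients plus the gamma dispersion.
#'
#' @param fit A `gamma_fit`.
#' @return Scalar AICc.
#' @export
aicc <- function(fit) {
  stopifnot(inherits(fit, "gamma_fit"))
  k <- fit$p + 1
  if (fit$n <= k + 1) stop("AICc undefined: n <= k + 1")
  fit$aicc
}

# average model-matrix row for each level of `factor`, over the reference
# grid of observed combinations of the other model factors
emm_linfct <- function(fit, factor) {
  mf <- fit$model_frame
  others <- setdiff(names(mf), factor)
  grid <- if (length(others)) unique(mf[others]) else
    data.frame(matrix(nrow = 1, ncol = 0))
  levels_f <- fit$xlevels[[factor]]
  linfct <- matrix(NA_real_, length(levels_f),
                   length(fit$coefficients),
                   dimnames = list(levels_f, names(fit$coefficients)))
  for (l in levels_f) {
    nd <- grid
    nd[[factor]] <- base::factor(l, levels = levels_f)
    for (v in others) nd[[v]] <- base::factor(nd[[v]], levels = fit$xlevels[[v]])
    Xn <- stats::model.matrix(fit$terms, nd)
    Xn <- Xn[, names(fit$coefficients), drop = FALSE]
    linfct[l, ] <- colMeans(Xn)
  }
  linfct
}

#' Estimated marginal means of a model factor
#'
#' Level means of the linear predictor averaged over a reference grid: the
#' distinct observed combinations of the other model factors (including the
#' blocking dummies), equally weighted. Cells never observed in the data are
#' thereby dropped from the grid. Wald 95% intervals use the coefficient
#' covariance; response-scale values are obtained by exponentiation.
#'
#' @param fit A `gamma_fit`.
#' @param factor Name of one fixed factor in the fit.
#' @param level Confidence level (default 0.95).
#' @return Object of class `emm_result`: tibble `table` with `level, emmean,
#'   se, lower, upper, response, response_lower, response_upper` (link scale
#'   unless named `response*`), plus the `linfct` matrix used.
#' @export
estimated_marginal_means <- function(fit, factor, level = 0.95) {
  stopifnot(inherits(fit, "gamma_fit"))
  if (!factor %in% names(fit$xlevels)) {
    stop("'", factor, "' is not a factor of this fit")
  }
  linfct <- emm_linfct(fit, factor)
  est <- drop(linfct %*% fit$coefficients)
  se <- sqrt(rowSums((linfct %*% fit$vcov) * linfct))
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- unname(est)
  se <- unname(se)
  tab <- tibble(
    level = rownames(linfct), emmean = est, se = se,
    lower = est - z * se, upper = est + z * se,
    response = exp(est), response_lower = exp(est - z * se),
    response_upper = exp(est + z * se))
  structure(list(table = tab, factor = factor, linfct = linfct,
                 conf_level = level),
            class = "emm_result")
}

#' @export
print.emm_result <- function(x, ...) {
  cat("Estimated marginal means for '", x$factor, "' (link scale):\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Pairwise comparisons of estimated marginal means
#'
#' All level pairs of a factor: link-scale difference of marginal means, Wald
#' 95% CI, and Cohen's d — the difference divided by the population standard
#' deviation, taken as the model's residual SD on the link (log) scale,
#' `sigma_pop = sqrt(trigamma(1/alpha))` (the SD of `log x` for a gamma with
#' dispersion `alpha`). A pair is `flagged` when the effect-size CI excludes
#' zero. No multiplicity adjustment is applied to these CIs.
#'
#' @param emm An [estimated_marginal_means()] result.
#' @param fit The `gamma_fit` the EMMs came from.
#' @param sigma_pop Population SD used for Cohen's d; defaults to
#'   `sqrt(trigamma(1/alpha))`. Pluggable because the choice of SD is a
#'   reporting convention, not a model quantity.
#' @return Tibble: `level1, level2, difference, lower, upper, d, d_lower,
#'   d_upper, flagged`.
#' @export
pairwise_comparisons <- function(emm, fit, sigma_pop = NULL) {
  stopifnot(inherits(emm, "emm_result"), inherits(fit, "gamma_fit"))
  if (is.null(sigma_pop)) sigma_pop <- sqrt(trigamma(1 / fit$alpha))
  linfct <- emm$linfct
  lv <- rownames(linfct)
  if (length(lv) < 2) {
    return(tibble(level1 = character(0), level2 = character(0),
                  difference = numeric(0), lower = numeric(0),
                  upper = numeric(0), d = numeric(0), d_lower = numeric(0),
                  d_upper = numeric(0), flagged = logical(0)))
  }
  z <- stats::qnorm(1 - (1 - emm$conf_level) / 2)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  bind_rows(lapply(pairs, function(pr) {
    cvec <- linfct[pr[1], ] - linfct[pr[2], ]
    diff <- drop(cvec %*% fit$coefficients)
    se <- sqrt(drop(cvec %*% fit$vcov %*% cvec))
    lo <- diff - z * se
    hi <- diff + z * se
    tibble(level1 = pr[1], level2 = pr[2], difference = diff,
           lower = lo, upper = hi, d = diff / sigma_pop,
           d_lower = lo / sigma_pop, d_upper = hi / sigma_pop,
           flagged = lo > 0 | hi < 0)
  }))
}
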