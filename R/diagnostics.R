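# MCMC convergence diagnostics: split-chain potential scale reduction (R-hat)
# and autocorrelation-based effective sample size.

#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half and the classical between/within-variance ratio
#' is computed over the resulting 2m half-chains:
#' `R-hat = sqrt(((n-1)/n * W + B/n) / W)`. Chains with zero within-chain
#' variance everywhere return 1 by convention.
#'
#' @param x numeric matrix of draws, iterations x chains (>= 2 chains, >= 4
#'   draws each).
#' @return scalar R-hat.
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2L, nrow(x) >= 4L)
  n2 <- nrow(x) %/% 2L
  halves <- cbind(x[seq_len(n2), , drop = FALSE],
                  x[n2 + seq_len(n2), , drop = FALSE])
  w <- mean(apply(halves, 2L, stats::var))
  b <- n2 * stats::var(colMeans(halves))
  if (!is.finite(w) || w == 0) {
    # all chains constant: identical constants mix perfectly (1 by
    # convention); distinct constants have not mixed at all
    return(if (b > 0) Inf else 1)
  }
  sqrt(((n2 - 1) / n2 * w + b / n2) / w)
}

#' Effective sample size
#'
#' Autocorrelation-sum estimator over chains: within-chain autocovariances are
#' averaged, converted to autocorrelations against the pooled-variance
#' estimate, and summed over lag pairs until the paired sum turns negative
#' (initial positive sequence). The result is capped at the total number of
#' draws; a constant chain returns the total draw count by convention.
#'
#' @param x numeric matrix of draws, iterations x chains (a vector is treated
#'   as one chain).
#' @return scalar effective sample size.
#' @export
ess <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  stopifnot(n >= 4L)
  ch_var <- apply(x, 2L, stats::var)
  w <- mean(ch_var)
  if (!is.finite(w) || w == 0) return(as.numeric(n * m))
  b <- if (m > 1L) n * stats::var(colMeans(x)) else 0
  var_plus <- (n - 1) / n * w + b / n
  max_lag <- min(n - 1L, 1000L)
  acov <- matrix(0, max_lag + 1L, m)
  for (j in seq_len(m)) {
    a <- stats::acf(x[, j], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1L, 1L]
    acov[, j] <- a
  }
  rho <- 1 - (w - rowMeans(acov)) / var_plus
  # Geyer initial positive sequence on paired sums (rho[1] is lag 0)
  s <- 0
  t <- 1L
  prev_pair <- Inf
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev_pair)  # enforce monotone decrease
    s <- s + pair
    prev_pair <- pair
    t <- t + 2L
  }
  tau <- max(-1 + 2 * s, 1 / (n * m))
  min(n * m, n * m / tau)
}

#' Summarize posterior draws
#'
#' Pools retained draws across chains and reports, per parameter, the
#' posterior mean, SD, equal-tailed 95% credible interval (empirical 2.5% and
#' 97.5% percentiles), split R-hat and effective sample size.
#'
#' @param draws 3-d array, iterations x chains x parameters, with parameter
#'   dimnames.
#' @return data frame with columns `parameter`, `mean`, `sd`, `q2.5`, `q97.5`,
#'   `rhat`, `ess`.
#' @export
summarize_draws <- function(draws) {
  stopifnot(length(dim(draws)) == 3L, dim(draws)[1L] >= 100L)
  pn <- dimnames(draws)[[3L]]
  out <- data.frame(parameter = pn, mean = NA_real_, sd = NA_real_,
                    q2.5 = NA_real_, q97.5 = NA_real_, rhat = NA_real_,
                    ess = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_along(pn)) {
    mat <- draws[, , j, drop = TRUE]
    if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1L)
    pooled <- as.vector(mat)
    q <- stats::quantile(pooled, c(0.025, 0.975), names = FALSE)
    out$mean[j] <- mean(pooled)
    out$sd[j] <- stats::sd(pooled)
    out$q2.5[j] <- q[1L]
    out$q97.5[j] <- q[2L]
    out$rhat[j] <- rhat(mat)
    out$ess[j] <- ess(mat)
  }
  out
}
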