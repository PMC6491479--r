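# Hamiltonian Monte Carlo with dual-averaging step-size adaptation and
# diagonal mass-matrix estimation during warmup. The target is supplied as a
# single function returning the unconstrained log-density and its gradient.

#' Sampler configuration
#'
#' Four chains of 2000 iterations each, with the first half of each chain used
#' for adaptation (step size and diagonal mass matrix) and discarded, is the
#' default; 1000 draws per chain are retained.
#'
#' @param chains number of chains (>= 2).
#' @param iterations total iterations per chain.
#' @param warmup adaptation iterations discarded from the start of each chain
#'   (< `iterations`).
#' @param seed integer seed; chains derive independent deterministic streams.
#' @param leapfrog_steps maximum leapfrog steps per iteration (the realized
#'   number is jittered uniformly over the upper half of this range to avoid
#'   periodic trajectories).
#' @param target_accept dual-averaging target acceptance probability.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(chains = 4L, iterations = 2000L, warmup = 1000L,
                           seed = 1L, leapfrog_steps = 16L,
                           target_accept = 0.8) {
  stopifnot(chains >= 2L, warmup >= 20L, warmup < iterations,
            leapfrog_steps >= 2L, target_accept > 0, target_accept < 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 leapfrog_steps = as.integer(leapfrog_steps),
                 target_accept = target_accept),
            class = "sampler_config")
}

# one HMC chain; fn(u) must return list(lp=, grad=)
hmc_chain <- function(fn, init, cfg, chain_seed) {
  set.seed(chain_seed)
  d <- length(init)
  n_iter <- cfg$iterations; warmup <- cfg$warmup
  keep <- n_iter - warmup
  draws <- matrix(NA_real_, keep, d)
  minv <- rep(1, d)           # inverse mass (posterior variance estimates)
  sqrt_mass <- rep(1, d)      # sd of momentum = sqrt(1/minv)

  cur <- fn(init)
  if (!is.finite(cur$lp)) stop("non-finite log-posterior at initialization")
  u <- init

  # dual averaging state (Hoffman & Gelman 2014 defaults)
  eps <- 0.1 / d^0.25
  da_mu <- log(10 * eps); log_eps_bar <- 0; h_bar <- 0
  gamma0 <- 0.05; t0 <- 10; kappa <- 0.75; da_count <- 0
  da_reset <- function() {
    da_mu <<- log(10 * eps); log_eps_bar <<- log(eps)
    h_bar <<- 0; da_count <<- 0
  }
  w_collect_from <- max(2L, floor(warmup * 0.35))
  w_mass_at <- floor(warmup * 0.8)
  coll <- matrix(NA_real_, max(0L, w_mass_at - w_collect_from), d)
  divergences <- 0L          # post-warmup only
  warmup_divergences <- 0L

  L_max <- cfg$leapfrog_steps
  L_min <- max(1L, L_max %/% 2L)

  for (it in seq_len(n_iter)) {
    p <- stats::rnorm(d) * sqrt_mass
    H0 <- -cur$lp + 0.5 * sum(minv * p^2)
    L <- if (L_max > L_min) sample(L_min:L_max, 1L) else L_max
    up <- u; st <- cur
    # leapfrog
    pp <- p + 0.5 * eps * st$grad
    diverged <- FALSE
    for (l in seq_len(L)) {
      up <- up + eps * (minv * pp)
      st2 <- fn(up)
      if (!all(is.finite(st2$grad)) || !is.finite(st2$lp)) {
        diverged <- TRUE; break
      }
      st <- st2
      pp <- pp + (if (l < L) eps else 0.5 * eps) * st$grad
    }
    if (!diverged) {
      H1 <- -st$lp + 0.5 * sum(minv * pp^2)
      dH <- H0 - H1
      diverged <- !is.finite(dH) || dH < -1000
    }
    if (diverged) {
      accept_prob <- 0
      if (it > warmup) divergences <- divergences + 1L
      else warmup_divergences <- warmup_divergences + 1L
    } else {
      accept_prob <- min(1, exp(min(0, dH)))
      if (stats::runif(1) < accept_prob) { u <- up; cur <- st }
    }

    if (it <= warmup) {
      # dual averaging of the step size
      da_count <- da_count + 1
      h_bar <- (1 - 1 / (da_count + t0)) * h_bar +
        (cfg$target_accept - accept_prob) / (da_count + t0)
      log_eps <- da_mu - sqrt(da_count) / gamma0 * h_bar
      w <- da_count^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      if (it > w_collect_from && it <= w_mass_at)
        coll[it - w_collect_from, ] <- u
      if (it == w_mass_at && nrow(coll) >= 10L) {
        v <- apply(coll, 2L, stats::var)
        n_c <- nrow(coll)
        minv <- pmax(v * n_c / (n_c + 5) + 1e-3 * 5 / (n_c + 5), 1e-8)
        sqrt_mass <- 1 / sqrt(minv)
        eps <- exp(log_eps_bar)
        da_reset()
      }
      if (it == warmup) eps <- exp(log_eps_bar)
    } else {
      draws[it - warmup, ] <- u
    }
  }
  list(draws = draws, divergences = divergences,
       warmup_divergences = warmup_divergences, step_size = eps,
       inv_mass = minv)
}

# run all chains; init_fn(chain) -> unconstrained init vector
hmc_run <- function(fn, init_fn, cfg) {
  set.seed(cfg$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, cfg$chains)
  out <- vector("list", cfg$chains)
  for (ch in seq_len(cfg$chains)) {
    init <- NULL
    set.seed(chain_seeds[ch])
    for (try in 1:10) {
      cand <- init_fn(ch)
      if (is.finite(fn(cand)$lp)) { init <- cand; break }
    }
    if (is.null(init))
      stop("non-finite log-posterior at initialization after 10 retries")
    out[[ch]] <- hmc_chain(fn, init, cfg, chain_seeds[ch])
  }
  out
}
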