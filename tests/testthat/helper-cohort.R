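# Small in-code fixtures shared across test files.

# a tiny three-group cohort with hand-set values; panel restricted to k
# metabolites for speed
tiny_cohort <- function(n_per_group = 4, k = 2, seed = 100) {
  panel <- default_panel()[seq_len(k), , drop = FALSE]
  class(panel) <- c("metabolite_panel", "data.frame")
  set.seed(seed)
  eth <- rep(c("european", "ghanaian", "african_surinamese"), each = n_per_group)
  n <- length(eth)
  participants <- data.frame(
    id = sprintf("p%02d", seq_len(n)),
    ethnicity = eth,
    sex = rep_len(c("male", "female"), n),
    age_years = round(runif(n, 40, 70), 1),
    bmi = round(runif(n, 24, 36), 1),
    fasting_glucose_mmol_l = round(runif(n, 5.1, 9), 2),
    hba1c_mmol_mol = round(runif(n, 35, 70), 1),
    glycemic_status = rep_len(c("prediabetic", "diabetic"), n),
    stringsAsFactors = FALSE)
  conc <- matrix(round(exp(rnorm(n * k, 4, 0.4)), 3), n, k,
                 dimnames = list(NULL, panel$name))
  status <- matrix("observed", n, k, dimnames = list(NULL, panel$name))
  cohort(participants, conc, status, panel)
}

# simulation config scaled down for fast fits; full missingness machinery on
small_sim_config <- function(seed = 1, k = 1, n_eur = 70, n_gha = 70,
                             n_sur = 60, ...) {
  panel <- default_panel()[seq_len(k), , drop = FALSE]
  class(panel) <- c("metabolite_panel", "data.frame")
  sim_config(group_sizes = c(european = n_eur, ghanaian = n_gha,
                             african_surinamese = n_sur),
             panel = panel, seed = seed, ...)
}

fast_sampler <- function(seed = 1, iterations = 600, warmup = 300)
  sampler_config(chains = 4, iterations = iterations, warmup = warmup,
                 seed = seed)

# deterministic cohort with exact group sizes and diabetic counts
counts_cohort <- function(sizes = c(european = 301, ghanaian = 255,
                                    african_surinamese = 217),
                          diabetic = c(european = 38, ghanaian = 99,
                                       african_surinamese = 153),
                          female = NULL) {
  panel <- default_panel()[1, ]
  rows <- lapply(names(sizes), function(e) {
    n <- sizes[[e]]
    d <- diabetic[[e]]
    nf <- if (is.null(female)) floor(n / 2) else female[[e]]
    data.frame(id = paste0(substr(e, 1, 3), seq_len(n)), ethnicity = e,
               sex = rep(c("female", "male"), c(nf, n - nf)),
               age_years = seq(40, 70, length.out = n),
               bmi = seq(25, 35, length.out = n),
               fasting_glucose_mmol_l = 6,
               hba1c_mmol_mol = seq(38, 70, length.out = n),
               glycemic_status = rep(c("diabetic", "prediabetic"), c(d, n - d)),
               stringsAsFactors = FALSE)
  })
  participants <- do.call(rbind, rows)
  n <- nrow(participants)
  conc <- matrix(10, n, 1, dimnames = list(NULL, panel$name))
  status <- matrix("observed", n, 1, dimnames = list(NULL, panel$name))
  cohort(participants, conc, status, panel)
}
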