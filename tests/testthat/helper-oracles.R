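# Independent oracles and small fixture builders used across tests.
# These deliberately re-derive quantities through different code paths than
# the package (explicit per-time risk tables, raw-polynomial regression,
# reverse-loop step-up) so agreement is evidence, not tautology.

# Brute-force two-group log-rank: walk the distinct event times and build
# each 2x2 risk table by explicit subsetting.
bruteforce_logrank <- function(time, event, high) {
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & high)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & high)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * ((n - n1) / n) * (n - d) / (n - 1)
  }
  list(O1 = O1, E1 = E1, V = V, chi2 = if (V > 0) (O1 - E1)^2 / V else 0)
}

# Independent Storey q-value implementation: raw cubic regression for pi0,
# explicit reverse loop for the step-up enforcement.
oracle_qvalues <- function(p) {
  m <- length(p)
  lam <- seq(0.05, 0.90, by = 0.05)
  pi0l <- vapply(lam, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  fit <- stats::lm(pi0l ~ lam + I(lam^2) + I(lam^3))
  b <- stats::coef(fit)
  b[is.na(b)] <- 0
  pi0 <- sum(b * c(1, 0.9, 0.9^2, 0.9^3))
  pi0 <- min(max(pi0, .Machine$double.eps), 1)
  ord <- order(p)
  ps <- p[ord]
  q <- pmin(pi0 * m * ps / seq_len(m), 1)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[ord] <- q
  out
}

# Random small right-censored two-group instance (possibly with heavy ties).
random_survival_instance <- function(n_max = 30) {
  n <- sample(5:n_max, 1)
  list(time = sample(1:12, n, replace = TRUE),
       event = stats::rbinom(n, 1, 0.7),
       group = stats::rbinom(n, 1, 0.5))
}

# Survival table from bare vectors, ids "s1".."sn".
make_survival <- function(time, event) {
  data.frame(sample_id = paste0("s", seq_along(time)),
             time_months = time, event = as.integer(event),
             stringsAsFactors = FALSE)
}

# Null cohort (no feature-survival link): exponential events, light
# truncated-exponential censoring.
null_cohort_vectors <- function(n, baseline = 0.02, cens = 0.008, admin = 120) {
  t_ev <- stats::rexp(n, baseline)
  c_t <- pmin(stats::rexp(n, cens), admin)
  list(time = pmin(t_ev, c_t), event = as.integer(t_ev <= c_t))
}

# Write a tiny expression TSV from a character row list.
write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
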