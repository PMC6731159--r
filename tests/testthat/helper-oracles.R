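# Independent brute-force oracles.  Deliberately coded scalar-first and
# term-by-term, sharing no code with the package's vectorised
# implementations, so agreement is a genuine dual-route check.

oracle_ihc4 <- function(er, pr, ki67, her2, ki67_percent = TRUE) {
  k <- if (ki67_percent) ki67 else ki67 / 100
  er_term <- -0.100 * (er / 10)
  pr_term <- -0.079 * (pr / 10)
  her2_term <- 0.586 * her2
  ki67_term <- 0.240 * log(1 + 10 * k)
  94.7 * (er_term + pr_term + her2_term + ki67_term)
}

oracle_c_score <- function(age, size_mm, grade, nodes, whole_bracket = FALSE) {
  node_term <- if (nodes == 0) 0 else if (nodes <= 3) 0.417 else 1.566
  cm <- size_mm / 10
  t12 <- if (cm > 1 && cm <= 2) 1 else 0
  t23 <- if (cm > 2 && cm <= 3) 1 else 0
  tgt3 <- if (cm > 3) 1 else 0
  rest <- 0.882 * t23 + 1.838 * tgt3 +
    c(0, 0.559, 0.970)[grade] +
    (if (age >= 65) 0.130 else 0) +
    0.149 * 0
  inner <- if (whole_bracket) 0.930 * (0.497 * t12 + rest)
           else 0.930 * (0.497 * t12) + rest
  100 * (node_term + inner)
}

oracle_predict <- function(age, size_mm, grade, nodes) {
  d <- age / 10
  term_age1 <- 34.53 * d^(-2) - 0.0287
  term_age2 <- -34.20 * d^(-2) * log(d) - 0.0510
  term_size <- 0.7531 * log(size_mm / 100) + 1.5452
  term_nodes <- 0.7069 * log((nodes + 1) / 10) + 1.3876
  term_age1 + term_age2 + term_size + term_nodes + 0.7467 * grade
}

# Exact Efron log partial likelihood for a single covariate, summed over
# distinct event times; maximised by golden-section search.
oracle_efron_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    ll <- ll + beta * sum(x[D])
    sum_risk <- sum(exp(beta * x[R]))
    sum_tied <- sum(exp(beta * x[D]))
    for (j in seq_len(d) - 1L) {
      ll <- ll - log(sum_risk - (j / d) * sum_tied)
    }
  }
  ll
}

oracle_efron_mle <- function(time, status, x, interval = c(-15, 15)) {
  stats::optimize(function(b) oracle_efron_loglik(b, time, status, x),
                  interval = interval, maximum = TRUE, tol = 1e-10)$maximum
}

# Random valid inputs for the formula-equivalence checks
random_ihc4_inputs <- function(n, seed) {
  withr::with_seed(seed, data.frame(
    er = runif(n, 0, 100), pr = runif(n, 0, 100),
    ki67 = runif(n, 0, 100), her2 = runif(n, 0, 3)))
}

random_clinical_inputs <- function(n, seed) {
  withr::with_seed(seed, data.frame(
    age = runif(n, 20, 90), size = runif(n, 1, 80),
    grade = sample(1:3, n, replace = TRUE),
    nodes = rpois(n, 1.2)))
}

# Small survival fixture used across Cox tests
six_patient_fixture <- function() {
  data.frame(time_years = c(1, 2, 3, 4, 5, 6),
             event = c(1, 1, 1, 1, 0, 0),
             x = c(0, 0, 1, 1, 0, 1))  # group A = 0, B = 1
}
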