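# Independent oracles, deliberately written differently from the package
# implementations they check.

# Exhaustive pair-enumeration concordance: loops over every (i, j) pair and
# applies the comparability and crediting rules directly.
brute_force_c <- function(predictor, time, event) {
  n <- length(predictor)
  num <- den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      s <- if (time[i] < time[j]) i else j
      l <- if (s == i) j else i
      if (!event[s]) next
      den <- den + 1
      if (predictor[s] > predictor[l]) num <- num + 1
      else if (predictor[s] == predictor[l]) num <- num + 0.5
    }
  }
  list(c = if (den > 0) num / den else NA_real_, comparable = den)
}

# Random censored survival instances for concordance property tests
random_records <- function(n, tie_prob = 0.3) {
  pred <- if (runif(1) < tie_prob) sample(1:4, n, replace = TRUE)
          else rnorm(n)
  time <- if (runif(1) < tie_prob) sample(1:5, n, replace = TRUE)
          else rexp(n) + 0.01
  event <- runif(n) < 0.6
  if (!any(event)) event[sample.int(n, 1)] <- TRUE
  survival_records(pred, time, event)
}
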