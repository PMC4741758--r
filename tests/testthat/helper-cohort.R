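# Small in-code fixtures shared across test files.

# gene x sample matrix with named dims
make_expr <- function(values, genes, samples) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  as_expression_matrix(m)
}

# minimal clinical table
make_clin <- function(sample_id, os_time, event,
                      age = rep(60, length(sample_id)),
                      gender = rep("male", length(sample_id)),
                      stage = rep("I", length(sample_id))) {
  data.frame(sample_id = sample_id, os_time = os_time,
             event = as.integer(event), age = age, gender = gender,
             stage = stage, stringsAsFactors = FALSE)
}

# a small simulated cohort reused by several files (cheap to build)
small_sim <- function(seed = 11, n_samples = 120, n_genes = 200,
                      immune_block_size = 40, prognostic_immune_count = 8,
                      ...) {
  simulate_cohort(sim_config(n_samples = n_samples, n_genes = n_genes,
                             immune_block_size = immune_block_size,
                             prognostic_immune_count = prognostic_immune_count,
                             seed = seed, ...))
}

# independent Pearson correlation oracle (textbook sum formula)
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# independent log-rank statistic oracle: loop over distinct event times,
# accumulate observed - expected and hypergeometric variance for group 1
logrank_oracle <- function(time, event, group) {
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
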