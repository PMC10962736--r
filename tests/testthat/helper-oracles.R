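# Independent oracles and tiny fixture builders used across the suite.

# Pooled-variance t test, written directly from the textbook formulas and
# independent of the package implementation.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

# Classic BH step-up q values, computed by explicit sort / cummin.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(pmin(m * p[o] / seq_len(m), 1))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Classic BH rejection set at level alpha (largest k with p_(k) <= k*alpha/m).
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  k <- which(p[o] <= seq_len(m) * alpha / m)
  rejected <- logical(m)
  if (length(k)) rejected[o[seq_len(max(k))]] <- TRUE
  rejected
}

# Three-arm, one-model expression fixture from a compact plan table.
make_fixture <- function(beta, dep, noise_sd = 0.1, n_per_arm = 4, seed = 1,
                         noiseless = FALSE, model = "m1") {
  plans <- data.frame(model = model,
                      gene_id = sprintf("g%03d", seq_along(beta)),
                      baseline = 8, beta = beta, dependence_pct = dep,
                      noise_sd = noise_sd, stringsAsFactors = FALSE)
  generate_expression_fixture(
    fixture_spec(plans, n_per_arm = n_per_arm, seed = seed,
                 noiseless = noiseless))
}

# Stress and KO contrasts plus dependence table for a one-model fixture.
run_model <- function(fx, model = "m1", ...) {
  stress <- run_contrast(fx$matrix, arm_samples(fx$samples, model, "stress_wt"),
                         arm_samples(fx$samples, model, "control"), ...)
  ko <- run_contrast(fx$matrix, arm_samples(fx$samples, model, "stress_ko"),
                     arm_samples(fx$samples, model, "stress_wt"), ...)
  list(stress = stress, ko = ko,
       dep = classify_dependent(stress, ko, model = model))
}

# Full three-model heart pipeline used by several tests.
run_heart <- function(spec) {
  fx <- generate_expression_fixture(spec)
  models <- unique(fx$samples$model)
  stress <- list(); ko <- list(); dep <- list()
  for (m in models) {
    r <- run_model(fx, m)
    stress[[m]] <- r$stress; ko[[m]] <- r$ko; dep[[m]] <- r$dep
  }
  list(fx = fx, stress = stress, ko = ko, dep = dep)
}
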