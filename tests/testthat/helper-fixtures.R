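# shared fixture builders (everything generated in code; no stored data)

# two planted blocks of binary variables, each a noisy copy of an
# independent fair-coin parent
planted_two_blocks <- function(n = 2000, flip = 0.05, seed = 42) {
  set.seed(seed)
  parent <- matrix(stats::rbinom(2 * n, 1, 0.5), n, 2)
  X <- sapply(1:10, function(j) {
    p <- parent[, ifelse(j <= 5, 1, 2)]
    ifelse(stats::runif(n) < flip, 1 - p, p)
  })
  colnames(X) <- paste0("v", 1:10)
  list(x = X, truth = rep(1:2, each = 5))
}

# cohort used by the structure-recovery checks: 8 plasma blocks of 5
recovery_cohort <- function(seed) {
  generate_cohort(cohort_spec(
    n_subjects = 800, n_plasma_blocks = 8, block_sizes = rep(5L, 8),
    block_loading = 0.8, n_noise_analytes = 0, n_roi_pairs = 2, seed = seed))
}

cohort_composite <- function(co) {
  cognitive_composite(
    mmse = data.frame(baseline = co$outcomes$mmse_baseline,
                      followup = co$outcomes$mmse_followup),
    adas13 = data.frame(baseline = co$outcomes$adas13_baseline,
                        followup = co$outcomes$adas13_followup),
    cdr_sob = data.frame(baseline = co$outcomes$cdr_sob_baseline,
                         followup = co$outcomes$cdr_sob_followup))
}

# hand-built single-factor layer with controllable posterior, for testing
# the labelling rules in isolation
toy_layer <- function(p0_given_x0 = 0.9) {
  lr <- log(p0_given_x0 / 0.5)
  structure(list(
    alpha = matrix(1, 1, 1, dimnames = list("a", "F00")),
    mi = matrix(0.5, 1, 1),
    labels = NULL, posterior = NULL,
    explained_tc = 0.5, tc_history = NULL,
    assignment = c(a = 1L),
    p_y = matrix(0.5, 1, 2),
    model = list(
      log_py = matrix(log(0.5), 1, 2),
      p_y = matrix(0.5, 1, 2),
      log_pxgy = list(
        list(matrix(log(p0_given_x0), 1, 1), matrix(log(1 - p0_given_x0), 1, 1)),
        list(matrix(log(1 - p0_given_x0), 1, 1), matrix(log(p0_given_x0), 1, 1))),
      log_px = list(matrix(log(0.5), 1, 1), matrix(log(0.5), 1, 1)),
      mi = matrix(0.5, 1, 1)),
    converged = TRUE,
    config = list(n_factors = 1L, cardinality = 2L, seed = 1L),
    n_levels = 2L,
    variables = "a"), class = "corex_layer")
}
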