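# Shared fixtures, built once per test run.

# Small default-world dataset for clustering / preprocessing / stats tests
# (full-size recovery is exercised in test-acceptance.R).
small_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) ds <<- make_synthetic_dataset(n_neurons = 60, n_reps = 8,
                                                   seed = 7)
    ds
  }
})

small_preprocessed <- local({
  pp <- NULL
  function() {
    if (is.null(pp)) pp <<- preprocess_traces(small_dataset()$traces)
    pp
  }
})

small_profiles <- local({
  X <- NULL
  function() {
    if (is.null(X)) {
      ds <- small_dataset()
      pp <- small_preprocessed()
      rp <- epoch_and_average(pp$r, ds$trials, frame_rate = pp$frame_rate)
      X <<- profiles_matrix(rp)
    }
    X
  }
})

# Independent brute-force oracle for the rate-model trajectories: a literal
# re-statement of the update equation, shared by unit and acceptance tests.
brute_force_rates <- function(spec, inputs, context) {
  f1 <- function(x, nl) {
    if (x <= nl$theta) {
      max(0, nl$offset + nl$k_lo * x)
    } else {
      max(0, nl$offset + nl$k_lo * nl$theta) + nl$k_hi * (x - nl$theta)
    }
  }
  r <- baseline_fixed_point(spec, context)
  np <- length(spec$populations)
  out <- matrix(0, np, length(inputs$t))
  for (ti in seq_along(inputs$t)) {
    new <- numeric(np)
    for (i in seq_len(np)) {
      x <- spec$b[[context]][i] +
        spec$g_auditory[i] * inputs$s_auditory[ti] +
        spec$g_visual[i] * inputs$s_visual[ti] +
        sum(spec$G[i, ] * r)
      new[i] <- f1(x, spec$nonlin[[i]])
    }
    r <- new
    out[, ti] <- r
  }
  rownames(out) <- spec$populations
  out
}

random_stable_spec <- function(seed) {
  set.seed(seed)
  pops <- c("I", "E")
  nl <- lapply(pops, function(p) {
    k_lo <- runif(1, 0, 0.5)
    list(theta = runif(1, 0.5, 2), k_lo = k_lo,
         k_hi = k_lo + runif(1, 0, 1), offset = runif(1, 0, 0.5))
  })
  names(nl) <- pops
  rate_model_spec(
    populations = pops,
    b = list(dark = stats::setNames(runif(2, -0.5, 0.5), pops),
             light = stats::setNames(runif(2, -0.5, 0.5), pops)),
    g_auditory = stats::setNames(runif(2, 0, 1), pops),
    g_visual = stats::setNames(runif(2, -1, 1), pops),
    G = matrix(runif(4, -0.4, 0.2), 2), nonlin = nl)
}
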