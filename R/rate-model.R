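# Minimal threshold-linear rate network: an inhibitory population (putative
# L1 interneurons) and an excitatory population (L2/3 pyramidal cells), both
# with two-segment nonlinearities, driven by an exponentially decaying
# auditory input and a plateauing visual input. Context (dark/light) enters
# only through the per-population baseline. With the shipped defaults the
# excitatory sound response is negative in the dark and positive in the
# light, and bimodal responses are boosted supra-linearly for the preferred
# visual stimulus only.

#' Two-segment threshold-linear response function
#'
#' `f(x) = max(0, offset + k_lo * x)` for `x <= theta` and
#' `f(theta) + k_hi * (x - theta)` above, continuous at the threshold. The
#' sub-threshold segment is not constant zero: background inputs are
#' stochastic and can drive firing below the mean threshold.
#'
#' @param x input (any shape).
#' @param theta threshold.
#' @param k_lo,k_hi sub-/supra-threshold gains, `k_hi >= k_lo >= 0`.
#' @param offset sub-threshold intercept.
#' @return non-negative rates, same shape as `x`.
#' @export
f_piecewise <- function(x, theta, k_lo, k_hi, offset = 0) {
  stopifnot(is.finite(theta), is.finite(k_lo), is.finite(k_hi),
            is.finite(offset))
  f_theta <- max(0, offset + k_lo * theta)
  ifelse(x <= theta, pmax(0, offset + k_lo * x), f_theta + k_hi * (x - theta))
}

#' Construct a rate-model specification
#'
#' @param populations character vector of population names (>= 1; the
#'   excitatory readout population must be named "E").
#' @param b named list/matrix of baselines: `b[[context]][pop]`.
#' @param g_auditory,g_visual named numeric vectors of input gains per
#'   population.
#' @param G recurrent gain matrix, `G[i, j]` = weight from population j onto
#'   population i (zero diagonal unless deliberately configured).
#' @param nonlin named list per population: `theta`, `k_lo`, `k_hi`,
#'   `offset` (see [f_piecewise()]).
#' @param dt simulation time step (s).
#' @param tau_auditory decay constant of the auditory input transient (s).
#' @return object of class `RateModelSpec`.
#' @export
rate_model_spec <- function(populations, b, g_auditory, g_visual, G, nonlin,
                            dt = 0.01, tau_auditory = 0.3) {
  np <- length(populations)
  G <- matrix(as.numeric(G), np, np, dimnames = list(populations, populations))
  for (p in populations) {
    nl <- nonlin[[p]]
    if (!(nl$k_hi >= nl$k_lo && nl$k_lo >= 0)) {
      xmv1_stop(sprintf("population %s: need k_hi >= k_lo >= 0", p),
                "xmv1_bad_argument")
    }
  }
  structure(list(populations = populations, b = b,
                 g_auditory = g_auditory[populations],
                 g_visual = g_visual[populations], G = G,
                 nonlin = nonlin[populations], dt = dt,
                 tau_auditory = tau_auditory),
            class = "RateModelSpec")
}

#' Default two-population specification
#'
#' Loads the shipped YAML (`inst/extdata/rate_model_default.yaml`). The
#' parameter values are chosen to reproduce the qualitative signatures
#' (sign switch and preferred-stimulus boosting) and are NOT fitted to data:
#' the inhibitory population sits at its threshold in the dark and well
#' below it in the light; the excitatory population crosses its high-gain
#' threshold only with preferred visual drive.
#'
#' @param path optional path to an alternative YAML spec.
#' @return `RateModelSpec`.
#' @export
default_rate_model_spec <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rate_model_default.yaml", package = "xmv1")
  }
  y <- yaml::read_yaml(path)
  pops <- y$populations
  b <- lapply(y$b, function(v) unlist(v)[pops])
  rate_model_spec(
    populations = pops, b = b,
    g_auditory = unlist(y$g_auditory), g_visual = unlist(y$g_visual),
    G = do.call(rbind, lapply(pops, function(i) unlist(y$G[[i]])[pops])),
    nonlin = y$nonlin, dt = y$dt, tau_auditory = y$tau_auditory)
}

#' Stimulus input time series
#'
#' Auditory drive: exponentially decaying transient from sound onset
#' (`exp(-(t - onset)/tau_auditory)` during the stimulus, zero outside).
#' Visual drive: plateau (unit step scaled by `visual_level`) during the
#' stimulus.
#'
#' @param spec `RateModelSpec` (provides `dt`, `tau_auditory`).
#' @param t_total simulated duration (s).
#' @param onset,duration stimulus onset and duration (s).
#' @param auditory_level,visual_level input amplitudes (0 = input absent).
#' @return list of class `StimulusInputs`: `s_auditory`, `s_visual`, `t`,
#'   `dt`, `stim_idx` (indices of the stimulation period).
#' @export
stimulus_inputs <- function(spec, t_total = 4, onset = 0.5, duration = 2,
                            auditory_level = 1, visual_level = 0) {
  t <- seq(0, t_total, by = spec$dt)
  during <- t >= onset & t <= onset + duration
  s_aud <- numeric(length(t))
  s_aud[during] <- auditory_level * exp(-(t[during] - onset) / spec$tau_auditory)
  s_vis <- numeric(length(t))
  s_vis[during] <- visual_level
  structure(list(s_auditory = s_aud, s_visual = s_vis, t = t, dt = spec$dt,
                 stim_idx = which(during)),
            class = "StimulusInputs")
}

apply_nonlin <- function(spec, x) {
  vapply(seq_along(spec$populations), function(i) {
    nl <- spec$nonlin[[i]]
    f_piecewise(x[i], nl$theta, nl$k_lo, nl$k_hi, nl$offset)
  }, numeric(1))
}

#' Baseline fixed point of the no-stimulus dynamics
#'
#' Damped iteration `r <- (1 - eta) r + eta f(b + G r)` to tolerance 1e-12;
#' non-convergence (e.g. an oscillatory regime) is an error with diagnostics.
#'
#' @param spec `RateModelSpec`.
#' @param context "dark" or "light".
#' @param eta damping factor.
#' @param tol,max_iter convergence controls.
#' @return named rate vector at the fixed point.
#' @export
baseline_fixed_point <- function(spec, context, eta = 0.5, tol = 1e-12,
                                 max_iter = 1e4) {
  b <- spec$b[[context]]
  if (is.null(b)) xmv1_stop(paste0("unknown context: ", context),
                            "xmv1_bad_argument")
  r <- pmax(0, apply_nonlin(spec, b))
  delta <- Inf
  for (it in seq_len(max_iter)) {
    r_new <- (1 - eta) * r + eta * apply_nonlin(spec, b + spec$G %*% r)
    delta <- max(abs(r_new - r))
    if (!is.finite(delta)) break  # runaway dynamics
    if (delta < tol) {
      names(r_new) <- spec$populations
      return(r_new)
    }
    r <- r_new
  }
  xmv1_stop(sprintf("baseline fixed point did not converge (context %s, last delta %.3g)",
                    context, delta), "xmv1_fixed_point")
}

#' Simulate the rate network
#'
#' Synchronous update with a one-step recurrent delay:
#' `r_i(t) = f_i(b_i + g_aud_i s_aud(t) + g_vis_i s_vis(t) + sum_j G_ij r_j(t-1))`,
#' started at the no-stimulus baseline fixed point.
#'
#' @param spec `RateModelSpec`.
#' @param inputs `StimulusInputs`.
#' @param context "dark" or "light".
#' @return list: `rates` (population x time), `baseline` (fixed point),
#'   `response` (baseline-subtracted rates), `t`.
#' @export
simulate_rate_model <- function(spec, inputs, context) {
  r0 <- baseline_fixed_point(spec, context)
  b <- spec$b[[context]]
  n_t <- length(inputs$t)
  np <- length(spec$populations)
  rates <- matrix(0, np, n_t, dimnames = list(spec$populations, NULL))
  prev <- r0
  for (ti in seq_len(n_t)) {
    x <- b + spec$g_auditory * inputs$s_auditory[ti] +
      spec$g_visual * inputs$s_visual[ti] + as.numeric(spec$G %*% prev)
    prev <- apply_nonlin(spec, x)
    rates[, ti] <- prev
  }
  list(rates = rates, baseline = r0, response = rates - r0, t = inputs$t)
}

#' Context experiment: sound-alone response in dark vs light
#'
#' Simulates the sound-alone condition in both contexts and returns the
#' signed mean baseline-subtracted response of the excitatory population
#' over the stimulation window. With the default parameters the dark
#' response is negative and the light response positive.
#'
#' @param spec `RateModelSpec`.
#' @param inputs optional `StimulusInputs` (default: standard sound alone).
#' @param population readout population (default "E").
#' @return named numeric: mean response per context; attribute `traces`
#'   holds the full simulations.
#' @export
context_experiment <- function(spec, inputs = NULL, population = "E") {
  if (is.null(inputs)) inputs <- stimulus_inputs(spec)
  sims <- lapply(c(dark = "dark", light = "light"), function(ctx) {
    simulate_rate_model(spec, inputs, ctx)
  })
  out <- vapply(sims, function(s) {
    mean(s$response[population, inputs$stim_idx])
  }, numeric(1))
  attr(out, "traces") <- sims
  out
}

#' Bimodal experiment: boosting of visual responses by sound
#'
#' For each visual drive level, computes
#' `boost = response(bimodal) - response(visual alone) - response(auditory alone)`
#' in the light context (mean baseline-subtracted excitatory response over
#' the stimulation window). With the defaults: zero boost without visual
#' drive, near-zero for the sub-threshold (non-preferred) drive, and strong
#' supra-linear boost for the preferred drive — the auditory input sums with
#' the high gain only when the visual drive puts the excitatory population
#' near/above its threshold.
#'
#' @param spec `RateModelSpec`.
#' @param visual_levels named numeric vector of visual drive amplitudes
#'   (default `c(none = 0, nonpreferred = 0.35, preferred = 1)`).
#' @param context context for the bimodal condition (default "light").
#' @param population readout population.
#' @return data.frame: level, visual_drive, response_visual,
#'   response_auditory, response_bimodal, boost.
#' @export
bimodal_experiment <- function(spec,
                               visual_levels = c(none = 0, nonpreferred = 0.35,
                                                 preferred = 1),
                               context = "light", population = "E") {
  resp <- function(aud, vis) {
    inputs <- stimulus_inputs(spec, auditory_level = aud, visual_level = vis)
    s <- simulate_rate_model(spec, inputs, context)
    mean(s$response[population, inputs$stim_idx])
  }
  r_aud <- resp(1, 0)
  out <- do.call(rbind, lapply(names(visual_levels), function(lv) {
    v <- visual_levels[[lv]]
    r_vis <- resp(0, v)
    r_bi <- resp(1, v)
    data.frame(level = lv, visual_drive = v, response_visual = r_vis,
               response_auditory = r_aud, response_bimodal = r_bi,
               boost = r_bi - r_vis - r_aud, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Make every nonlinearity affine (control condition)
#'
#' Sets `k_hi = k_lo` and shifts offsets up so that no rate clips at zero in
#' the standard experiments; with all transfer functions affine the network
#' is linear and bimodal boosting vanishes exactly.
#'
#' @param spec `RateModelSpec`.
#' @param offset common large intercept (default 20).
#' @return modified spec.
#' @export
make_affine <- function(spec, offset = 20) {
  for (p in spec$populations) {
    nl <- spec$nonlin[[p]]
    nl$k_hi <- nl$k_lo
    nl$offset <- offset
    spec$nonlin[[p]] <- nl
  }
  spec
}
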