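# Downstream-neuron model: a single-compartment Izhikevich neuron driven by
# a population of instantaneous excitatory or inhibitory synaptic inputs
# whose timings are jittered by a Gaussian of SD sigma.
#
#   dv/dt = 0.04 v^2 + 5 v + 140 - u + I(t)
#   du/dt = a (b v - u)
#
# integrated with the model's original modified Euler scheme: v advances in
# two half-steps of dt/2 per single u update. When v reaches the cap
# (30 mV) the trace records the cap, then v <- c and u <- u + d. Each input
# is an instantaneous (delta) current: its time-integral is delivered as a
# fixed membrane-potential jump at the binned input time, which makes the
# injected drive exactly invariant to the step size.

#' Izhikevich neuron parameters
#'
#' Defaults are the canonical regular-spiking set. `v0` defaults to the
#' resting fixed point of the (v, u) system and `u0` to `b * v0`.
#'
#' @param a recovery rate (1/ms scale, default 0.02).
#' @param b recovery coupling (default 0.2).
#' @param c reset potential in mV (default -65).
#' @param d recovery increment at spike (default 8).
#' @param v_cap_mv spike cap in mV (default 30).
#' @param dt_ms integration step in ms (default 0.5).
#' @param v0,u0 initial state (defaults: resting point -70 mV, `b * v0`).
#' @return object of class `izhikevich_params`.
#' @export
izhikevich_params <- function(a = 0.02, b = 0.2, c = -65, d = 8,
                              v_cap_mv = 30, dt_ms = 0.5,
                              v0 = -70, u0 = b * v0) {
  check_scalar(dt_ms, "dt_ms", positive = TRUE)
  check_scalar(v_cap_mv, "v_cap_mv")
  structure(list(a = a, b = b, c = c, d = d, v_cap_mv = v_cap_mv,
                 dt_ms = dt_ms, v0 = v0, u0 = u0),
            class = "izhikevich_params")
}

#' Jittered synaptic input population
#'
#' @param n_inputs number of inputs (>= 0).
#' @param polarity `"excitatory"` (depolarizing, +) or `"inhibitory"`
#'   (hyperpolarizing, -).
#' @param sigma_ms SD of the Gaussian input-timing jitter (ms, >= 0);
#'   `sigma_ms = 0` means perfectly synchronous inputs.
#' @param t0_ms mean input time (ms, default 100).
#' @param amplitude time-integral of the instantaneous input current,
#'   expressed as the membrane-potential jump per input in mV (default 8):
#'   each input shifts the membrane by exactly `amplitude` mV at its binned
#'   arrival time, independent of the integration step. The default is set
#'   so that 20 synchronous excitatory inputs reliably elicit a spike and
#'   20 synchronous inhibitory inputs a deep, clearly measurable
#'   hyperpolarization.
#' @return object of class `input_population`.
#' @export
input_population <- function(n_inputs, polarity = c("excitatory",
                                                    "inhibitory"),
                             sigma_ms = 0, t0_ms = 100, amplitude = 8) {
  polarity <- match.arg(polarity)
  if (!is.numeric(n_inputs) || n_inputs < 0) {
    stop("`n_inputs` must be >= 0", call. = FALSE)
  }
  check_scalar(sigma_ms, "sigma_ms", nonneg = TRUE)
  check_scalar(amplitude, "amplitude", positive = TRUE)
  structure(list(n_inputs = as.integer(n_inputs), polarity = polarity,
                 sigma_ms = sigma_ms, t0_ms = t0_ms, amplitude = amplitude),
            class = "input_population")
}

#' Sample jittered input times on the simulation grid
#'
#' Draws `n_inputs` times from Normal(`t0_ms`, `sigma_ms`) and bins them to
#' the integration grid at `dt_ms` resolution; `sigma_ms = 0` puts every
#' input at `t0_ms`.
#'
#' @param pop an [input_population()].
#' @param seed integer seed.
#' @param dt_ms grid resolution in ms (default 0.5).
#' @return numeric vector of binned input times (ms).
#' @export
sample_input_times <- function(pop, seed, dt_ms = 0.5) {
  stopifnot(inherits(pop, "input_population"))
  check_scalar(dt_ms, "dt_ms", positive = TRUE)
  times <- if (pop$sigma_ms == 0) {
    rep(pop$t0_ms, pop$n_inputs)
  } else {
    with_seed(seed, stats::rnorm(pop$n_inputs, pop$t0_ms, pop$sigma_ms))
  }
  round(times / dt_ms) * dt_ms
}

# Core integrator, vectorized over iterations. `impulse_steps` is a list
# (one element per iteration) of integer step indices at which inputs
# arrive (with multiplicity); each input adds `signed_jump` mV to v at the
# start of its step. Returns the voltage matrix (n_steps x n_iter, sampled
# after the step's dynamics, capped at spike samples), per-iteration spike
# times, and the running post-jump minimum voltage (the instantaneous
# post-input value, needed for a step-size-independent inhibition depth).
izh_integrate <- function(params, impulse_steps, n_steps, signed_jump) {
  n_iter <- length(impulse_steps)
  dt <- params$dt_ms
  jmat <- matrix(0, n_steps, n_iter)
  for (k in seq_len(n_iter)) {
    st <- impulse_steps[[k]]
    st <- st[st >= 1L & st <= n_steps]
    if (length(st)) {
      jmat[, k] <- tabulate(st, nbins = n_steps) * signed_jump
    }
  }
  v <- rep(params$v0, n_iter)
  u <- rep(params$u0, n_iter)
  vrec <- matrix(NA_real_, n_steps, n_iter)
  vmin <- rep(Inf, n_iter)
  spikes <- vector("list", n_iter)
  for (s in seq_len(n_steps)) {
    v <- v + jmat[s, ]
    vmin <- pmin(vmin, v)
    v <- v + (dt / 2) * (0.04 * v^2 + 5 * v + 140 - u)
    v <- v + (dt / 2) * (0.04 * v^2 + 5 * v + 140 - u)
    u <- u + dt * params$a * (params$b * v - u)
    if (any(!is.finite(v)) || any(!is.finite(u))) {
      stop(sprintf("numerical failure (non-finite state) at step %d", s),
           call. = FALSE)
    }
    fired <- v >= params$v_cap_mv
    vrec[s, ] <- ifelse(fired, params$v_cap_mv, v)
    vmin <- pmin(vmin, v)
    if (any(fired)) {
      for (k in which(fired)) {
        spikes[[k]] <- c(spikes[[k]], s * dt)
      }
      v[fired] <- params$c
      u[fired] <- u[fired] + params$d
    }
  }
  list(v = vrec, spikes = spikes, vmin = vmin)
}

# Depth of hyperpolarization: baseline (mean voltage over the 50 ms before
# the earliest input) minus the overall minimum voltage (including the
# instantaneous post-jump values); floored at 0. Before the first input the
# neuron sits at rest, so the pre-input trace never deepens the minimum.
inhibition_depth <- function(v_trace, vmin, first_input_step, dt_ms) {
  pre <- seq(max(1L, first_input_step - round(50 / dt_ms)),
             max(1L, first_input_step - 1L))
  baseline <- mean(v_trace[pre])
  max(0, baseline - vmin)
}

#' Simulate the downstream neuron for one input draw
#'
#' @param params an [izhikevich_params()].
#' @param pop an [input_population()].
#' @param seed integer seed for the input-time draw.
#' @param t_end_ms simulation end (ms); default `t0_ms + 500`. Must exceed
#'   `t0_ms + 5 * sigma_ms`.
#' @return object of class `izh_sim`: `time_ms`, `v_trace` (mV, capped at
#'   spike samples), `spike_times_ms`, `n_spikes`, `inhibition_depth_mv`
#'   (baseline minus post-input minimum), `input_times_ms`.
#' @export
simulate_downstream <- function(params, pop, seed = 1L,
                                t_end_ms = pop$t0_ms + 500) {
  stopifnot(inherits(params, "izhikevich_params"),
            inherits(pop, "input_population"))
  if (t_end_ms <= pop$t0_ms + 5 * pop$sigma_ms) {
    stop("`t_end_ms` must exceed t0_ms + 5 * sigma_ms", call. = FALSE)
  }
  dt <- params$dt_ms
  n_steps <- ceiling(t_end_ms / dt)
  times <- sample_input_times(pop, seed, dt)
  steps <- as.integer(round(times / dt))
  amp <- if (pop$polarity == "excitatory") pop$amplitude else -pop$amplitude
  res <- izh_integrate(params, list(steps), n_steps, amp)
  depth <- if (length(steps)) {
    inhibition_depth(res$v[, 1L], res$vmin[1L], max(1L, min(steps)), dt)
  } else 0
  sp <- res$spikes[[1L]] %||% numeric(0)
  structure(
    list(time_ms = seq_len(n_steps) * dt, v_trace = res$v[, 1L],
         u_trace = NULL, spike_times_ms = sp, n_spikes = length(sp),
         inhibition_depth_mv = depth, input_times_ms = times,
         params = params, pop = pop),
    class = "izh_sim")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.izh_sim <- function(x, ...) {
  cat(sprintf(
    "<izh_sim> %d %s inputs, sigma %g ms: %d spikes, depth %.2f mV\n",
    x$pop$n_inputs, x$pop$polarity, x$pop$sigma_ms, x$n_spikes,
    x$inhibition_depth_mv))
  invisible(x)
}

#' @export
plot.izh_sim <- function(x, ...) {
  graphics::plot(x$time_ms, x$v_trace, type = "l", xlab = "time (ms)",
                 ylab = "membrane potential (mV)", ...)
  graphics::rug(x$input_times_ms, col = "grey40")
  invisible(x)
}

# Shared driver for the sweeps: runs n_iter independent input draws per
# condition in one vectorized integration.
run_condition <- function(params, pop, n_iter, seeds, t_end_ms) {
  dt <- params$dt_ms
  n_steps <- ceiling(t_end_ms / dt)
  amp <- if (pop$polarity == "excitatory") pop$amplitude else -pop$amplitude
  step_list <- lapply(seq_len(n_iter), function(k) {
    as.integer(round(sample_input_times(pop, seeds[k], dt) / dt))
  })
  res <- izh_integrate(params, step_list, n_steps, amp)
  n_spikes <- vapply(res$spikes, function(s) length(s %||% numeric(0)), 1L)
  depth <- vapply(seq_len(n_iter), function(k) {
    st <- step_list[[k]]
    if (!length(st)) return(0)
    inhibition_depth(res$v[, k], res$vmin[k], max(1L, min(st)), dt)
  }, numeric(1))
  list(n_spikes = n_spikes, depth = depth)
}

#' Sweep over input-timing jitter
#'
#' For each jitter SD in `sigma_grid`, runs `n_iter` independent
#' simulations. Inhibitory mode summarizes the per-iteration inhibition
#' depth (baseline minus post-input minimum, then averaged); excitatory
#' mode summarizes the spike count.
#'
#' @param params an [izhikevich_params()].
#' @param polarity `"excitatory"` or `"inhibitory"`.
#' @param n_inputs inputs per draw (default 20).
#' @param sigma_grid jitter SDs to test (ms), e.g. `c(0, 10, 50)`.
#' @param n_iter iterations per sigma (default 500).
#' @param seed master seed.
#' @param t0_ms mean input time (default 100).
#' @param amplitude per-input membrane jump in mV (default 8).
#' @param t_end_ms simulation end; default covers `t0 + 5 * max(sigma)` and
#'   at least `t0 + 500`.
#' @return data.frame of class `izh_sweep` with columns `sigma_ms`, `mean`,
#'   `sd`, `n_iter`; the summarized quantity is `"depth_mv"` or
#'   `"n_spikes"` depending on polarity (attribute `measure`).
#' @export
sweep_sigma <- function(params = izhikevich_params(),
                        polarity = c("excitatory", "inhibitory"),
                        n_inputs = 20, sigma_grid = c(0, 10, 50),
                        n_iter = 500, seed = 1L, t0_ms = 100,
                        amplitude = 8,
                        t_end_ms = max(t0_ms + 500,
                                       t0_ms + 5 * max(sigma_grid) + 100)) {
  polarity <- match.arg(polarity)
  if (length(sigma_grid) == 0L) stop("`sigma_grid` is empty", call. = FALSE)
  check_scalar(n_iter, "n_iter", positive = TRUE)
  seeds <- matrix(derive_seeds(seed, n_iter * length(sigma_grid)),
                  nrow = n_iter)
  rows <- lapply(seq_along(sigma_grid), function(i) {
    pop <- input_population(n_inputs, polarity, sigma_grid[i], t0_ms,
                            amplitude)
    res <- run_condition(params, pop, n_iter, seeds[, i], t_end_ms)
    x <- if (polarity == "inhibitory") res$depth else res$n_spikes
    data.frame(sigma_ms = sigma_grid[i], mean = mean(x),
               sd = stats::sd(x), n_iter = as.integer(n_iter))
  })
  out <- do.call(rbind, rows)
  attr(out, "measure") <- if (polarity == "inhibitory") "depth_mv" else
    "n_spikes"
  attr(out, "polarity") <- polarity
  class(out) <- c("izh_sweep", "data.frame")
  out
}

#' Sweep over the number of excitatory inputs
#'
#' @param params an [izhikevich_params()].
#' @param sigma_ms input-timing jitter SD (ms).
#' @param n_grid input counts to test, e.g. `c(10, 30, 50)`.
#' @param n_iter iterations per count (default 500).
#' @param seed master seed.
#' @param t0_ms mean input time (default 100).
#' @param amplitude per-input membrane jump in mV (default 8).
#' @param t_end_ms simulation end.
#' @return data.frame of class `izh_sweep` with columns `n_inputs`, `mean`,
#'   `sd`, `n_iter` (mean/SD of the spike count).
#' @export
sweep_n_inputs <- function(params = izhikevich_params(), sigma_ms = 10,
                           n_grid = c(10, 30, 50), n_iter = 500, seed = 1L,
                           t0_ms = 100, amplitude = 8,
                           t_end_ms = max(t0_ms + 500,
                                          t0_ms + 5 * sigma_ms + 100)) {
  if (length(n_grid) == 0L) stop("`n_grid` is empty", call. = FALSE)
  check_scalar(n_iter, "n_iter", positive = TRUE)
  seeds <- matrix(derive_seeds(seed, n_iter * length(n_grid)),
                  nrow = n_iter)
  rows <- lapply(seq_along(n_grid), function(i) {
    pop <- input_population(n_grid[i], "excitatory", sigma_ms, t0_ms,
                            amplitude)
    res <- run_condition(params, pop, n_iter, seeds[, i], t_end_ms)
    data.frame(n_inputs = n_grid[i], mean = mean(res$n_spikes),
               sd = stats::sd(res$n_spikes), n_iter = as.integer(n_iter))
  })
  out <- do.call(rbind, rows)
  attr(out, "measure") <- "n_spikes"
  attr(out, "polarity") <- "excitatory"
  class(out) <- c("izh_sweep", "data.frame")
  out
}

#' @export
print.izh_sweep <- function(x, ...) {
  cat(sprintf("<izh_sweep> %s inputs, measure: %s\n",
              attr(x, "polarity"), attr(x, "measure")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
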