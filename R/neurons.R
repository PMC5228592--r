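#' Point-neuron parameter sets
#'
#' Two hybrid point-neuron families are used: the quadratic
#' integrate-and-fire model with adaptation (striatal projection neurons and
#' fast-spiking interneurons) and the adaptive exponential
#' integrate-and-fire model (pallidal, nigral and subthalamic neurons).
#' `qif_params()` and `adex_params()` build validated parameter objects;
#' `neuron_params()` loads the catalogued set for one of the seven model
#' populations from the parameter file shipped with the package.
#'
#' Units are mV, ms, pF, nS and pA throughout (so nS*mV = pA and
#' pF*mV/ms = pA). The recovery rate constant `a` of the quadratic family is
#' stored in 1/ms.
#'
#' @param C Membrane capacitance (pF).
#' @param k Steady-state I-V coefficient (quadratic family).
#' @param v_r,v_th Resting and threshold potentials (mV).
#' @param v_peak Spike cutoff (mV).
#' @param c Spike reset (mV).
#' @param a Recovery rate constant (1/ms).
#' @param b Recovery voltage dependence.
#' @param d Spike-triggered recovery increment (pA).
#' @param v_b Recovery-current kink voltage (mV); setting it marks the
#'   fast-spiking variant whose recovery is cubic below `v_b`.
#' @return An object of class `qif_params` or `adex_params`.
#' @examples
#' p <- neuron_params("MSN_D2")
#' qif_derivatives(neuron_state(-80, 0), p, I = 0)
#' @export
qif_params <- function(C, k, v_r, v_th, v_peak, c, a, b, d, v_b = NA_real_) {
  p <- list(C = C, k = k, v_r = v_r, v_th = v_th, v_peak = v_peak, c = c,
            a = a, b = b, d = d, v_b = v_b,
            is_fsn_variant = is.finite(v_b))
  stopifnot(p$C > 0, p$v_r < p$v_th, p$v_th < p$v_peak, p$c < p$v_peak, p$a > 0)
  structure(p, class = "qif_params")
}

#' @rdname qif_params
#' @param g_L Leak conductance (nS).
#' @param E_L Leak reversal potential (mV).
#' @param V_T Threshold potential (mV).
#' @param Delta_T Spike slope factor (mV).
#' @param a_sub Subthreshold adaptation conductance (nS).
#' @param tau_w Adaptation time constant (ms).
#' @param b_spike Spike-triggered adaptation increment (pA).
#' @param V_r Spike reset (mV).
#' @param t_f Spike cutoff (mV).
#' @param I_e Tonic bias current (pA).
#' @param stn_rebound Enable the subthalamic rebound-burst reset variant.
#' @param stn_reset_offset,stn_reset_cap Constants of the rebound reset
#'   `V = V_r + max(w - offset, cap)` applied when `w < 0` at spike time.
#' @param adaptation_gate Voltage (mV) below which `a_sub` acts; `NA` for no
#'   gate (subthalamic neurons gate adaptation below -70 mV).
#' @export
adex_params <- function(C, g_L, E_L, V_T, Delta_T, a_sub, tau_w, b_spike,
                        V_r, t_f, I_e = 0, stn_rebound = FALSE,
                        stn_reset_offset = 15, stn_reset_cap = 20,
                        adaptation_gate = NA_real_) {
  p <- list(C = C, g_L = g_L, E_L = E_L, V_T = V_T, Delta_T = Delta_T,
            a_sub = a_sub, tau_w = tau_w, b_spike = b_spike, V_r = V_r,
            t_f = t_f, I_e = I_e, stn_rebound = stn_rebound,
            stn_reset_offset = stn_reset_offset, stn_reset_cap = stn_reset_cap,
            adaptation_gate = adaptation_gate)
  stopifnot(p$C > 0, p$g_L > 0, p$Delta_T > 0, p$tau_w > 0, p$V_r < p$t_f)
  structure(p, class = "adex_params")
}

#' @rdname qif_params
#' @param population One of `"MSN_D1"`, `"MSN_D2"`, `"FSN"`, `"STN"`,
#'   `"GPe_TA"`, `"GPe_TI"`, `"SNr"`.
#' @export
neuron_params <- function(population) {
  cat <- read_catalogue("neurons.tsv")
  rows <- cat[cat$population == population, ]
  if (nrow(rows) == 0L)
    stop("unknown population: ", population)
  val <- function(p) {
    v <- rows$value[rows$param == p]
    if (length(v) == 0L) NA_real_ else as.numeric(v)
  }
  if (rows$family[1] == "qif") {
    qif_params(C = val("C"), k = val("k"), v_r = val("v_r"),
               v_th = val("v_th"), v_peak = val("v_peak"), c = val("c"),
               a = val("a"), b = val("b"), d = val("d"), v_b = val("v_b"))
  } else {
    adex_params(C = val("C"), g_L = val("g_L"), E_L = val("E_L"),
                V_T = val("V_T"), Delta_T = val("Delta_T"),
                a_sub = val("a_sub"), tau_w = val("tau_w"),
                b_spike = val("b_spike"), V_r = val("V_r"), t_f = val("t_f"),
                I_e = val("I_e"),
                stn_rebound = population == "STN",
                adaptation_gate = val("adaptation_gate"))
  }
}

#' @rdname qif_params
#' @param V Membrane potential (mV).
#' @param u Recovery/adaptation current (pA).
#' @export
neuron_state <- function(V, u = 0) {
  if (!is.finite(V) || !is.finite(u)) stop("non-finite neuron state")
  structure(list(V = V, u = u), class = "neuron_state")
}

#' Membrane and recovery derivatives
#'
#' Right-hand sides of the two neuron families, in mV/ms and pA/ms. For the
#' fast-spiking variant the recovery derivative follows
#' [fsn_recovery_derivative()]. The subthalamic adaptation conductance is
#' gated off above `adaptation_gate`.
#'
#' @param state A [neuron_state()].
#' @param p Parameter object.
#' @param I Input current (pA).
#' @return `c(dV = , du = )` in mV/ms and pA/ms.
#' @export
qif_derivatives <- function(state, p, I = 0) {
  stopifnot(inherits(p, "qif_params"))
  if (!all(is.finite(c(state$V, state$u, I)))) stop("non-finite neuron state")
  dV <- (p$k * (state$V - p$v_r) * (state$V - p$v_th) - state$u + I) / p$C
  du <- if (p$is_fsn_variant) fsn_recovery_derivative(state, p)
        else p$a * (p$b * (state$V - p$v_r) - state$u)
  c(dV = dV, du = du)
}

#' @rdname qif_derivatives
#' @export
fsn_recovery_derivative <- function(state, p) {
  stopifnot(inherits(p, "qif_params"), p$is_fsn_variant)
  if (state$V <= p$v_b) p$a * (p$b * (state$V - p$v_b)^3 - state$u)
  else -p$a * state$u
}

#' @rdname qif_derivatives
#' @export
adex_derivatives <- function(state, p, I = 0) {
  stopifnot(inherits(p, "adex_params"))
  if (!all(is.finite(c(state$V, state$u, I)))) stop("non-finite neuron state")
  ex <- min((state$V - p$V_T) / p$Delta_T, 30)  # overflow ends in a declared spike
  dV <- (-p$g_L * (state$V - p$E_L) + p$g_L * p$Delta_T * exp(ex) -
           state$u + I) / p$C
  a_eff <- if (is.finite(p$adaptation_gate) && state$V >= p$adaptation_gate) 0
           else p$a_sub
  du <- (a_eff * (state$V - p$E_L) - state$u) / p$tau_w
  c(dV = dV, du = du)
}

#' Post-spike reset
#'
#' Applies the reset of the relevant family once the membrane potential has
#' crossed the cutoff: the quadratic family resets `V` to `c` and increments
#' the recovery current by `d`; the adaptive exponential family resets `V`
#' to `V_r` and increments the adaptation current by `b`. The subthalamic
#' rebound variant, when the adaptation current is negative at spike time,
#' instead resets to `V_r + max(w - 15, 20)` (a depolarised reset sustaining
#' the rebound burst); `rule = "min"` swaps the max for a min.
#'
#' @inheritParams qif_derivatives
#' @param rule `"max"` (literal form) or `"min"`.
#' @return The reset [neuron_state()].
#' @export
apply_spike_reset <- function(state, p, rule = c("max", "min")) {
  rule <- match.arg(rule)
  if (inherits(p, "qif_params")) {
    neuron_state(p$c, state$u + p$d)
  } else {
    w <- state$u + p$b_spike
    V <- if (isTRUE(p$stn_rebound) && state$u < 0) {
      off <- state$u - p$stn_reset_offset
      p$V_r + if (rule == "max") max(off, p$stn_reset_cap)
              else min(off, p$stn_reset_cap)
    } else p$V_r
    neuron_state(V, w)
  }
}

#' Population heterogeneity
#'
#' Cell-to-cell variability is introduced by sampling the membrane
#' capacitance from a normal distribution with coefficient of variation
#' `C_cv` (resampled until positive) and the threshold potential from a
#' normal distribution with standard deviation `Vth_sd` mV; all other
#' parameters are shared.
#'
#' @param C_cv Coefficient of variation of the capacitance (default 0.10).
#' @param Vth_sd Standard deviation of the threshold (mV, default 1).
#' @param seed Integer seed making the draw reproducible.
#' @export
heterogeneity_spec <- function(C_cv = 0.10, Vth_sd = 1.0, seed = 1L) {
  stopifnot(C_cv >= 0, Vth_sd >= 0)
  structure(list(C_cv = C_cv, Vth_sd = Vth_sd, seed = as.integer(seed)),
            class = "heterogeneity_spec")
}

#' @rdname heterogeneity_spec
#' @param base Base parameter object ([qif_params()] or [adex_params()]).
#' @param spec A [heterogeneity_spec()].
#' @param n Number of parameter records to draw.
#' @return A data.frame with columns `C` and `threshold` (`v_th` or `V_T`),
#'   one row per neuron.
#' @export
sample_heterogeneity <- function(base, spec, n) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  C0 <- base$C
  th0 <- if (inherits(base, "qif_params")) base$v_th else base$V_T
  out <- withr_seed(spec$seed, {
    C <- rnorm(n, C0, spec$C_cv * C0)
    bad <- which(C <= 0)
    while (length(bad)) {
      C[bad] <- rnorm(length(bad), C0, spec$C_cv * C0)
      bad <- bad[C[bad] <= 0]
    }
    data.frame(C = C, threshold = rnorm(n, th0, spec$Vth_sd))
  })
  out
}

# Evaluate expr under a local RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 12-column engine parameter row + family code for one neuron.
param_row <- function(p) {
  if (inherits(p, "qif_params")) {
    list(fam = if (p$is_fsn_variant) 1L else 0L,
         row = c(p$C, p$k, p$v_r, p$v_th, p$v_peak, p$c, p$a, p$b, p$d,
                 if (is.finite(p$v_b)) p$v_b else 0, 0, 0))
  } else {
    gate <- if (is.finite(p$adaptation_gate)) p$adaptation_gate else 1e9
    list(fam = if (isTRUE(p$stn_rebound)) 3L else 2L,
         row = c(p$C, p$g_L, p$E_L, p$V_T, p$t_f, p$V_r, p$tau_w, p$a_sub,
                 p$b_spike, gate, p$I_e, p$Delta_T))
  }
}

#' Single-neuron simulation and f-I curves
#'
#' `simulate_neuron()` integrates one neuron with forward Euler at fixed
#' `dt` under a constant (or piecewise-constant) current and returns spike
#' times and, optionally, the state trajectory. `fi_curve()` maps injected
#' current to mean firing rate after discarding an initial transient.
#' The current `I` replaces the tonic bias `I_e` (i.e. it is the total
#' constant current), so the catalogued in-vitro rates are obtained at
#' `I = I_e`.
#'
#' @param p Parameter object.
#' @param I Constant current (pA), or for `simulate_neuron` a two-column
#'   matrix `(t_start, amplitude)` of piecewise-constant segments.
#' @param duration Simulated time (ms).
#' @param dt Integration step (ms).
#' @param V0,u0 Initial state; defaults to rest with zero recovery current.
#' @param record Return `V`/`u` traces.
#' @param reset_rule Subthalamic reset rule, see [apply_spike_reset()].
#' @return `simulate_neuron`: list with `spikes` (ms) and optional `trace`.
#' @export
simulate_neuron <- function(p, I = 0, duration = 1000, dt = 0.1,
                            V0 = NULL, u0 = 0, record = FALSE,
                            reset_rule = c("max", "min")) {
  reset_rule <- match.arg(reset_rule)
  if (dt <= 0) stop("dt must be positive")
  pr <- param_row(p)
  if (is.matrix(I)) Iseg <- I
  else Iseg <- cbind(0, I[1])
  if (is.null(V0)) V0 <- if (inherits(p, "qif_params")) p$v_r else p$E_L
  single_neuron_run(pr$fam, pr$row, Iseg, as.double(duration), as.double(dt),
                    as.double(V0), as.double(u0), isTRUE(record),
                    reset_rule == "min")
}

#' @rdname simulate_neuron
#' @param I_values Currents to probe (pA).
#' @param transient Initial window discarded from the rate estimate (ms).
#' @param init `"post_spike"` starts from the reset state (measuring
#'   sustained firing; some pacemakers, e.g. the arkypallidal model, are
#'   bistable and would otherwise stay on a silent fixed point);
#'   `"rest"` starts from the resting potential.
#' @return `fi_curve`: data.frame with columns `I` and `rate` (Hz).
#' @export
fi_curve <- function(p, I_values, duration = 10000, dt = 0.1,
                     transient = 1000, init = c("post_spike", "rest")) {
  init <- match.arg(init)
  if (dt <= 0) stop("dt must be positive")
  if (duration < 2000) stop("duration must be at least 2000 ms")
  qif <- inherits(p, "qif_params")
  V0 <- if (init == "rest") NULL else if (qif) p$c else p$V_r
  u0 <- if (init == "rest") 0 else if (qif) p$d else p$b_spike
  rate <- vapply(I_values, function(I) {
    s <- simulate_neuron(p, I = I, duration = duration, dt = dt,
                         V0 = V0, u0 = u0)$spikes
    sum(s >= transient) / ((duration - transient) / 1000)
  }, numeric(1))
  data.frame(I = I_values, rate = rate)
}
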