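#' Synapse parameter catalogue
#'
#' Returns the catalogued conductance-based synapse parameters, one row per
#' connection: peak conductance `g0` (nS), decay constant `tau_syn` (ms),
#' reversal potential `E_rev` (mV), axonal `delay` (ms), receptor, and for
#' short-term-plastic rows the Tsodyks-Markram utilisation `U` and recovery /
#' facilitation time constants (ms).
#'
#' @param name Optional connection name; returns the full table if missing.
#' @return A data.frame (or single-row data.frame when `name` is given).
#' @export
synapse_catalogue <- function(name = NULL) {
  cat <- read_catalogue("synapses.tsv")
  if (is.null(name)) return(cat)
  row <- cat[cat$name == name, ]
  if (nrow(row) != 1L) stop("unknown synapse: ", name)
  row
}

#' Static conductance synapse
#'
#' Exponential-decay conductance: each presynaptic spike increments the
#' conductance by `g0` (linear superposition); between events the
#' conductance decays with `tau_syn`. Updates use the exact closed form.
#'
#' @param g Current conductance (nS).
#' @param p A list/row with `g0` and `tau_syn`.
#' @param dt Elapsed time (ms).
#' @export
static_decay <- function(g, p, dt) {
  if (dt <= 0) stop("dt must be positive")
  g * exp(-dt / p$tau_syn)
}

#' @rdname static_decay
#' @export
static_on_spike <- function(g, p) g + p$g0

#' NMDA magnesium block
#'
#' Voltage-dependent relief of the magnesium block of NMDA receptors, in
#' the standard form `B(V) = 1 / (1 + (Mg/3.57) * exp(-0.062 V))` with the
#' membrane potential in mV (the voltage constant 0.062 is per mV). `B` is
#' strictly increasing in `V`, tends to 1 for depolarised and 0 for
#' hyperpolarised membranes; at 1 mM magnesium and -80 mV roughly 2.4% of
#' the NMDA conductance is unblocked.
#'
#' @param V Membrane potential (mV).
#' @param mg_mM Extracellular magnesium concentration (mM, default 1).
#' @param k_conc Concentration constant (mM).
#' @param k_volt Voltage constant (1/mV).
#' @return Factor in (0, 1].
#' @export
mg_block_factor <- function(V, mg_mM = 1.0, k_conc = 3.57, k_volt = 0.062) {
  stopifnot(all(is.finite(V)), mg_mM >= 0)
  1 / (1 + (mg_mM / k_conc) * exp(-k_volt * V))
}

#' Tsodyks-Markram short-term plasticity
#'
#' A finite pool of synaptic resources moves between recovered (`x`),
#' active (`y`) and inactive (`z`) states, with `x + y + z = 1`. At a
#' presynaptic spike the utilisation `u` is first incremented by
#' `U * (1 - u)` (so a spike from rest releases exactly `U`), then the
#' released fraction `r = u * x` moves from `x` to `y`; the postsynaptic
#' conductance is `g0 * y`. Between spikes `y` decays to the inactive pool
#' with `tau_syn`, the inactive pool drains back to `x` with `tau_rec`, and
#' `u` decays to 0 with `tau_fac`. `tau_fac = 0` is the non-facilitating
#' limit in which `u` returns to 0 instantly (every spike releases `U * x`).
#' Between-spike updates use the exact closed-form solution.
#'
#' @param state List with `u`, `x`, `y`, `z`.
#' @param p List/row with `U`, `tau_rec`, `tau_fac`, `tau_syn`.
#' @export
tsodyks_state <- function(u = 0, x = 1, y = 0, z = 0) {
  stopifnot(x >= 0, y >= 0, z >= 0, u >= 0, u <= 1,
            abs(x + y + z - 1) < 1e-9)
  list(u = u, x = x, y = y, z = z)
}

#' @rdname tsodyks_state
#' @return `tsodyks_on_spike`: list with the updated `state` and the
#'   `released` fraction.
#' @export
tsodyks_on_spike <- function(state, p) {
  u <- state$u + p$U * (1 - state$u)
  r <- u * state$x
  list(state = list(u = u, x = state$x - r, y = state$y + r, z = state$z),
       released = r)
}

#' @rdname tsodyks_state
#' @param dt Elapsed time since the last update (ms).
#' @export
tsodyks_evolve <- function(state, p, dt) {
  if (dt <= 0) stop("dt must be positive")
  u <- if (p$tau_fac > 0) state$u * exp(-dt / p$tau_fac) else 0
  es <- exp(-dt / p$tau_syn)
  er <- exp(-dt / p$tau_rec)
  y <- state$y * es
  # z' = y/tau_syn - z/tau_rec, driven by the decaying active pool
  A <- state$y * p$tau_rec / (p$tau_syn - p$tau_rec)
  z <- (state$z - A) * er + A * es
  list(u = u, x = 1 - y - z, y = y, z = z)
}

#' Steady-state release of a periodically driven Tsodyks synapse
#'
#' Closed-form fixed point of the per-spike recurrence under periodic
#' stimulation at interval `isi` (ms), used as an independent check of the
#' event-driven implementation.
#'
#' @param p Synapse parameters (as in [tsodyks_evolve()]).
#' @param isi Interspike interval (ms).
#' @return Released fraction per spike at steady state.
#' @export
tsodyks_steady_release <- function(p, isi) {
  er <- exp(-isi / p$tau_rec)
  ef <- if (p$tau_fac > 0) exp(-isi / p$tau_fac) else 0
  # u just after a spike: u+ = u- + U (1 - u-), u- = u+ * ef
  u_plus <- p$U / (1 - ef * (1 - p$U))
  # x just before a spike: x- = 1 - (1 - x-(1 - u+)) er  (tau_syn-fast limit)
  # solve x- = 1 - er + er x- (1 - u+)
  x_minus <- (1 - er) / (1 - er * (1 - u_plus))
  u_plus * x_minus
}
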