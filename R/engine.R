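#' Run a network simulation
#'
#' Clock-driven integration of a built network under a set of extrinsic
#' drives: all neurons advance with forward Euler at fixed `dt`, spikes are
#' detected at step end by cutoff crossing, synaptic events are queued in
#' per-connection ring buffers and delivered after their axonal delay
#' (rounded to the step grid), and short-term-plastic synapses update their
#' resource state lazily at event times with exact closed forms. The run
#' is deterministic given `seed`.
#'
#' @param net A [build_network()] network.
#' @param drives A drive set from [default_drives()] (or derived helpers);
#'   `NULL` simulates without extrinsic input.
#' @param duration Simulated time (ms).
#' @param dt Step (ms, default 0.1); all delays must be >= `dt`.
#' @param seed Integer master seed; every random stream (drive realisations,
#'   initial-condition jitter) derives from it.
#' @param injections List of current injections, each
#'   `list(population=, amp=, t0=, t1=)` (pA; see [inject_current()]).
#' @param mg_mM Magnesium concentration for the NMDA block (mM).
#' @param stn_reset_rule Subthalamic rebound reset rule (see
#'   [apply_spike_reset()]).
#' @param init_jitter Half-width of the uniform initial-voltage jitter (mV).
#' @param probe Optional global neuron ids (1-based) whose membrane
#'   trajectories are recorded every step.
#' @return A `bg_spikes` object: spike times `t` (ms), global neuron ids
#'   `id` (1-based), population labels `pop`, plus metadata (duration, dt,
#'   sizes, offsets, audit counters, probes).
#' @export
simulate <- function(net, drives = NULL, duration = 1000, dt = 0.1,
                     seed = 1L, injections = list(), mg_mM = 1.0,
                     stn_reset_rule = c("max", "min"), init_jitter = 5,
                     probe = integer()) {
  stopifnot(inherits(net, "bg_network"), duration > 0, dt > 0)
  stn_reset_rule <- match.arg(stn_reset_rule)

  channels <- list()
  rconns <- list()
  for (cn in net$conns) {
    delay <- cn$syn$delay
    if (delay < dt) stop("connection ", cn$name, ": delay below dt")
    channels[[length(channels) + 1L]] <- list(
      off = cn$post_off, n = cn$n_post,
      delay_steps = as.integer(round(delay / dt)),
      nmda = identical(cn$syn$receptor, "NMDA"),
      E = cn$syn$E_rev, tau = cn$syn$tau_syn)
    chan_id <- length(channels) - 1L
    ord <- order(cn$pre_edges)
    ptr <- cumsum(c(0L, tabulate(cn$pre_edges + 1L, nbins = cn$n_pre)))
    plastic <- isTRUE(cn$syn$plastic == 1) && !isTRUE(cn$force_static)
    rconns[[length(rconns) + 1L]] <- list(
      chan = chan_id, pre_off = cn$pre_off, n_pre = cn$n_pre,
      pre_pop = match(cn$pre, POPS) - 1L,
      ptr = as.integer(ptr), post = as.integer(cn$post_edges[ord]),
      g0 = cn$syn$g0 * cn$g_scale, plastic = plastic,
      U = if (plastic) cn$syn$U else 0,
      tau_rec = if (plastic) cn$syn$tau_rec else 1,
      tau_fac = if (plastic) cn$syn$tau_fac else 0,
      tau_syn = cn$syn$tau_syn)
  }

  rdrives <- list()
  for (d in drives) {
    if (length(d$tgt) == 0) next
    channels[[length(channels) + 1L]] <- list(
      off = min(d$tgt) - 1L, n = max(d$tgt) - min(d$tgt) + 1L,
      delay_steps = 1L, nmda = FALSE, E = d$E_rev, tau = d$ampa_tau)
    ca <- length(channels) - 1L
    cnid <- -1L
    if (is.finite(d$nmda_g0) && !is.na(d$nmda_g0)) {
      channels[[length(channels) + 1L]] <- list(
        off = min(d$tgt) - 1L, n = max(d$tgt) - min(d$tgt) + 1L,
        delay_steps = 1L, nmda = TRUE, E = d$E_rev, tau = d$nmda_tau)
      cnid <- length(channels) - 1L
    }
    rdrives[[length(rdrives) + 1L]] <- list(
      tgt = d$tgt - 1L, chan_a = ca, chan_n = cnid,
      g0a = d$ampa_g0, g0n = if (cnid >= 0) d$nmda_g0 else 0,
      base = d$base, amp = d$amp, fmod = d$fmod,
      phase = d$phase %||% 0,
      fac = epoch_matrix(d$fac), add = epoch_matrix(d$add))
  }

  rinj <- lapply(injections, function(q) {
    if (!q$population %in% POPS) stop("unknown population: ", q$population)
    off <- net$offsets[[q$population]]
    ids <- if (!is.null(q$neurons)) off + q$neurons else
      off + seq_len(net$sizes[[q$population]])
    list(i0 = min(ids) - 1L, i1 = max(ids),
         t0 = q$t0 %||% 0, t1 = q$t1 %||% duration, amp = q$amp)
  })

  res <- engine_run(
    list(fam = net$fam, par = net$par, pop_of = net$pop_of),
    channels, rconns, rdrives, rinj, duration, dt, as.double(seed),
    mg_mM, stn_reset_rule == "min", init_jitter, as.integer(probe) - 1L)

  structure(list(t = res$t, id = res$id + 1L,
                 pop = POPS[net$pop_of[res$id + 1L] + 1L],
                 duration = duration, dt = dt, seed = seed,
                 sizes = net$sizes, offsets = net$offsets,
                 labels = net$labels,
                 emitted = res$emitted, delivered = res$delivered,
                 probe_V = res$probe_V, probe_u = res$probe_u),
            class = "bg_spikes")
}

epoch_matrix <- function(m) {
  if (is.null(m) || nrow(m) == 0) matrix(0, 0, 3)
  else matrix(as.double(as.matrix(m)), nrow(m), 3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bg_spikes <- function(x, ...) {
  cat("<bg_spikes>", length(x$t), "spikes over", x$duration, "ms\n")
  print(round(population_rates(x), 2))
  invisible(x)
}

#' @export
as.data.frame.bg_spikes <- function(x, ...) {
  data.frame(t = x$t, id = x$id, pop = x$pop)
}

#' Population firing rates
#'
#' Mean per-neuron firing rate of each population over
#' `[transient, duration]`.
#'
#' @param spikes A `bg_spikes` record.
#' @param transient Initial window to discard (ms).
#' @return Named numeric vector (Hz).
#' @export
population_rates <- function(spikes, transient = 0) {
  keep <- spikes$t >= transient
  secs <- (spikes$duration - transient) / 1000
  cnt <- table(factor(spikes$pop[keep], levels = names(spikes$sizes)))
  stats::setNames(as.numeric(cnt) / (as.numeric(spikes$sizes) * secs),
                  names(spikes$sizes))
}

#' Per-neuron spike trains
#'
#' @param spikes A `bg_spikes` record.
#' @param population Population name.
#' @param neurons Optional local (1-based) neuron indices within the
#'   population.
#' @return Named list of spike-time vectors, one per requested neuron.
#' @export
spike_trains <- function(spikes, population, neurons = NULL) {
  off <- spikes$offsets[[population]]
  nn <- spikes$sizes[[population]]
  if (is.null(neurons)) neurons <- seq_len(nn)
  sel <- spikes$id > off & spikes$id <= off + nn
  loc <- spikes$id[sel] - off
  tt <- spikes$t[sel]
  out <- lapply(neurons, function(j) tt[loc == j])
  names(out) <- as.character(neurons)
  out
}

#' Current injection and connection scaling
#'
#' `inject_current()` builds an injection descriptor adding a constant
#' current to every member of a population during a window.
#' `scale_connection()` multiplies a connection's synaptic conductance by
#' a factor (0 silences it, larger factors strengthen it).
#' `find_silencing_current()` searches for the smallest-magnitude
#' hyperpolarising current that yields zero spikes of the population in a
#' probe run.
#'
#' @param population Population name.
#' @param amp Amplitude (pA; negative hyperpolarises).
#' @param t0,t1 Window (ms); defaults to the whole run.
#' @param neurons Optional local indices.
#' @export
inject_current <- function(population, amp, t0 = NULL, t1 = NULL,
                           neurons = NULL) {
  list(population = population, amp = amp, t0 = t0, t1 = t1,
       neurons = neurons)
}

#' @rdname inject_current
#' @param net Network.
#' @param name Connection name (row of the connectivity catalogue).
#' @param factor Non-negative scale factor.
#' @export
scale_connection <- function(net, name, factor) {
  stopifnot(inherits(net, "bg_network"), factor >= 0)
  if (!name %in% names(net$conns)) stop("unknown connection: ", name)
  net$conns[[name]]$g_scale <- net$conns[[name]]$g_scale * factor
  net
}

#' @rdname inject_current
#' @param drives Drive set for the probe runs.
#' @param probe_ms Probe duration (ms).
#' @param step Initial search step (pA).
#' @param tol Current resolution (pA).
#' @param seed Probe seed.
#' @export
find_silencing_current <- function(net, drives, population, probe_ms = 1000,
                                   step = 50, tol = 10, seed = 1L) {
  rate_at <- function(a) {
    s <- simulate(net, drives, duration = probe_ms, seed = seed,
                  injections = list(inject_current(population, a)))
    sum(s$pop == population & s$t > probe_ms / 5)
  }
  hi <- 0
  repeat {
    hi <- hi - step
    if (rate_at(hi) == 0) break
    if (hi < -5000) stop("silencing current search failed for ", population)
  }
  lo <- hi + step  # lo spikes, hi silent
  while (lo - hi > tol) {
    mid <- (lo + hi) / 2
    if (rate_at(mid) == 0) hi <- mid else lo <- mid
  }
  hi
}
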