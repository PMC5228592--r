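#' Extrinsic drive catalogue
#'
#' Table of the cortical/thalamic Poisson drives: mean rate per cortical
#' state (slow-wave vs activation), square-wave modulation amplitude, and
#' the conductance parameters of the synapse each drive enters through.
#'
#' @export
drive_catalogue <- function() read_catalogue("drives.tsv")

#' Square-wave-modulated Poisson events
#'
#' Generates one realisation of a piecewise-homogeneous Poisson process
#' whose rate alternates between `v(1+a)` and `v(1-a)` every half cycle of
#' the modulation frequency, the process used to emulate slow-wave (1 Hz)
#' and beta (20 Hz) cortical regimes. The long-run mean rate is `v`.
#'
#' @param rate Mean rate `v` (Hz).
#' @param amp Modulation amplitude `a` in [0, 1).
#' @param freq Modulation frequency (Hz); 0 for a homogeneous process.
#' @param duration Duration (ms).
#' @param seed Integer seed.
#' @return Sorted event times (ms).
#' @export
modulated_poisson <- function(rate, amp = 0, freq = 0, duration = 1000,
                              seed = 1L) {
  stopifnot(rate >= 0, duration > 0)
  if (amp < 0 || amp >= 1) stop("modulation amplitude must be in [0, 1)")
  withr_seed(seed, {
    if (freq <= 0 || amp == 0) {
      nev <- stats::rpois(1, rate * duration / 1000)
      return(sort(runif(nev, 0, duration)))
    }
    half <- 500 / freq
    starts <- seq(0, duration, by = half)
    ev <- lapply(seq_along(starts), function(k) {
      t0 <- starts[k]
      t1 <- min(t0 + half, duration)
      if (t1 <= t0) return(numeric())
      r <- rate * (1 + if ((k - 1) %% 2 == 0) amp else -amp)
      nev <- stats::rpois(1, r * (t1 - t0) / 1000)
      runif(nev, t0, t1)
    })
    sort(unlist(ev))
  })
}

# One engine drive entry.
drive_entry <- function(name, tgt, base, amp, fmod, ampa_g0, ampa_tau,
                        nmda_g0, nmda_tau, E_rev,
                        fac = matrix(0, 0, 3), add = matrix(0, 0, 3),
                        phase = 0) {
  list(name = name, tgt = as.integer(tgt), base = base, amp = amp,
       fmod = fmod, ampa_g0 = ampa_g0, ampa_tau = ampa_tau,
       nmda_g0 = nmda_g0, nmda_tau = nmda_tau, E_rev = E_rev,
       fac = fac, add = add, phase = phase)
}

#' Split a drive over a neuron subset
#'
#' Splits one drive entry into a subset drive (e.g. an activated pool of
#' striatal neurons) and the remainder, optionally attaching burst factor
#' epochs to the subset. Used for cluster-activation and pool-burst
#' protocols.
#'
#' @param drives Drive set.
#' @param name Entry to split.
#' @param ids Global neuron ids forming the subset.
#' @param fac Factor-epoch matrix `(start, end, factor)` for the subset.
#' @export
split_drive <- function(drives, name, ids, fac = matrix(0, 0, 3)) {
  d <- drives[[name]]
  if (is.null(d)) stop("unknown drive: ", name)
  rest <- setdiff(d$tgt, ids)
  sub <- d
  sub$tgt <- as.integer(intersect(d$tgt, ids))
  sub$name <- paste0(name, "@sub")
  sub$fac <- rbind(sub$fac, fac)
  d$tgt <- as.integer(rest)
  drives[[name]] <- d
  drives[[sub$name]] <- sub
  drives
}

#' Build the extrinsic drive set for a network
#'
#' Instantiates the drive catalogue for a built network in one of the two
#' cortical states. Slow-wave drives carry the 1-Hz square-wave modulation
#' in both dopamine conditions; the 20-Hz beta modulation of the
#' activation state is enabled with `beta = TRUE` (used for the
#' dopamine-depleted condition). When the network has embedded action
#' channels, the striatal drives are split per action pool so selection
#' schedules can address them individually.
#'
#' @param net A [build_network()] network.
#' @param state `"activation"` or `"slow_wave"`.
#' @param beta Apply 20-Hz modulation to the cortical activation drives.
#' @param rate_factors Optional named numeric vector of multiplicative
#'   factors on drive base rates (names = drive names, e.g. `"CTX-MSN_D2"`).
#' @return A list of drive entries (class `bg_drives`).
#' @export
default_drives <- function(net, state = c("activation", "slow_wave"),
                           beta = FALSE, rate_factors = NULL) {
  state <- match.arg(state)
  dcat <- net$config$drives
  off <- net$offsets
  out <- list()
  for (k in seq_len(nrow(dcat))) {
    row <- dcat[k, ]
    pop <- row$target
    base <- if (state == "activation") row$rate_act else row$rate_slow
    amp <- if (state == "activation") row$amp_act else row$amp_slow
    fmod <- if (state == "activation") (if (beta) 20 else 0) else 1
    if (amp == 0) fmod <- 0
    if (!is.null(rate_factors) && row$name %in% names(rate_factors))
      base <- base * rate_factors[[row$name]]
    ids <- off[[pop]] + seq_len(net$sizes[[pop]])  # 1-based global
    lab <- if (!is.null(net$labels)) net$labels[[pop]] else NULL
    groups <- if (!is.null(lab) && any(lab > 0))
      split(ids, lab) else list(`0` = ids)
    for (g in names(groups)) {
      nm <- if (g == "0") row$name else paste0(row$name, "@A", g)
      out[[nm]] <- drive_entry(nm, groups[[g]], base, amp, fmod,
                               row$ampa_g0, row$ampa_tau,
                               row$nmda_g0, row$nmda_tau, row$E_rev)
    }
  }
  structure(out, class = "bg_drives")
}

#' Stepwise cortical-input sweep
#'
#' One drive set per factor, scaling the cortical inputs to the striatal
#' projection neurons, interneurons and the subthalamic nucleus (the
#' protocol probing how striatal inhibition controls firing at varying
#' cortical drive, factors 0.8 to 1.5).
#'
#' @param net Network.
#' @param factors Positive factors.
#' @param ... Passed to [default_drives()].
#' @return Named list of drive sets, one per factor.
#' @export
stepwise_input_sweep <- function(net, factors = seq(0.8, 1.5, by = 0.1), ...) {
  stopifnot(all(factors > 0))
  ctx <- c("CTX-MSN_D1", "CTX-MSN_D2", "CTX-FSN", "CTX-STN")
  sets <- lapply(factors, function(f) {
    rf <- stats::setNames(rep(f, length(ctx)), ctx)
    default_drives(net, rate_factors = rf, ...)
  })
  names(sets) <- as.character(factors)
  sets
}

#' Action-selection trial schedules
#'
#' A selection trial is a 100-ms burst on the channelised striatal drives
#' followed by a 900-ms rest with background drive only. A schedule covers
#' a grid of burst-factor combinations for the two competing actions with
#' a fixed number of trials per combination.
#'
#' @param factors1,factors2 Burst factors (multiples of the base drive
#'   rate, >= 1) for action 1 and 2.
#' @param trials_per_cell Trials per factor combination (80 in the full
#'   protocol).
#' @param burst_ms,rest_ms Burst and rest durations (ms).
#' @param start_ms Settling time before the first trial (ms).
#' @return data.frame of class `trial_schedule` with one row per trial:
#'   `trial`, `i`, `j`, `f1`, `f2`, `onset`.
#' @export
build_selection_trials <- function(factors1, factors2, trials_per_cell = 80,
                                   burst_ms = 100, rest_ms = 900,
                                   start_ms = 1000) {
  stopifnot(length(factors1) > 0, length(factors2) > 0,
            all(factors1 >= 1), all(factors2 >= 1), burst_ms > 0)
  grid <- expand.grid(i = seq_along(factors1), j = seq_along(factors2))
  sch <- grid[rep(seq_len(nrow(grid)), each = trials_per_cell), ]
  sch$rep <- rep(seq_len(trials_per_cell), times = nrow(grid))
  sch$trial <- seq_len(nrow(sch))
  sch$f1 <- factors1[sch$i]
  sch$f2 <- factors2[sch$j]
  trial_ms <- burst_ms + rest_ms
  sch$onset <- start_ms + (sch$trial - 1) * trial_ms
  attr(sch, "burst_ms") <- burst_ms
  attr(sch, "trial_ms") <- trial_ms
  class(sch) <- c("trial_schedule", "data.frame")
  rownames(sch) <- NULL
  sch
}

#' @rdname build_selection_trials
#' @param drives A [default_drives()] set built from a channelised network.
#' @param schedule A `trial_schedule`.
#' @param fsn_burst Also burst the interneuron drive with the larger of the
#'   two action factors during the selection phase. Off by default: with
#'   the catalogued depressing feed-forward synapses an interneuron burst
#'   acts mostly through global suppression of the indirect-pathway
#'   striatal neurons, masking the channel structure.
#' @return The drive set with burst factor epochs attached.
#' @export
apply_selection_schedule <- function(drives, schedule, fsn_burst = FALSE) {
  burst <- attr(schedule, "burst_ms")
  ep <- function(f) cbind(schedule$onset, schedule$onset + burst, f)
  # action-1 command bursts Go pool 1 (direct) and NoGo pool 2 (indirect)
  map <- list(`CTX-MSN_D1@A1` = schedule$f1, `CTX-MSN_D1@A2` = schedule$f2,
              `CTX-MSN_D2@A2` = schedule$f1, `CTX-MSN_D2@A1` = schedule$f2)
  for (nm in names(map)) {
    if (!is.null(drives[[nm]])) {
      keep <- map[[nm]] != 1
      drives[[nm]]$fac <- rbind(drives[[nm]]$fac, ep(map[[nm]])[keep, , drop = FALSE])
    }
  }
  if (fsn_burst && !is.null(drives[["CTX-FSN"]])) {
    f <- pmax(schedule$f1, schedule$f2)
    drives[["CTX-FSN"]]$fac <- rbind(drives[["CTX-FSN"]]$fac,
                                     ep(f)[f != 1, , drop = FALSE])
  }
  drives
}

#' Transient subthalamic stop pulse
#'
#' Adds a 100-ms additive rate increase to the subthalamic drive
#' (hyperdirect-pathway burst), by convention expressed as a multiple of
#' the drive's base rate.
#'
#' @param drives Drive set.
#' @param onsets Pulse onset times (ms).
#' @param duration Pulse length (ms, default 100 to match the striatal
#'   selection burst).
#' @param factor Added rate as a multiple of the base rate (0 = no pulse).
#' @export
stn_stop_pulse <- function(drives, onsets, duration = 100, factor = 1) {
  stopifnot(duration > 0, factor >= 0)
  d <- drives[["CTX-STN"]]
  if (is.null(d)) stop("drive set has no subthalamic drive")
  if (factor > 0)
    d$add <- rbind(d$add, cbind(onsets, onsets + duration, factor * d$base))
  drives[["CTX-STN"]] <- d
  drives
}
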