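#' Configuration editing helpers
#'
#' Small utilities for the perturbation and robustness experiments:
#' changing a connection's fan-in, adding a connection (referencing an
#' existing synapse-catalogue row), or changing a synaptic time constant.
#'
#' @param config A [bg_config()].
#' @param name Connection / synapse name.
#' @param fan_in New in-degree.
#' @export
set_connection_fan_in <- function(config, name, fan_in) {
  j <- match(name, config$connections$name)
  if (is.na(j)) stop("unknown connection: ", name)
  config$connections$fan_in[j] <- as.integer(fan_in)
  config
}

#' @rdname set_connection_fan_in
#' @param pre,post Population names.
#' @param synapse Synapse-catalogue row to use.
#' @param window,pre_fraction Spatial window and eligible presynaptic
#'   fraction.
#' @export
add_connection <- function(config, name, pre, post, fan_in, synapse,
                           window = NA, pre_fraction = 1) {
  config$connections <- rbind(
    config$connections,
    data.frame(name = name, pre = pre, post = post,
               fan_in = as.integer(fan_in), window = window,
               pre_fraction = pre_fraction, synapse = synapse))
  config
}

#' @rdname set_connection_fan_in
#' @param tau_syn New decay constant (ms).
#' @export
set_synapse_tau <- function(config, name, tau_syn) {
  j <- match(name, config$synapses$name)
  if (is.na(j)) stop("unknown synapse: ", name)
  config$synapses$tau_syn[j] <- tau_syn
  config
}

# Build a network for a named dopamine condition.
condition_network <- function(N, alpha = 0.8, seed = 1L, channels = NULL,
                              restore = character(), config = NULL) {
  cfg <- config %||% bg_config(N)
  if (alpha != 0.8 || length(restore))
    cfg <- apply_depletion(cfg, alpha, restore = restore)
  build_network(cfg, seed = seed, channels = channels)
}

# Metrics for one spike record.
condition_metrics <- function(spk, transient, n_units = 24, nwin = 256,
                              band = c(15, 25)) {
  rates <- population_rates(spk, transient)
  rows <- lapply(names(spk$sizes), function(pop) {
    tr <- spike_trains(spk, pop, seq_len(min(spk$sizes[[pop]], n_units)))
    counts <- bin_spikes(tr, transient, spk$duration)
    ff <- if (sum(counts) > 0) fano_factor(counts) else NA_real_
    oi <- if (sum(lengths(tr)) > 0)
      oscillation_index(tr, transient, spk$duration, band = band,
                        nwin = nwin) else NA_real_
    data.frame(population = pop, rate = unname(rates[pop]),
               cv = isi_cv(tr), fano = ff, oi = oi)
  })
  do.call(rbind, rows)
}

# Population-level pair summaries (coherence at the band peak + phase).
pair_metrics <- function(spk, transient, pairs, band = c(15, 25),
                         nwin = 256) {
  all_times <- function(pop) sort(spk$t[spk$pop == pop])
  rows <- lapply(pairs, function(pr) {
    a <- all_times(pr[1]); b <- all_times(pr[2])
    ph <- tryCatch(phase_relation(a, b, transient, spk$duration, band = band),
                   error = function(e) list(circ_mean = NA, resultant = NA))
    # unit-pair coherence over the most active units of each population,
    # summarised at the bin nearest the band centre
    ua <- spike_trains(spk, pr[1])
    ub <- spike_trains(spk, pr[2])
    ua <- ua[order(-lengths(ua))][seq_len(min(8, length(ua)))]
    ub <- ub[order(-lengths(ub))][seq_len(min(8, length(ub)))]
    fc <- mean(band)
    cohs <- mapply(function(x, y) {
      co <- tryCatch(suppressWarnings(
        spike_coherence(x, y, transient, spk$duration, nwin = nwin)),
        error = function(e) NULL)
      if (is.null(co)) return(c(NA, NA))
      c(co$coh[which.min(abs(co$freq - fc))], co$signif)
    }, ua, ub)
    data.frame(pair = paste(pr[1], pr[2], sep = "-"),
               coh_band = mean(cohs[1, ], na.rm = TRUE),
               signif = mean(cohs[2, ], na.rm = TRUE),
               phase = ph$circ_mean, resultant = ph$resultant)
  })
  do.call(rbind, rows)
}

#' Dynamics validation experiment
#'
#' Simulates the control and dopamine-depleted network in a cortical state
#' and tabulates, per population, the mean rate, interspike-interval CV,
#' population Fano factor (synchrony) and oscillation index, plus
#' coherence/phase summaries for the subthalamo-pallidal pairs. The
#' depleted condition uses the 20-Hz beta-modulated activation drive (or
#' the 1-Hz modulation in the slow-wave state).
#'
#' @param N Network size.
#' @param state `"activation"` or `"slow_wave"`.
#' @param duration,transient Simulated and discarded time (ms).
#' @param seed Seed (build and simulation).
#' @param alphas Occupancies for the conditions (control 0.8, lesioned 0).
#' @return List of data.frames `metrics` and `pairs` with a `condition`
#'   column.
#' @export
run_dynamics_validation <- function(N = 10000, state = "activation",
                                    duration = 4000, transient = 1000,
                                    seed = 1L, alphas = c(control = 0.8,
                                                          lesioned = 0)) {
  band <- if (state == "activation") c(15, 25) else c(0.5, 1.5)
  nwin <- if (state == "activation") 256 else 2048
  pairs <- list(c("STN", "GPe_TI"), c("STN", "GPe_TA"),
                c("GPe_TI", "GPe_TA"))
  out_m <- list(); out_p <- list()
  for (cond in names(alphas)) {
    alpha <- alphas[[cond]]
    net <- condition_network(N, alpha, seed = seed)
    drv <- default_drives(net, state = state, beta = alpha < 0.8)
    spk <- simulate(net, drv, duration = duration, seed = seed + 17L)
    m <- condition_metrics(spk, transient, nwin = nwin, band = band)
    m$condition <- cond
    p <- pair_metrics(spk, transient, pairs, band = band, nwin = nwin)
    p$condition <- cond
    out_m[[cond]] <- m
    out_p[[cond]] <- p
  }
  list(metrics = do.call(rbind, out_m), pairs = do.call(rbind, out_p))
}

#' Striatal inhibition sweep
#'
#' Reduced striatal module (about 3000 projection neurons at the default
#' scale) driven with stepwise-scaled cortical input under different
#' inhibition arms: all inhibition, collaterals only, feed-forward
#' (interneuron) only, feed-forward with the depressing synapse made
#' static, arkypallidal only, and none.
#'
#' @param N Total network size (default gives ~3000 projection neurons).
#' @param factors Cortical input factors.
#' @param arms Subset of arms to run.
#' @param duration,transient ms.
#' @param seed Seed.
#' @return data.frame `(arm, factor, population, rate)`.
#' @export
run_inhibition_sweep <- function(N = 3160,
                                 factors = seq(0.8, 1.5, by = 0.1),
                                 arms = c("all", "msn_only", "fsn_only",
                                          "fsn_static", "ta_only", "none"),
                                 duration = 3000, transient = 500,
                                 seed = 1L) {
  coll <- c("MSN_D1-MSN_D1", "MSN_D1-MSN_D2", "MSN_D2-MSN_D1",
            "MSN_D2-MSN_D2")
  ffw <- c("FSN-MSN_D1", "FSN-MSN_D2")
  ta <- c("GPe_TA-MSN_D1", "GPe_TA-MSN_D2")
  off_for <- list(all = character(),
                  msn_only = c(ffw, ta),
                  fsn_only = c(coll, ta),
                  fsn_static = c(coll, ta),
                  ta_only = c(coll, ffw),
                  none = c(coll, ffw, ta))
  base_net <- build_network(bg_config(N), seed = seed)
  out <- list()
  for (arm in arms) {
    net <- base_net
    for (nm in off_for[[arm]]) net <- scale_connection(net, nm, 0)
    if (arm == "fsn_static")
      for (nm in ffw) net$conns[[nm]]$force_static <- TRUE
    for (f in factors) {
      drv <- default_drives(net, rate_factors = stats::setNames(
        rep(f, 4), c("CTX-MSN_D1", "CTX-MSN_D2", "CTX-FSN", "CTX-STN")))
      spk <- simulate(net, drv, duration = duration, seed = seed + 101L)
      r <- population_rates(spk, transient)
      out[[length(out) + 1L]] <- data.frame(
        arm = arm, factor = f, population = c("MSN_D1", "MSN_D2"),
        rate = unname(r[c("MSN_D1", "MSN_D2")]))
    }
  }
  do.call(rbind, out)
}

#' Non-connected-cluster contrast
#'
#' Activates a fraction of the striatal projection neurons with a 100-ms
#' burst, either a random subset or a carved non-connected cluster, and
#' returns the burst-phase rates of the activated pools. Lateral
#' inhibition predicts the non-connected pool fires higher.
#'
#' @param N Module size.
#' @param fraction Activated fraction of each projection population.
#' @param burst_factor Burst multiple of the base cortical rate.
#' @param duration Trial length; the burst occupies the last 100 ms
#'   before `duration`.
#' @param seed Seed.
#' @return data.frame `(scenario, population, rate)`.
#' @export
run_cluster_contrast <- function(N = 3160, fraction = 0.1, burst_factor = 3,
                                 duration = 1500, seed = 1L) {
  burst <- cbind(duration - 100, duration, burst_factor)
  out <- list()
  for (scenario in c("random", "nonconnected")) {
    net <- build_network(bg_config(N), seed = seed)
    if (scenario == "nonconnected")
      net <- carve_nonconnected_clusters(net, fraction, seed = seed + 3L)
    drv <- default_drives(net)
    pools <- list()
    for (pop in c("MSN_D1", "MSN_D2")) {
      nn <- net$sizes[[pop]]
      k <- max(1L, round(fraction * nn))
      loc <- if (scenario == "nonconnected") seq_len(k)
             else withr_seed(seed + 9L, sample.int(nn, k))
      ids <- net$offsets[[pop]] + loc
      pools[[pop]] <- ids
      drv <- split_drive(drv, paste0("CTX-", pop), ids, fac = burst)
    }
    spk <- simulate(net, drv, duration = duration, seed = seed + 77L)
    for (pop in c("MSN_D1", "MSN_D2")) {
      sel <- spk$id %in% pools[[pop]] & spk$t >= duration - 100
      rate <- sum(sel) / length(pools[[pop]]) / 0.1
      out[[length(out) + 1L]] <- data.frame(scenario = scenario,
                                            population = pop, rate = rate)
    }
  }
  do.call(rbind, out)
}

#' Action-selection grid experiment
#'
#' Runs a schedule of selection trials on a channelised network and
#' classifies every trial against the control baseline. Arms toggle the
#' indirect pathway, remove collateral or feed-forward inhibition, add the
#' subthalamic stop pulse, or remove the arkypallidal projection.
#'
#' @param N Network size.
#' @param alpha Dopamine occupancy of the tested network.
#' @param factors1,factors2 Burst-factor grids.
#' @param trials_per_cell Trials per grid cell.
#' @param pool_fraction Striatal action-pool fraction.
#' @param include_indirect Embed the indirect pathway channels.
#' @param scale0 Connection names silenced in this arm.
#' @param stn_pulse Stop-pulse factor (0 = none).
#' @param seed Seed.
#' @param baseline Optional precomputed control baseline (Hz per action
#'   pool); computed from a control run when missing.
#' @return List: `outcomes` (per trial), `summary`
#'   ([outcome_grid_summary()]), `baseline`.
#' @export
run_selection_grid <- function(N = 4000, alpha = 0.8,
                               factors1 = c(1.5, 2.5), factors2 = c(1.5, 2.5),
                               trials_per_cell = 5, pool_fraction = 0.25,
                               include_indirect = TRUE,
                               scale0 = character(), stn_pulse = 0,
                               seed = 1L, baseline = NULL) {
  spec <- action_channel_spec(pool_fraction = pool_fraction,
                              include_indirect = include_indirect)
  net <- condition_network(N, alpha, seed = seed, channels = spec)
  for (nm in scale0) net <- scale_connection(net, nm, 0)
  sch <- build_selection_trials(factors1, factors2, trials_per_cell)
  duration <- max(sch$onset) + attr(sch, "trial_ms")
  beta_mod <- alpha < 0.8
  if (is.null(baseline)) {
    bnet <- condition_network(N, 0.8, seed = seed, channels = spec)
    bspk <- simulate(bnet, default_drives(bnet), duration = 2000,
                     seed = seed + 5L)
    baseline <- snr_pool_rates(bspk, 500, 2000)
  }
  drv <- default_drives(net, beta = beta_mod)
  drv <- apply_selection_schedule(drv, sch)
  if (stn_pulse > 0)
    drv <- stn_stop_pulse(drv, onsets = sch$onset, factor = stn_pulse)
  spk <- simulate(net, drv, duration = duration, seed = seed + 13L)
  burst <- attr(sch, "burst_ms")
  sch$outcome <- vapply(seq_len(nrow(sch)), function(k) {
    rates <- snr_pool_rates(spk, sch$onset[k], sch$onset[k] + burst)
    classify_selection(rates, baseline)
  }, character(1))
  list(outcomes = sch, summary = outcome_grid_summary(sch),
       baseline = baseline)
}

# Mean SNr rate per action pool over a window (Hz).
snr_pool_rates <- function(spk, t0, t1) {
  lab <- spk$labels$SNr
  if (is.null(lab)) stop("network has no action channels")
  off <- spk$offsets[["SNr"]]
  nn <- spk$sizes[["SNr"]]
  sel <- spk$id > off & spk$id <= off + nn & spk$t >= t0 & spk$t < t1
  loc <- spk$id[sel] - off
  vapply(sort(unique(lab)), function(a) {
    sum(lab[loc] == a) / sum(lab == a) / ((t1 - t0) / 1000)
  }, numeric(1))
}

#' Dopamine-parameter restoration sweep
#'
#' Starting from the fully depleted network, restores one modulated
#' parameter at a time to its control value (same seeds throughout) and
#' reports the change in synchrony (Fano factor) and oscillation index
#' per population relative to the depleted baseline.
#'
#' @param N Network size.
#' @param targets Modulation-entry names to restore (default: all).
#' @param duration,transient ms.
#' @param seed Seed.
#' @return data.frame `(target, population, d_fano, d_oi)`.
#' @export
run_restoration_sweep <- function(N = 6000, targets = NULL,
                                  duration = 3000, transient = 500,
                                  seed = 1L) {
  tab <- modulation_table()
  if (is.null(targets)) targets <- tab$name
  base <- restoration_metrics(N, character(), duration, transient, seed)
  out <- list()
  for (tg in targets) {
    m <- restoration_metrics(N, tg, duration, transient, seed)
    out[[tg]] <- data.frame(target = tg, population = m$population,
                            d_fano = m$fano - base$fano,
                            d_oi = m$oi - base$oi)
  }
  do.call(rbind, out)
}

restoration_metrics <- function(N, restore, duration, transient, seed) {
  net <- condition_network(N, 0, seed = seed, restore = restore)
  drv <- default_drives(net, beta = TRUE)
  spk <- simulate(net, drv, duration = duration, seed = seed + 17L)
  condition_metrics(spk, transient)
}

#' Connection / nucleus perturbation screen
#'
#' On top of the depleted beta-driven network, scales single connections
#' (x0 / x5) or injects currents into single nuclei (a silencing
#' hyperpolarisation and its matched positive counterpart) and reports
#' synchrony/oscillation deltas per population relative to the unperturbed
#' depleted network.
#'
#' @param N Network size.
#' @param connections Named list: connection name -> factor vector.
#' @param nuclei Character vector of populations to silence/excite.
#' @param duration,transient ms.
#' @param seed Seed.
#' @return data.frame `(arm, population, d_fano, d_oi)`.
#' @export
run_perturbation_screen <- function(N = 6000,
                                    connections = list(),
                                    nuclei = character(),
                                    duration = 3000, transient = 500,
                                    seed = 1L) {
  net0 <- condition_network(N, 0, seed = seed)
  drv <- default_drives(net0, beta = TRUE)
  run_one <- function(net, injections = list()) {
    spk <- simulate(net, drv, duration = duration, seed = seed + 17L,
                    injections = injections)
    condition_metrics(spk, transient)
  }
  base <- run_one(net0)
  out <- list()
  add <- function(arm, m) {
    out[[arm]] <<- data.frame(arm = arm, population = m$population,
                              d_fano = m$fano - base$fano,
                              d_oi = m$oi - base$oi)
  }
  for (nm in names(connections)) {
    for (f in connections[[nm]]) {
      net <- scale_connection(net0, nm, f)
      add(paste0(nm, " x", f), run_one(net))
    }
  }
  for (pop in nuclei) {
    amp <- find_silencing_current(net0, drv, pop, probe_ms = duration / 3,
                                  seed = seed + 23L)
    add(paste0(pop, " silent"), run_one(net0, list(inject_current(pop, amp))))
    add(paste0(pop, " excited"), run_one(net0, list(inject_current(pop, -amp))))
  }
  do.call(rbind, out)
}

#' Robustness sweeps
#'
#' Structural-parameter sweeps probing model robustness: the arkypallidal
#' synaptic decay onto projection neurons (oscillation onset in striatum),
#' the projection-neuron fan-in onto arkypallidal cells (pallidal phase
#' reversal), the corticostriatal / cortico-subthalamic modulation lags,
#' and the pallidal fan-in mix onto arkypallidal cells.
#'
#' @param N Network size.
#' @param sweep One of `"ta_msn_tau"`, `"msn_ta_fanin"`,
#'   `"ctx_striatum_delay"`, `"ctx_stn_delay"`, `"ta_fanin_mix"`.
#' @param values Sweep values (tau ms; fan-in counts; delays ms; or for
#'   the mix, a list of `c(ti, ta)` fan-in pairs).
#' @param alpha Dopamine occupancy (control for the tau sweep, depleted
#'   for the phase sweeps).
#' @param duration,transient ms.
#' @param seed Seed.
#' @return data.frame with one row per value (per population where
#'   relevant) and the measured metric.
#' @export
run_robustness_checks <- function(N = 6000, sweep, values,
                                  alpha = if (sweep == "ta_msn_tau") 0.8 else 0,
                                  duration = 3000, transient = 500,
                                  seed = 1L) {
  if (length(values) == 0) return(data.frame())
  out <- list()
  for (k in seq_along(values)) {
    v <- values[[k]]
    cfg <- bg_config(N)
    phase <- c()
    if (sweep == "ta_msn_tau") {
      cfg <- set_synapse_tau(cfg, "GPe_TA-MSN_D1", v)
      cfg <- set_synapse_tau(cfg, "GPe_TA-MSN_D2", v)
    } else if (sweep == "msn_ta_fanin") {
      cfg <- add_connection(cfg, "MSN_D2-GPe_TA", "MSN_D2", "GPe_TA", v,
                            synapse = "MSN_D2-GPe_TI")
    } else if (sweep == "ta_fanin_mix") {
      cfg <- set_connection_fan_in(cfg, "GPe_TI-GPe_TA", v[1])
      cfg <- set_connection_fan_in(cfg, "GPe_TA-GPe_TA", v[2])
    } else if (sweep == "ctx_striatum_delay") {
      phase <- c("CTX-MSN_D1", "CTX-MSN_D2", "CTX-FSN")
    } else if (sweep == "ctx_stn_delay") {
      phase <- "CTX-STN"
    } else stop("unknown sweep: ", sweep)
    net <- condition_network(N, alpha, seed = seed, config = cfg)
    drv <- default_drives(net, beta = alpha < 0.8)
    for (nm in phase) drv[[nm]]$phase <- v
    spk <- simulate(net, drv, duration = duration, seed = seed + 17L)
    if (sweep == "ta_msn_tau") {
      for (pop in c("MSN_D1", "MSN_D2")) {
        tr <- spike_trains(spk, pop, seq_len(min(spk$sizes[[pop]], 24)))
        oi <- if (sum(lengths(tr)) > 0)
          oscillation_index(tr, transient, duration) else NA_real_
        out[[length(out) + 1L]] <- data.frame(sweep = sweep, value = v,
                                              population = pop, metric = "oi",
                                              measure = oi)
      }
    } else {
      pr <- if (sweep == "msn_ta_fanin" || sweep == "ta_fanin_mix")
        c("GPe_TI", "GPe_TA") else c("STN", "GPe_TI")
      ph <- pair_metrics(spk, transient, list(pr))
      out[[length(out) + 1L]] <- data.frame(
        sweep = sweep, value = if (is.list(values)) k else v,
        population = ph$pair, metric = "phase", measure = ph$phase)
    }
  }
  do.call(rbind, out)
}
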