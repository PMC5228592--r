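test_that("square-wave-modulated drives keep the catalogued mean rate", {
  ev <- modulated_poisson(100, amp = 0, duration = 1e5, seed = 1)
  expect_lt(abs(length(ev) / 100 - 100) / 100, 0.02)
  ev <- modulated_poisson(250, amp = 0.35, freq = 20, duration = 1e5, seed = 2)
  expect_lt(abs(length(ev) / 100 - 250) / 250, 0.02)
  expect_identical(ev, modulated_poisson(250, 0.35, 20, 1e5, seed = 2))
  expect_error(modulated_poisson(100, amp = 1), "amplitude")
})

test_that("half-cycle event counts follow the alternating Poisson rates", {
  v <- 250; a <- 0.35; f <- 20
  ev <- modulated_poisson(v, a, f, duration = 5e4, seed = 3)
  half <- 500 / f
  idx <- floor(ev / half)
  hi <- table(factor(idx[idx %% 2 == 0], levels = seq(0, 1998, by = 2)))
  lo <- table(factor(idx[idx %% 2 == 1], levels = seq(1, 1999, by = 2)))
  lam_hi <- v * (1 + a) * half / 1000
  lam_lo <- v * (1 - a) * half / 1000
  gof <- function(counts, lam) {
    br <- unique(c(-Inf, qpois(seq(0.1, 0.9, by = 0.2), lam), Inf))
    obs <- table(cut(as.numeric(counts), br))
    pr <- diff(ppois(br, lam))
    suppressWarnings(chisq.test(obs, p = pr / sum(pr))$p.value)
  }
  expect_gt(gof(hi, lam_hi), 0.01)
  expect_gt(gof(lo, lam_lo), 0.01)
  # means differ in the right direction
  expect_gt(mean(hi), mean(lo))
})

test_that("drive sets instantiate the catalogue per state and condition", {
  net <- small_net()
  act <- default_drives(net, state = "activation", beta = FALSE)
  expect_equal(act[["CTX-MSN_D2"]]$base, 722)
  expect_equal(act[["CTX-MSN_D2"]]$fmod, 0)       # control: no beta
  les <- default_drives(net, state = "activation", beta = TRUE)
  expect_equal(les[["CTX-STN"]]$fmod, 20)
  expect_equal(les[["CTX-STN"]]$amp, 0.35)
  sw <- default_drives(net, state = "slow_wave")
  expect_equal(sw[["CTX-MSN_D1"]]$base, 448)
  expect_equal(sw[["CTX-MSN_D1"]]$fmod, 1)        # slow wave in both
  expect_equal(sw[["EXT-SNr"]]$fmod, 0)           # unmodulated externals
  expect_equal(length(act[["CTX-FSN"]]$tgt), net$sizes[["FSN"]])
})

test_that("stepwise sweeps scale only the cortical drives", {
  net <- small_net()
  sets <- stepwise_input_sweep(net, factors = c(0.8, 1.0, 1.5))
  expect_equal(length(sets), 3)
  expect_equal(sets[["1.5"]][["CTX-MSN_D2"]]$base, 722 * 1.5)
  expect_equal(sets[["1"]][["CTX-MSN_D2"]]$base, 722)
  expect_equal(sets[["1.5"]][["EXT-SNr"]]$base, 1800)
})

test_that("selection schedules cover the factor grid", {
  sch <- build_selection_trials(seq(1, 3, length.out = 7),
                                seq(1, 3, length.out = 7),
                                trials_per_cell = 80)
  expect_equal(nrow(sch), 3920)
  expect_equal(length(unique(paste(sch$i, sch$j))), 49)
  one <- build_selection_trials(1, 1, trials_per_cell = 1, start_ms = 0)
  expect_equal(nrow(one), 1)
  expect_equal(one$onset, 0)
  expect_equal(attr(one, "trial_ms"), 1000)
  expect_error(build_selection_trials(numeric(), 1))
})

test_that("burst epochs land on the channelised pools", {
  spec <- action_channel_spec(pool_fraction = 0.4)
  net <- suppressWarnings(build_network(bg_config(2000), seed = 2,
                                        channels = spec))
  sch <- build_selection_trials(2, 3, trials_per_cell = 2)
  drv <- apply_selection_schedule(default_drives(net), sch)
  # action-1 factor bursts Go pool 1 and NoGo pool 2
  expect_equal(nrow(drv[["CTX-MSN_D1@A1"]]$fac), 2)
  expect_equal(unique(drv[["CTX-MSN_D1@A1"]]$fac[, 3]), 2)
  expect_equal(unique(drv[["CTX-MSN_D2@A2"]]$fac[, 3]), 2)
  expect_equal(unique(drv[["CTX-MSN_D1@A2"]]$fac[, 3]), 3)
  expect_equal(unname(drv[["CTX-MSN_D1@A1"]]$fac[1, 2] -
                        drv[["CTX-MSN_D1@A1"]]$fac[1, 1]), 100)
  # a unit factor attaches no epochs
  null_sch <- build_selection_trials(1, 1, trials_per_cell = 2)
  drv0 <- apply_selection_schedule(default_drives(net), null_sch)
  expect_equal(nrow(drv0[["CTX-MSN_D1@A1"]]$fac), 0)
})

test_that("the stop pulse adds rate to the subthalamic drive only", {
  net <- small_net()
  drv <- default_drives(net)
  p0 <- stn_stop_pulse(drv, onsets = 500, factor = 0)
  expect_equal(nrow(p0[["CTX-STN"]]$add), 0)
  p1 <- stn_stop_pulse(drv, onsets = c(500, 1500), duration = 100, factor = 2)
  expect_equal(nrow(p1[["CTX-STN"]]$add), 2)
  expect_equal(unname(p1[["CTX-STN"]]$add[1, ]), c(500, 600, 2 * 250))
  expect_equal(nrow(p1[["CTX-MSN_D1"]]$add), 0)
})
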