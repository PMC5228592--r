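test_that("quadratic-family derivatives match hand-evaluated forms", {
  d2 <- neuron_params("MSN_D2")
  # resting potential with no input is a fixed point
  expect_equal(unname(qif_derivatives(neuron_state(d2$v_r, 0), d2, 0)),
               c(0, 0))
  d1 <- neuron_params("MSN_D1")
  # (V - v_r)(V - v_th) = (-60+78.2)(-60+29.7); du = a*b*(V - v_r)
  dv_expect <- (18.2 * (-30.3) + 100) / 15.2
  got <- qif_derivatives(neuron_state(-60, 0), d1, 100)
  expect_equal(unname(got["dV"]), dv_expect, tolerance = 1e-12)
  expect_equal(unname(got["du"]), 0.01 * (-20 * 18.2), tolerance = 1e-12)
  expect_error(qif_derivatives(neuron_state(0, 0), d1, NaN), "non-finite")
})

test_that("fast-spiking recovery uses the cubic branch below v_b", {
  fsn <- neuron_params("FSN")
  expect_equal(fsn_recovery_derivative(neuron_state(fsn$v_b, 0), fsn), 0)
  expect_equal(fsn_recovery_derivative(neuron_state(-40, 7), fsn),
               -fsn$a * 7)
  # cubic branch at V = -60, u = 5: a*(b*(-5)^3 - 5)
  expect_equal(fsn_recovery_derivative(neuron_state(-60, 5), fsn),
               0.2 * (0.025 * (-5)^3 - 5), tolerance = 1e-12)
})

test_that("adaptive-exponential derivatives and the adaptation gate", {
  ti <- neuron_params("GPe_TI")
  # algebraic balance: dV = 0 when w absorbs leak + exponential + input
  w0 <- ti$g_L * ti$Delta_T * exp((ti$E_L - ti$V_T) / ti$Delta_T) + 12
  expect_equal(unname(adex_derivatives(neuron_state(ti$E_L, w0), ti, 12)["dV"]),
               0, tolerance = 1e-12)
  dv_expect <- (-1 * (-60 + 55.1) + 1 * 1.7 * exp((-60 + 54.7) / 1.7)) / 40 + 12 / 40
  got <- adex_derivatives(neuron_state(-60, 0), ti, 12)
  expect_equal(unname(got["dV"]), dv_expect, tolerance = 1e-12)
  expect_equal(unname(got["du"]), (2.5 * (-60 + 55.1)) / 20, tolerance = 1e-12)
  # subthalamic gate: above -70 mV the subthreshold adaptation is off
  stn <- neuron_params("STN")
  expect_equal(unname(adex_derivatives(neuron_state(-60, 10), stn)["du"]),
               -10 / 333, tolerance = 1e-12)
  expect_lt(unname(adex_derivatives(neuron_state(-85, 0), stn)["du"]), 0)
})

test_that("spike resets follow each family's rule", {
  d2 <- neuron_params("MSN_D2")
  st <- apply_spike_reset(neuron_state(41, 5), d2)
  expect_equal(st$V, -60)
  expect_equal(st$u, 5 + 91)
  ta <- neuron_params("GPe_TA")
  st <- apply_spike_reset(neuron_state(16, 3), ta)
  expect_equal(st$V, -60)
  expect_equal(st$u, 3 + 105)
  stn <- neuron_params("STN")
  # depolarised rebound reset when w < 0: V = -70 + max(-30 - 15, 20)
  st <- apply_spike_reset(neuron_state(16, -30), stn)
  expect_equal(st$V, -70 + 20)
  st <- apply_spike_reset(neuron_state(16, -30), stn, rule = "min")
  expect_equal(st$V, -70 + min(-45, 20))
  st <- apply_spike_reset(neuron_state(16, 4), stn)
  expect_equal(st$V, -70)
})

test_that("heterogeneity sampling is calibrated and reproducible", {
  d1 <- neuron_params("MSN_D1")
  degenerate <- sample_heterogeneity(d1, heterogeneity_spec(0, 0, 1), 5)
  expect_true(all(degenerate$C == d1$C))
  expect_true(all(degenerate$threshold == d1$v_th))
  h <- sample_heterogeneity(d1, heterogeneity_spec(seed = 7), 1e4)
  expect_true(all(h$C > 0))
  expect_lt(abs(mean(h$C) - 15.2) / 15.2, 0.01)
  expect_lt(abs(sd(h$C) - 1.52) / 1.52, 0.05)
  expect_lt(abs(sd(h$threshold) - 1), 0.05)
  expect_identical(h, sample_heterogeneity(d1, heterogeneity_spec(seed = 7), 1e4))
  expect_error(sample_heterogeneity(d1, heterogeneity_spec(), 0))
})

test_that("pallidal pacemakers fire at their calibrated in-vitro rates", {
  ti <- fi_curve(neuron_params("GPe_TI"), 12, duration = 5000)
  expect_lt(abs(ti$rate - 18), 1)
  ta <- fi_curve(neuron_params("GPe_TA"), 1, duration = 5000)
  expect_lt(abs(ta$rate - 8), 1)
  # far below rheobase nothing fires
  expect_equal(fi_curve(neuron_params("SNr"), -200, duration = 2000)$rate, 0)
})

test_that("arkypallidal f-I slope is flatter than prototypical", {
  I <- seq(0, 100, by = 25)
  ti <- fi_curve(neuron_params("GPe_TI"), I, duration = 4000)$rate
  ta <- fi_curve(neuron_params("GPe_TA"), I, duration = 4000)$rate
  fit <- function(r) coef(lm(r ~ I))[2]
  expect_lt(fit(ta), fit(ti))
  # adaptive-exponential f-I curves are monotone non-decreasing here
  expect_true(all(diff(ti) >= 0))
  expect_true(all(diff(ta) >= 0))
})

test_that("noise-free pacemaker has constant interspike intervals", {
  s <- simulate_neuron(neuron_params("GPe_TI"), I = 12, duration = 5000)
  isi <- diff(s$spikes[s$spikes > 1000])
  expect_lt(sd(isi) / mean(isi), 0.01)
})

test_that("fixed-step rates agree with a finer-step reference", {
  for (pop in c("GPe_TI", "SNr")) {
    p <- neuron_params(pop)
    r1 <- fi_curve(p, p$I_e, duration = 5000, dt = 0.1)$rate
    r2 <- fi_curve(p, p$I_e, duration = 5000, dt = 0.01)$rate
    expect_lt(abs(r1 - r2) / r2, 0.02)
  }
})

test_that("subthalamic rebound reset produces a burst after release", {
  stn <- neuron_params("STN")
  Iseg <- rbind(c(0, 5), c(500, -100), c(1000, 5))
  s1 <- simulate_neuron(stn, I = Iseg, duration = 1600, dt = 0.1)
  post <- s1$spikes[s1$spikes >= 1000]
  burst <- sum(post < post[1] + 100)
  stn_plain <- stn
  stn_plain$stn_rebound <- FALSE
  s2 <- simulate_neuron(stn_plain, I = Iseg, duration = 1600, dt = 0.1)
  p2 <- s2$spikes[s2$spikes >= 1000]
  expect_gte(burst, 2)
  expect_lt(sum(p2 < p2[1] + 100), burst)
})
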