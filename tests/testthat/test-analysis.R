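test_that("population Fano factor matches the hand-computed form", {
  x <- c(0, 0, 8, 0, 0, 8)
  expect_equal(fano_factor(x), (64 * 2 / 6 - (16 / 6)^2) / (16 / 6))
  expect_equal(fano_factor(x), 5.3333, tolerance = 1e-4)
  expect_equal(fano_factor(rep(4, 100)), 0)
  expect_error(fano_factor(rep(0, 10)), "zero mean")
  expect_error(fano_factor(3))
})

test_that("independent Poisson populations have unit Fano factor", {
  set.seed(21)
  ffs <- replicate(200, {
    counts <- rpois(500, 4)  # population count per bin
    fano_factor(counts)
  })
  # sampling sd of FF for Poisson ~ sqrt(2/n)
  expect_lt(abs(mean(ffs) - 1), 3 * sqrt(2 / 500) / sqrt(200))
  set.seed(22)
  trains <- lapply(1:20, function(i) sort(runif(400, 0, 1e4)))
  counts <- colSums(bin_spikes(trains, 0, 1e4))
  expect_lt(abs(fano_factor(counts) - 1), 0.05)
})

test_that("oscillation index separates modulated from unmodulated trains", {
  flat <- lapply(1:12, function(i) modulated_poisson(20, 0, 0, 6e4, seed = i))
  oi_flat <- oscillation_index(flat, 0, 6e4)
  expect_lt(abs(oi_flat - 10 / 128), 0.01)
  mod <- lapply(1:12, function(i) modulated_poisson(20, 0.8, 20, 6e4,
                                                    seed = 100 + i))
  oi_mod <- oscillation_index(mod, 0, 6e4)
  expect_gt(oi_mod, oi_flat)
  # invariant to a uniform time translation
  shifted <- lapply(mod, function(tt) tt + 500)
  expect_equal(oscillation_index(shifted, 500, 6e4 + 500), oi_mod,
               tolerance = 0.02)
  expect_error(oscillation_index(list(numeric()), 0, 1000), "empty")
})

test_that("coherence of a train with itself is 1; the L-segment threshold", {
  a <- modulated_poisson(30, 0.5, 20, 3e4, seed = 5)
  co <- spike_coherence(a, a, 0, 3e4)
  expect_true(all(abs(co$coh[!is.na(co$coh)] - 1) < 1e-9))
  # threshold formula instance: L = 21 disjoint segments at p = 0.95
  b <- modulated_poisson(30, 0, 0, 21 * 1000, seed = 6)
  co21 <- spike_coherence(a, b, 0, 21 * 1000)
  expect_equal(co21$L, 21)
  expect_equal(co21$signif, 1 - 0.05^(1 / 20), tolerance = 1e-12)
  expect_error(spike_coherence(a, b, 0, 1500), "two segments")
})

test_that("null calibration: independent trains exceed threshold ~5%", {
  set.seed(31)
  exceed <- integer(0)
  total <- integer(0)
  for (r in 1:6) {
    a <- modulated_poisson(40, 0, 0, 1e5, seed = 300 + r)
    b <- modulated_poisson(40, 0, 0, 1e5, seed = 400 + r)
    co <- spike_coherence(a, b, 0, 1e5)
    ok <- !is.na(co$coh) & co$freq > 0
    exceed <- c(exceed, sum(co$coh[ok] > co$signif))
    total <- c(total, sum(ok))
  }
  pv <- binom.test(sum(exceed), sum(total), p = 0.05)$p.value
  expect_gt(pv, 0.01)
})

test_that("phase relations recover constructed alignments", {
  a <- modulated_poisson(60, 0.9, 20, 4e4, seed = 41)
  b <- modulated_poisson(60, 0.9, 20, 4e4, seed = 42)
  inph <- phase_relation(a, b, 0, 4e4)
  expect_lt(abs(inph$circ_mean), 0.2)
  expect_equal(sum(inph$mass), 1, tolerance = 1e-9)
  # antiphase: shift one train by half a beta cycle (25 ms)
  anti <- phase_relation(a, b + 25, 0, 4e4)
  expect_gt(abs(anti$circ_mean), pi - 0.2)
  # histogram of (A,B) reflects that of (B,A)
  ab <- phase_relation(a, b + 5, 0, 4e4)
  ba <- phase_relation(b + 5, a, 0, 4e4)
  expect_equal(ab$circ_mean, -ba$circ_mean, tolerance = 1e-6)
  # identical trains concentrate mass at zero
  self <- phase_relation(a, a, 0, 4e4)
  expect_gt(self$mass[50] + self$mass[51], 0.99)
})

test_that("selection classification implements the half-baseline rule", {
  expect_equal(classify_selection(c(10, 20), 30), "action1")
  expect_equal(classify_selection(c(20, 10), 30), "action2")
  expect_equal(classify_selection(c(10, 10), 30), "dual")
  expect_equal(classify_selection(c(20, 20), 30), "none")
  expect_equal(classify_selection(c(14.9, 40), c(30, 20)), "action1")
  expect_error(classify_selection(c(1, 2), 0), "baseline")
})

test_that("outcome grids aggregate to per-cell proportions", {
  out <- data.frame(i = rep(1:2, each = 4), j = 1,
                    outcome = c("dual", "dual", "dual", "dual",
                                "action1", "action1", "action1", "none"))
  s <- outcome_grid_summary(out)
  c11 <- s[s$i == 1 & s$j == 1, ]
  expect_equal(c11$prop[c11$outcome == "dual"], 1)
  c21 <- s[s$i == 2 & s$j == 1, ]
  expect_equal(c21$prop[c21$outcome == "action1"], 0.75)
  expect_equal(c21$prop[c21$outcome == "none"], 0.25)
  agg <- aggregate(prop ~ i + j, s, sum)
  expect_true(all(abs(agg$prop - 1) < 1e-9))
})
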