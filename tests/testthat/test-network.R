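test_that("population census scales proportionally from the reference", {
  s <- population_sizes(80000)
  expect_identical(unname(s[c("MSN_D1", "FSN", "STN", "GPe_TA", "GPe_TI", "SNr")]),
                   c(37971L, 1599L, 388L, 329L, 988L, 754L))
  expect_equal(unname(s[["GPe_TA"]] / (s[["GPe_TA"]] + s[["GPe_TI"]])),
               0.25, tolerance = 0.01)
  expect_lte(abs(sum(s) - 80000), 7)
  s8 <- population_sizes(8000)
  expect_identical(unname(s8), as.integer(round(unname(s) / 10)))
  expect_error(population_sizes(50))
})

test_that("fan-ins derive from neighbourhood size times probability", {
  expect_equal(derived_fan_in(2800, 0.13), 364)
  expect_equal(derived_fan_in(2800, 0), 0)
  expect_equal(derived_fan_in(60, 0.27), 16)
  expect_equal(derived_fan_in(60, 0.18), 11)
})

test_that("edge sampling gives exact in-degrees, no self or duplicate edges", {
  e <- sample_in_edges(500, 200, fan_in = 24, window = 100, same_pop = FALSE,
                       seed = 3)
  deg <- tabulate(e$post + 1L, nbins = 200)
  expect_true(all(deg == 24))
  key <- paste(e$pre, e$post)
  expect_false(any(duplicated(key)))
  expect_identical(e, sample_in_edges(500, 200, 24, window = 100, seed = 3))
  e2 <- sample_in_edges(500, 200, 24, window = 100, seed = 4)
  expect_false(identical(e, e2))
  # recurrent population: identity pairs excluded
  er <- sample_in_edges(300, 300, 12, window = NA, same_pop = TRUE, seed = 5)
  expect_false(any(er$pre == er$post))
  expect_equal(length(sample_in_edges(10, 10, 0)$pre), 0)
  expect_error(sample_in_edges(100, 100, 5, window = 4), "window")
})

test_that("a built network satisfies every catalogued in-degree exactly", {
  net <- small_net()
  tab <- in_degree_table(net)
  expect_true(all(tab$min_in == tab$fan_in))
  expect_true(all(tab$max_in == tab$fan_in))
  # same seed gives bit-identical edges
  net2 <- suppressWarnings(build_network(bg_config(2000), seed = 42))
  expect_identical(net$conns[["MSN_D1-MSN_D1"]]$pre_edges,
                   net2$conns[["MSN_D1-MSN_D1"]]$pre_edges)
})

test_that("striatum-projecting prototypical subpopulation is respected", {
  net <- small_net()
  cn <- net$conns[["GPe_TI-FSN"]]
  eligible <- seq(1L, net$sizes[["GPe_TI"]], by = 10L) - 1L
  expect_true(all(cn$pre_edges %in% eligible))
})

test_that("out-degree bookkeeping is consistent with fan-in totals", {
  cn <- small_net()$conns[["MSN_D2-MSN_D1"]]
  # total edges = fan_in * n_post however they distribute over sources
  expect_equal(length(cn$pre_edges), cn$fan_in * cn$n_post)
  expect_equal(mean(tabulate(cn$pre_edges + 1L, cn$n_pre)),
               cn$fan_in * cn$n_post / cn$n_pre, tolerance = 0.01)
})

test_that("cluster carving removes in-cluster collaterals, keeps degrees", {
  net <- small_net()
  before <- in_degree_table(net)
  carved <- carve_nonconnected_clusters(net, 0.1, seed = 9)
  after <- in_degree_table(carved)
  expect_equal(after, before)
  cl <- carved$cluster
  for (nm in c("MSN_D1-MSN_D1", "MSN_D2-MSN_D1")) {
    cn <- carved$conns[[nm]]
    inin <- cn$pre_edges %in% (cl[[cn$pre]] - 1L) &
      cn$post_edges %in% (cl[[cn$post]] - 1L)
    expect_equal(sum(inin), 0)
  }
  expect_error(carve_nonconnected_clusters(net, 0.7))
})

test_that("action channels partition outputs and restrict pathways", {
  spec <- action_channel_spec(pool_fraction = 0.3)
  net <- suppressWarnings(build_network(bg_config(4000), seed = 8,
                                        channels = spec))
  lab <- net$labels
  # striatal pools disjoint by construction (labels partition members)
  expect_equal(sort(unique(lab$SNr)), 1:2)
  expect_true(all(lab$SNr %in% 1:2))        # every output neuron mapped
  for (pop in c("MSN_D1", "MSN_D2")) {
    n_half <- floor(net$sizes[[pop]] / 2)
    expect_equal(sum(lab[[pop]] == 1), round(0.3 * n_half))
    expect_equal(sum(lab[[pop]] == 2), round(0.3 * n_half))
  }
  # direct pathway: output pool a receives no input from Go pool b != a
  cn <- net$conns[["MSN_D1-SNr"]]
  pre_lab <- lab$MSN_D1[cn$pre_edges + 1L]
  post_lab <- lab$SNr[cn$post_edges + 1L]
  expect_true(all(pre_lab == 0 | pre_lab == post_lab))
  # indirect: pallidal pool a from matching NoGo pool only
  cn <- net$conns[["MSN_D2-GPe_TI"]]
  pre_lab <- lab$MSN_D2[cn$pre_edges + 1L]
  post_lab <- lab$GPe_TI[cn$post_edges + 1L]
  expect_true(all(pre_lab == 0 | pre_lab == post_lab))
  # direct-only variant leaves the indirect pathway unlabelled
  d1 <- suppressWarnings(build_network(
    bg_config(4000), seed = 8,
    channels = action_channel_spec(pool_fraction = 0.3,
                                   include_indirect = FALSE)))
  expect_true(all(d1$labels$MSN_D2 == 0))
})

test_that("infeasible fan-ins are capped with a warning, not silently", {
  w <- capture_warnings(build_network(bg_config(2000), seed = 1))
  expect_true(any(grepl("capped", w)))
})
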