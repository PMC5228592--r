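POPS <- c("MSN_D1", "MSN_D2", "FSN", "STN", "GPe_TA", "GPe_TI", "SNr")

# Reference census at the full scale of 80,000 neurons.
SIZES_80K <- c(MSN_D1 = 37971, MSN_D2 = 37971, FSN = 1599, STN = 388,
               GPe_TA = 329, GPe_TI = 988, SNr = 754)

#' Population sizes
#'
#' Nucleus sizes are fixed proportions of the total network size, anchored
#' to the census of the full 80,000-neuron model (47.5/47.5/2% split of
#' striatal neurons into the two projection-neuron types and fast-spiking
#' interneurons; 25/75% split of the external pallidum into arkypallidal
#' and prototypical cells).
#'
#' @param N_total Total network size (>= 100).
#' @return Named integer vector over the seven populations.
#' @export
population_sizes <- function(N_total) {
  if (!is.numeric(N_total) || N_total < 100) stop("N_total must be >= 100")
  out <- round(SIZES_80K / 80000 * N_total)
  storage.mode(out) <- "integer"
  out
}

#' @rdname population_sizes
#' @param neighborhood Number of candidate presynaptic neurons within an
#'   axonal/dendritic field.
#' @param probability Pairwise connection probability.
#' @export
derived_fan_in <- function(neighborhood, probability) {
  stopifnot(probability >= 0, probability <= 1)
  round(neighborhood * probability)
}

#' Network configuration
#'
#' Assembles the full parameterisation of the model at a given scale:
#' population sizes, neuron parameters, heterogeneity, the synapse and
#' connectivity catalogues, and the extrinsic-drive table. Fan-ins are
#' absolute (not probabilities), so scaled-down networks preserve
#' per-neuron input counts. The configuration is a plain value object;
#' dopamine depletion ([apply_depletion()]) returns a modified copy.
#'
#' @param N_total Total network size.
#' @param C_cv,Vth_sd Heterogeneity of capacitance (CV) and threshold (mV).
#' @param enable_d2_k_effect Enable the optional D2-receptor effect on the
#'   quadratic I-V coefficient of the D2-type projection neurons
#'   (coefficient 0.032); off by default since no consistent postsynaptic
#'   D2 excitability change is included in the model.
#' @return An object of class `bg_config`.
#' @export
bg_config <- function(N_total = 10000, C_cv = 0.10, Vth_sd = 1.0,
                      enable_d2_k_effect = FALSE) {
  sizes <- population_sizes(N_total)
  neurons <- lapply(POPS, neuron_params)
  names(neurons) <- POPS
  cfg <- list(N_total = as.integer(N_total), sizes = sizes,
              neurons = neurons,
              heterogeneity = list(C_cv = C_cv, Vth_sd = Vth_sd),
              synapses = read_catalogue("synapses.tsv"),
              connections = read_catalogue("connectivity.tsv"),
              drives = read_catalogue("drives.tsv"),
              alpha = 0.8,
              enable_d2_k_effect = enable_d2_k_effect,
              d2_k_beta = 0.032)
  structure(cfg, class = "bg_config")
}

#' @export
print.bg_config <- function(x, ...) {
  cat("<bg_config> N =", x$N_total, " alpha =", x$alpha, "\n")
  cat(" ", paste(names(x$sizes), x$sizes, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Sample exact-in-degree edges
#'
#' For every postsynaptic neuron, draws `fan_in` distinct presynaptic
#' partners uniformly without replacement, either from the whole
#' presynaptic population or from an index-ring spatial window of the
#' stated size centred on the postsynaptic neuron's position (striatal
#' collaterals and feed-forward inhibition). Self-connections are excluded
#' within a population. Reproducible given `seed`.
#'
#' @param n_pre,n_post Population sizes.
#' @param fan_in In-degree per postsynaptic neuron.
#' @param window Spatial window size (`NA` = whole population).
#' @param same_pop Exclude the identity pairing (recurrent population).
#' @param eligible Optional 1-based indices of eligible presynaptic neurons
#'   (e.g. the striatum-projecting prototypical-cell subpopulation).
#' @param post_subset Optional 1-based indices of postsynaptic neurons to
#'   (re)sample; defaults to all.
#' @param seed Integer seed.
#' @return List with 0-based integer vectors `pre`, `post` of equal length.
#' @export
sample_in_edges <- function(n_pre, n_post, fan_in, window = NA, same_pop = FALSE,
                            eligible = NULL, post_subset = NULL, seed = 1L) {
  if (fan_in == 0L) return(list(pre = integer(), post = integer()))
  posts <- if (is.null(post_subset)) seq_len(n_post) else post_subset
  use_window <- is.finite(window) && is.null(eligible)
  if (use_window) {
    w <- min(window, n_pre)
    avail <- w - as.integer(same_pop)
    if (avail < fan_in)
      stop("fan_in (", fan_in, ") exceeds window (", avail, ")")
  } else {
    pool <- if (is.null(eligible)) seq_len(n_pre) else eligible
    if (length(pool) - as.integer(same_pop) < fan_in)
      stop("fan_in (", fan_in, ") exceeds presynaptic pool (", length(pool), ")")
  }
  pre <- withr_seed(seed, {
    m <- matrix(0L, nrow = fan_in, ncol = length(posts))
    for (jj in seq_along(posts)) {
      j <- posts[jj]
      if (use_window) {
        center <- floor((j - 1) * n_pre / n_post)
        cand <- (center - floor(w / 2) + 0:(w - 1)) %% n_pre  # 0-based ring
        if (same_pop) cand <- cand[cand != (j - 1)]
        m[, jj] <- cand[sample.int(length(cand), fan_in)]
      } else {
        cand <- pool
        if (same_pop) cand <- cand[cand != j]
        m[, jj] <- cand[sample.int(length(cand), fan_in)] - 1L
      }
    }
    m
  })
  list(pre = as.integer(pre), post = rep(as.integer(posts) - 1L, each = fan_in))
}

pop_offsets <- function(sizes) {
  off <- cumsum(c(0L, unname(sizes[-length(sizes)])))
  names(off) <- names(sizes)
  off
}

#' Action-channel specification
#'
#' Two (or more) competing actions are embedded as labelled subpopulations:
#' for each action, a Go pool in the D1-type striatal projection neurons
#' whose nigral targets are restricted to that action's output pool, and,
#' when the indirect pathway is included, a NoGo pool in the D2-type
#' neurons projecting to an action-specific prototypical-pallidal pool
#' which in turn projects to the other actions' output pools. Output
#' (SNr) neurons are partitioned so each belongs to exactly one action.
#'
#' @param n_actions Number of competing actions (default 2).
#' @param pool_fraction Fraction of each half of a striatal population
#'   assigned to its action pool (0.1 to 1).
#' @param include_indirect Also embed NoGo channels through the indirect
#'   pathway.
#' @export
action_channel_spec <- function(n_actions = 2, pool_fraction = 0.2,
                                include_indirect = TRUE) {
  stopifnot(n_actions >= 2, pool_fraction > 0, pool_fraction <= 1)
  structure(list(n_actions = as.integer(n_actions),
                 pool_fraction = pool_fraction,
                 include_indirect = include_indirect),
            class = "action_channel_spec")
}

# Assign action labels: striatal pools are disjoint random subsets of equal
# halves; output/pallidal populations are partitioned into contiguous blocks.
channel_labels <- function(sizes, spec, seed) {
  nA <- spec$n_actions
  lab <- list()
  withr_seed(seed, {
    for (pop in c("MSN_D1", "MSN_D2")) {
      n <- sizes[[pop]]
      half <- floor(n / nA)
      v <- integer(n)
      for (a in seq_len(nA)) {
        block <- ((a - 1) * half + 1):(a * half)
        pool <- sample(block, max(1L, round(spec$pool_fraction * half)))
        v[pool] <- a
      }
      lab[[pop]] <- v
    }
  })
  for (pop in c("GPe_TI", "SNr")) {
    n <- sizes[[pop]]
    v <- pmin(nA, 1L + (seq_len(n) - 1L) %/% ceiling(n / nA))
    lab[[pop]] <- as.integer(v)
  }
  if (!spec$include_indirect) lab$MSN_D2 <- integer(sizes[["MSN_D2"]])
  lab
}

#' Build a network
#'
#' Compiles a configuration into a simulable network: samples neuron
#' heterogeneity, draws every connection's edge list at its exact fan-in,
#' and optionally embeds action channels. Every postsynaptic neuron of a
#' connection receives exactly the configured number of presynaptic
#' partners; when a scaled-down network cannot satisfy a fan-in within the
#' available pool, the fan-in is capped at the pool size with a warning.
#'
#' @param config A [bg_config()].
#' @param seed Master build seed.
#' @param channels Optional [action_channel_spec()].
#' @return An object of class `bg_network`.
#' @export
build_network <- function(config, seed = 1L, channels = NULL) {
  stopifnot(inherits(config, "bg_config"))
  sizes <- config$sizes
  off <- pop_offsets(sizes)
  n <- sum(sizes)
  fam <- integer(n)
  par <- matrix(0, n, 12)
  pop_of <- integer(n)
  for (pi in seq_along(POPS)) {
    pop <- POPS[pi]
    p <- config$neurons[[pop]]
    if (pop == "MSN_D2" && isTRUE(config$enable_d2_k_effect))
      p$k <- p$k * (1 + config$d2_k_beta * (config$alpha - 0.8))
    pr <- param_row(p)
    idx <- off[[pop]] + seq_len(sizes[[pop]])
    fam[idx] <- pr$fam
    par[idx, ] <- matrix(pr$row, sizes[[pop]], 12, byrow = TRUE)
    het <- sample_heterogeneity(
      p, heterogeneity_spec(config$heterogeneity$C_cv,
                            config$heterogeneity$Vth_sd,
                            seed = seed * 131L + pi),
      sizes[[pop]])
    par[idx, 1] <- het$C
    par[idx, 4] <- het$threshold
    pop_of[idx] <- pi - 1L
  }

  labels <- if (!is.null(channels))
    channel_labels(sizes, channels, seed = seed * 977L + 11L) else NULL

  conns <- list()
  ct <- config$connections
  for (k in seq_len(nrow(ct))) {
    row <- ct[k, ]
    syn <- config$synapses[match(row$synapse, config$synapses$name), ]
    if (nrow(syn) != 1L || is.na(syn$name[1]))
      stop("connection references unknown synapse: ", row$synapse)
    n_pre <- sizes[[row$pre]]
    n_post <- sizes[[row$post]]
    eligible <- NULL
    if (row$pre_fraction < 1)
      eligible <- seq(1L, n_pre, by = as.integer(round(1 / row$pre_fraction)))
    fan <- row$fan_in
    pool_n <- if (!is.null(eligible)) length(eligible)
              else if (is.finite(row$window)) min(row$window, n_pre) else n_pre
    avail <- pool_n - as.integer(row$pre == row$post)
    if (fan > avail) {
      warning("connection ", row$name, ": fan-in ", fan,
              " capped at available pool ", avail, call. = FALSE)
      fan <- avail
    }
    edges <- sample_edges_for_spec(row, fan, n_pre, n_post, eligible,
                                   labels, config, seed * 7919L + k)
    conns[[row$name]] <- list(
      name = row$name, pre = row$pre, post = row$post, fan_in = fan,
      syn = syn, pre_off = unname(off[[row$pre]]),
      post_off = unname(off[[row$post]]),
      n_pre = n_pre, n_post = n_post,
      pre_edges = edges$pre, post_edges = edges$post, g_scale = 1.0)
  }

  structure(list(config = config, sizes = sizes, offsets = off, n = n,
                 fam = fam, par = par, pop_of = pop_of, conns = conns,
                 labels = labels, channels = channels, seed = seed),
            class = "bg_network")
}

# Draw one connection's edges, honouring action-channel restrictions.
sample_edges_for_spec <- function(row, fan, n_pre, n_post, eligible, labels,
                                  config, seed) {
  restricted <- !is.null(labels) &&
    row$name %in% c("MSN_D1-SNr", "MSN_D2-GPe_TI", "GPe_TI-SNr")
  if (!restricted) {
    return(sample_in_edges(n_pre, n_post, fan, window = row$window,
                           same_pop = row$pre == row$post,
                           eligible = eligible, seed = seed))
  }
  pre_lab <- labels[[row$pre]]
  post_lab <- labels[[row$post]]
  indirect <- row$name %in% c("MSN_D2-GPe_TI", "GPe_TI-SNr") &&
    any(labels$MSN_D2 > 0)
  if (row$name %in% c("MSN_D2-GPe_TI", "GPe_TI-SNr") && !indirect) {
    return(sample_in_edges(n_pre, n_post, fan, window = row$window,
                           same_pop = FALSE, eligible = eligible, seed = seed))
  }
  pre <- integer(0); post <- integer(0)
  for (a in sort(unique(post_lab))) {
    posts <- which(post_lab == a)
    # action pool a draws its pathway input from matching-action or
    # unlabelled presynaptic cells (Go_a -> SNr_a; NoGo_a -> TI_a -> SNr_a)
    elig <- which(pre_lab == a | pre_lab == 0)
    f <- fan
    if (length(elig) < f) {
      warning("connection ", row$name, " (action ", a, "): fan-in ", fan,
              " capped at eligible pool ", length(elig), call. = FALSE)
      f <- length(elig)
    }
    e <- sample_in_edges(n_pre, length(posts), f, window = NA,
                         same_pop = FALSE, eligible = elig,
                         seed = seed + a)
    pre <- c(pre, e$pre)
    post <- c(post, posts[e$post + 1L] - 1L)
  }
  list(pre = pre, post = post)
}

#' @export
print.bg_network <- function(x, ...) {
  ne <- sum(vapply(x$conns, function(cn) length(cn$pre_edges), numeric(1)))
  cat("<bg_network> N =", x$n, "neurons,", length(x$conns), "connections,",
      format(ne, big.mark = ","), "edges\n")
  invisible(x)
}

#' In-degree audit
#'
#' Per-connection in-degree table used by the exact-fan-in invariant.
#'
#' @param net A [build_network()] result.
#' @return data.frame with `connection`, `fan_in`, `min_in`, `max_in`.
#' @export
in_degree_table <- function(net) {
  do.call(rbind, lapply(net$conns, function(cn) {
    deg <- tabulate(cn$post_edges + 1L, nbins = cn$n_post)
    data.frame(connection = cn$name, fan_in = cn$fan_in,
               min_in = min(deg), max_in = max(deg))
  }))
}

#' Carve non-connected striatal clusters
#'
#' Removes collateral edges between the designated cluster members (the
#' lowest-index fraction of each striatal projection population) and
#' redraws replacements from outside the cluster, so each neuron's
#' in-degree is preserved exactly.
#'
#' @param net A `bg_network`.
#' @param cluster_fraction Fraction of each projection population forming
#'   the non-connected cluster (in (0, 0.5]).
#' @param seed Seed for the replacement draws.
#' @return The modified network (input unchanged), with the cluster
#'   recorded in `net$cluster`.
#' @export
carve_nonconnected_clusters <- function(net, cluster_fraction, seed = 1L) {
  stopifnot(inherits(net, "bg_network"),
            cluster_fraction > 0, cluster_fraction <= 0.5)
  coll <- c("MSN_D1-MSN_D1", "MSN_D1-MSN_D2", "MSN_D2-MSN_D1", "MSN_D2-MSN_D2")
  cluster <- lapply(net$sizes[c("MSN_D1", "MSN_D2")],
                    function(nn) seq_len(max(1L, round(cluster_fraction * nn))))
  for (nm in coll) {
    cn <- net$conns[[nm]]
    if (is.null(cn)) next
    in_pre <- cn$pre_edges %in% (cluster[[cn$pre]] - 1L)
    in_post <- cn$post_edges %in% (cluster[[cn$post]] - 1L)
    bad <- which(in_pre & in_post)
    if (!length(bad)) next
    pre <- cn$pre_edges
    post <- cn$post_edges
    out_pool <- setdiff(seq_len(cn$n_pre), cluster[[cn$pre]]) - 1L
    withr_seed(seed + match(nm, coll), {
      for (j in unique(post[bad])) {
        idx <- bad[post[bad] == j]
        used <- pre[post == j]
        cand <- setdiff(out_pool, used)
        if (length(cand) < length(idx))
          stop("cluster carve infeasible for ", nm)
        pre[idx] <- cand[sample.int(length(cand), length(idx))]
      }
    })
    net$conns[[nm]]$pre_edges <- pre
  }
  net$cluster <- cluster
  net
}

#' Embed action channels into an existing network
#'
#' Relabels and redraws the pathway connections of a built network
#' according to an [action_channel_spec()]; equivalent to rebuilding with
#' `channels` supplied.
#'
#' @inheritParams carve_nonconnected_clusters
#' @param spec An [action_channel_spec()].
#' @export
embed_action_channels <- function(net, spec, seed = NULL) {
  stopifnot(inherits(net, "bg_network"), inherits(spec, "action_channel_spec"))
  build_network(net$config, seed = if (is.null(seed)) net$seed else seed,
                channels = spec)
}
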