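# Shared fixtures, built lazily and cached for the whole run.
.fix <- new.env()

fixture <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

# Small striatal-scale network used by several engine/analysis tests.
small_net <- function() fixture("small_net", suppressWarnings(
  build_network(bg_config(2000), seed = 42)))

small_drives <- function() default_drives(small_net())

# A hand-crafted two-neuron motif (one pallidal pacemaker inhibiting one
# nigral neuron) for exact delay bookkeeping tests.
micro_net <- function(delay = 3) {
  sizes <- c(MSN_D1 = 1L, MSN_D2 = 1L, FSN = 1L, STN = 1L, GPe_TA = 1L,
             GPe_TI = 1L, SNr = 1L)
  off <- c(0L, cumsum(unname(sizes))[-7])
  names(off) <- names(sizes)
  par <- matrix(0, 7, 12)
  fam <- integer(7)
  for (i in seq_along(sizes)) {
    pr <- bgnet:::param_row(neuron_params(names(sizes)[i]))
    fam[i] <- pr$fam
    par[i, ] <- pr$row
  }
  # silence everything except the pacemaker (GPe_TI) and its target (SNr)
  par[c(1:5), 11] <- -200
  syn <- synapse_catalogue("GPe_TI-SNr")
  syn$delay <- delay
  conns <- list(`GPe_TI-SNr` = list(
    name = "GPe_TI-SNr", pre = "GPe_TI", post = "SNr", fan_in = 1L,
    syn = syn, pre_off = unname(off[["GPe_TI"]]),
    post_off = unname(off[["SNr"]]), n_pre = 1L, n_post = 1L,
    pre_edges = 0L, post_edges = 0L, g_scale = 1))
  structure(list(config = NULL, sizes = sizes, offsets = off, n = 7L,
                 fam = fam, par = par, pop_of = 0:6, conns = conns,
                 labels = NULL, channels = NULL, seed = 1L),
            class = "bg_network")
}

# Tsodyks parameter list from a synapse-catalogue row.
ts_params <- function(name) {
  s <- synapse_catalogue(name)
  list(U = s$U, tau_rec = s$tau_rec, tau_fac = s$tau_fac, tau_syn = s$tau_syn)
}
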