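#' Dopamine-occupancy parameter scaling
#'
#' Tonic dopamine is represented by a receptor-occupancy scalar
#' `alpha` in [0, 1]; the normal level is `alpha0 = 0.8` and a 6-OHDA
#' lesion is modelled as `alpha = 0`. Every modulated parameter `p` is
#' scaled as `p * (1 + beta * phi(alpha))` with `phi(alpha) = alpha -
#' alpha0`, so parameters are untouched at the reference occupancy.
#'
#' @param alpha Occupancy in [0, 1].
#' @param alpha0 Reference occupancy (0.8).
#' @export
dopamine_state <- function(alpha = 0.8, alpha0 = 0.8) {
  stopifnot(alpha >= 0, alpha <= 1, alpha0 >= 0, alpha0 <= 1)
  structure(list(alpha = alpha, alpha0 = alpha0), class = "dopamine_state")
}

#' @rdname dopamine_state
#' @param state A [dopamine_state()].
#' @export
phi <- function(state) state$alpha - state$alpha0

#' @rdname dopamine_state
#' @param p_value Parameter value to scale.
#' @param beta Scaling coefficient.
#' @param clamp Clamp negative scaled conductances to zero (with a warning).
#' @export
scale_parameter <- function(p_value, beta, state, clamp = FALSE) {
  stopifnot(is.finite(p_value), is.finite(beta))
  v <- p_value * (1 + beta * phi(state))
  if (clamp && v < 0) {
    warning("scaled value clamped to 0 (degenerate depletion)")
    v <- 0
  }
  v
}

#' Re-derive scaling coefficients from experimental constraints
#'
#' `solve_beta_from_ratio()` inverts the scaling form for a measured
#' amplitude ratio `R = value(alpha_low) / value(alpha_high)`; for the
#' standard endpoints (0 and 1, reference 0.8) the closed form is
#' `beta = (1 - R) / (0.8 + 0.2 R)`. `solve_beta_from_shift()` handles
#' additive constraints ("x mV lower at zero occupancy"): with
#' `delta = value(0) - value(1)`, `beta = -delta / base`.
#'
#' @param ratio Amplitude ratio low-over-high occupancy (> 0).
#' @param alpha_low,alpha_high Occupancy endpoints of the constraint.
#' @param alpha0 Reference occupancy.
#' @return The coefficient `beta`; a warning is raised when it falls
#'   outside the catalogue range [-5, 1.25].
#' @export
solve_beta_from_ratio <- function(ratio, alpha_low = 0, alpha_high = 1,
                                  alpha0 = 0.8) {
  stopifnot(ratio > 0)
  pl <- alpha_low - alpha0
  ph <- alpha_high - alpha0
  # (1 + beta pl) / (1 + beta ph) = R
  beta <- (1 - ratio) / (ratio * ph - pl)
  if (abs(1 + beta * ph) < 1e-12) stop("degenerate constraint")
  if (beta < -5 || beta > 1.25)
    warning("beta outside the catalogue range [-5, 1.25]")
  beta
}

#' @rdname solve_beta_from_ratio
#' @param delta_mV Shift `value(0) - value(1)` (mV).
#' @param base_mV Unmodulated parameter value (mV).
#' @export
solve_beta_from_shift <- function(delta_mV, base_mV,
                                  alpha_low = 0, alpha_high = 1) {
  if (base_mV == 0) stop("base must be nonzero")
  beta <- -delta_mV / (base_mV * (alpha_high - alpha_low))
  if (beta < -5 || beta > 1.25)
    warning("beta outside the catalogue range [-5, 1.25]")
  beta
}

#' Dopamine modulation catalogue
#'
#' The table of scaling coefficients: synaptic conductances, extrinsic-drive
#' conductances, striatal fan-ins and neuron parameters, each with the
#' constraint it was derived from.
#'
#' @return A data.frame with columns `name`, `kind`, `target`, `field`,
#'   `beta`, `constraint`.
#' @export
modulation_table <- function() {
  tab <- read_catalogue("dopamine.tsv")
  stopifnot(all(tab$beta >= -5), all(tab$beta <= 1.25))
  tab
}

#' Apply dopamine depletion to a network configuration
#'
#' Returns a new configuration in which every catalogued synaptic and
#' drive conductance, neuron parameter and striatal fan-in is scaled to the
#' occupancy `alpha`; the input configuration is left untouched. Fan-ins
#' are rounded half-up with a floor of 0. Entries named in `restore` are
#' left at their reference (`alpha0`) value, which implements the
#' one-parameter restoration sweeps; `only` restricts modulation to the
#' named entries instead.
#'
#' @param config A [bg_config()].
#' @param alpha Occupancy in [0, 1] (0 = lesioned, 0.8 = control).
#' @param restore Character vector of modulation-entry names to hold at the
#'   reference value.
#' @param only Optional character vector: modulate only these entries.
#' @param table Modulation table (defaults to [modulation_table()]).
#' @return A new `bg_config` with `alpha` recorded.
#' @export
apply_depletion <- function(config, alpha, restore = character(),
                            only = NULL, table = modulation_table()) {
  stopifnot(inherits(config, "bg_config"))
  state <- dopamine_state(alpha)
  unknown <- setdiff(c(restore, only), table$name)
  if (length(unknown)) stop("unknown modulation entries: ",
                            paste(unknown, collapse = ", "))
  apply_rows <- table$name %in% setdiff(
    if (is.null(only)) table$name else only, restore)
  out <- config
  for (i in which(apply_rows)) {
    row <- table[i, ]
    fac <- 1 + row$beta * phi(state)
    if (row$kind == "syn_g0") {
      j <- match(row$target, out$synapses$name)
      if (is.na(j)) stop("modulation targets unknown synapse: ", row$target)
      out$synapses$g0[j] <- max(0, out$synapses$g0[j] * fac)
    } else if (row$kind == "drive_g0") {
      j <- match(row$target, out$drives$name)
      if (is.na(j)) stop("modulation targets unknown drive: ", row$target)
      out$drives[[row$field]][j] <- max(0, out$drives[[row$field]][j] * fac)
    } else if (row$kind == "fan_in") {
      j <- match(row$target, out$connections$name)
      if (is.na(j)) stop("modulation targets unknown connection: ", row$target)
      out$connections$fan_in[j] <-
        max(0L, as.integer(floor(out$connections$fan_in[j] * fac + 0.5)))
    } else if (row$kind == "neuron") {
      if (!row$target %in% names(out$neurons))
        stop("modulation targets unknown population: ", row$target)
      out$neurons[[row$target]][[row$field]] <-
        out$neurons[[row$target]][[row$field]] * fac
    } else stop("unknown modulation kind: ", row$kind)
  }
  out$alpha <- alpha
  out
}
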