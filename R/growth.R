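#' Angiogenesis-gated tumor growth rate
#'
#' Simeoni-type growth switching smoothly from exponential (rate `k0`) to
#' linear (rate `k1`) growth, gated by the ratio of the angiogenic signal
#' to its basal value:
#'
#' Model 1: `dV/dt = k0 V / (1 + (k0 V / k1)^psi)^(1/psi) * (Ang/Ang0)`
#'
#' Model 2 multiplies the Simeoni factor by
#' `1 - (Ang0 - C_Ang * Ang)/Ang0` instead (algebraically
#' `C_Ang * Ang/Ang0`; `C_Ang` is jointly non-identifiable with `Ang0` and
#' Model 2 is provided for simulation only).
#'
#' The Simeoni denominator is evaluated in the log domain so that large
#' `(k0 V / k1)^psi` never overflows.
#'
#' @param V tumor volume, cm^3 (vectorized).
#' @param Ang angiogenic signal, mol/cm^3 tissue (vectorized).
#' @param params list with `k0` (s^-1), `k1` (cm^3/s), `psi`, `Ang0`
#'   (mol/cm^3), optional `C_Ang` and `variant` ("model1"/"model2").
#' @param form `"ratio"` uses the simplified `Ang/Ang0` form; `"deficit"`
#'   uses the equivalent `1 - (Ang0 - Ang)/Ang0` form (identical up to
#'   rounding; both kept for cross-checking).
#' @return dV/dt in cm^3/s.
#' @export
growth_rate <- function(V, Ang, params, form = c("ratio", "deficit")) {
  form <- match.arg(form)
  stopifnot(all(V > 0), all(Ang >= 0))
  k0 <- params$k0; k1 <- params$k1; psi <- params$psi; Ang0 <- params$Ang0
  stopifnot(k0 > 0, k1 > 0, psi > 0, Ang0 > 0)
  simeoni <- k0 * V * exp(-log1p_exp(psi * log(k0 * V / k1)) / psi)
  variant <- if (is.null(params$variant)) "model1" else params$variant
  gate <- if (variant == "model2") {
    C <- if (is.null(params$C_Ang)) 1 else params$C_Ang
    1 - (Ang0 - C * Ang) / Ang0
  } else if (form == "deficit") {
    1 - (Ang0 - Ang) / Ang0
  } else {
    Ang / Ang0
  }
  simeoni * gate
}

# log(1 + exp(x)) without overflow
log1p_exp <- function(x) ifelse(x > 35, x, log1p(exp(x)))

#' Angiogenic signal of a model state
#'
#' Sums the concentrations of the pro-angiogenic VEGF-receptor complexes on
#' tumor endothelial cells (VEGFR1 or VEGFR2 bound to any VEGF isoform,
#' with or without NRP1).  Returns the total and the contributing
#' inventory.
#'
#' @param state named numeric vector of species concentrations
#'   (mol/cm^3 tissue), or a one-row slice of a trajectory state matrix.
#' @param network an `angiofit_network`.
#' @return list of class `angiofit_ang` with `value` and `inventory`
#'   (named numeric vector).
#' @export
angiogenic_signal <- function(state, network) {
  inv <- state[intersect(network$ang_species, names(state))]
  if (length(inv) == 0) inv <- numeric(0)
  structure(list(value = sum(inv), inventory = inv),
            class = "angiofit_ang")
}

#' @export
print.angiofit_ang <- function(x, ...) {
  cat("angiogenic signal:", format(x$value, digits = 6),
      "mol/cm^3 tissue from", length(x$inventory), "complexes\n")
  invisible(x)
}
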