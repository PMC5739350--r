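#' Tumor volume-fraction geometry
#'
#' The tumor compartment is partitioned into vascular space (constant
#' fraction), interstitial space, and tumor cells.  The interstitial
#' fraction decays exponentially with total tumor volume,
#' `f_int(V) = f_min + (f0 - f_min) * exp(-lambda * V)`, reflecting the
#' increase in cell density as the tumor grows; the cell fraction takes up
#' the remainder so the three fractions always sum to one.
#'
#' @param V tumor volume (cm^3), vectorized.
#' @param config an `angiofit_config` (only `compartments$tumor` is used).
#' @return data.frame with columns `V`, `f_int`, `f_vasc`, `f_cell`,
#'   `cells` (tumor cell count).
#' @export
update_tumor_geometry <- function(V, config) {
  if (any(V <= 0)) stop("tumor volume must be positive")
  g <- config$compartments$tumor
  f_int <- g$f_int_min + (g$f_int0 - g$f_int_min) * exp(-g$lambda * V)
  f_cell <- 1 - f_int - g$f_vasc
  if (any(f_cell < 0))
    stop("geometry parameters give a negative cell fraction at V = ",
         signif(V[which(f_cell < 0)[1]], 4))
  cell_vol_cm3 <- g$cell_volume_um3 * 1e-12
  data.frame(V = V, f_int = f_int, f_vasc = g$f_vasc, f_cell = f_cell,
             cells = f_cell * V / cell_vol_cm3)
}
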