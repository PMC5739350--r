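#' Receptor-density grid specification
#'
#' @param vegfr1 VEGFR1 levels on tumor cells (receptors/cell).
#' @param vegfr2 VEGFR2 levels on tumor cells (receptors/cell).
#' @param nrp NRP1 levels on tumor cells (receptors/cell); the study's
#'   panel anchors are 0, 20,000 and 100,000.
#' @param dose bevacizumab dose (mg/kg, default 10).
#' @return list of class `angiofit_receptor_grid`.
#' @export
receptor_grid <- function(vegfr1 = seq(0, 10000, length.out = 11),
                          vegfr2 = seq(0, 10000, length.out = 11),
                          nrp = c(0, 20000, 100000),
                          dose = 10) {
  if (any(c(vegfr1, vegfr2, nrp) < 0))
    stop("receptor densities must be nonnegative")
  structure(list(vegfr1 = vegfr1, vegfr2 = vegfr2, nrp = nrp,
                 dose = dose),
            class = "angiofit_receptor_grid")
}

#' Map treatment response over tumor-cell receptor densities
#'
#' For every combination of tumor-cell VEGFR1, VEGFR2 and NRP1 surface
#' density, the network is rebuilt, the time to reach the treatment
#' threshold (T_start) is recomputed, and paired control/treated
#' simulations (twice-weekly dosing for six weeks past T_start) give the
#' relative tumor volume.  Growth parameters are held fixed (a
#' representative best-fit set).  Combinations whose tumors never reach
#' the threshold, or whose simulation fails, are flagged in `status`
#' rather than dropped.
#'
#' @param grid an [receptor_grid()].
#' @param config an `angiofit_config`; the tumor-cell receptor entries
#'   are overridden per grid point.
#' @param growth fixed growth parameters (overrides the config's).
#' @param solver_opts see [simulate_model()].
#' @return data.frame (long format): `VEGFR1`, `VEGFR2`, `NRP1`,
#'   `T_start_days`, `RTV`, `status` ("ok", "no_crossing", "error").
#' @export
receptor_response_grid <- function(grid, config = default_config(),
                                   growth = NULL, solver_opts = list()) {
  combos <- expand.grid(VEGFR1 = grid$vegfr1, VEGFR2 = grid$vegfr2,
                        NRP1 = grid$nrp, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg_i <- modify_config(config, list(populations = list(
      tumor_cell = list(receptors = c(
        VEGFR1 = combos$VEGFR1[i], VEGFR2 = combos$VEGFR2[i],
        NRP1 = combos$NRP1[i], NRP2 = 0)))))
    res <- try({
      net <- build_network(cfg_i)
      relative_tumor_volume(net, growth = growth, dose = grid$dose,
                            solver_opts = solver_opts)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      msg <- attr(res, "condition")$message
      status <- if (grepl("never reaches", msg)) "no_crossing" else "error"
      rows[[i]] <- data.frame(combos[i, ], T_start_days = NA_real_,
                              RTV = NA_real_, status = status)
    } else {
      rows[[i]] <- data.frame(combos[i, ], T_start_days = res$T_start / DAY,
                              RTV = res$RTV, status = "ok")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
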