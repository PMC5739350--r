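DAY <- 86400
WEEK <- 7 * 86400

comp_code <- c(normal = 0L, blood = 1L, tumor = 2L)

# Pack a network into the flat integer/double representation consumed by
# the compiled RHS.  Growth parameters are filled with placeholders and
# overwritten per simulation.
make_packed <- function(network) {
  sp <- network$species
  idx <- stats::setNames(seq_len(nrow(sp)) - 1L, sp$name)
  rx <- network$reactions
  scale_code <- c(linear = 0L, fluid = 1L, surface = 2L)
  to_idx <- function(x) ifelse(is.na(x), -1L, idx[x])
  k <- rx$k
  # fluid-phase bimolecular constants are given in M^-1 s^-1; convert to
  # cm^3 mol^-1 s^-1 (1 M^-1 = 1000 cm^3/mol)
  k[rx$scale == "fluid"] <- k[rx$scale == "fluid"] * 1000
  cfg <- network$config
  tum <- cfg$compartments$tumor
  mt <- network$maintenance
  tr <- network$transport
  ly <- network$lymph
  sec <- network$secretion
  iinf <- if ("blood.drug" %in% sp$name) idx[["blood.drug"]] else -1L
  list(
    n = nrow(sp),
    comp = unname(comp_code[sp$compartment]),
    nr = nrow(rx),
    r1 = unname(to_idx(rx$r1)), r2 = unname(to_idx(rx$r2)),
    p1 = unname(to_idx(rx$p1)), p2 = unname(to_idx(rx$p2)),
    rsc = unname(scale_code[rx$scale]),
    rcomp = unname(comp_code[rx$compartment]),
    rk = as.double(k),
    ntr = nrow(tr),
    tb = unname(to_idx(tr$blood)), tt = unname(to_idx(tr$tissue)),
    tcomp = unname(comp_code[tr$compartment]),
    tperm = as.double(tr$perm_per_cm3),
    nly = nrow(ly),
    lf = unname(to_idx(ly$from)), lt = unname(to_idx(ly$to)),
    lymph = as.double(cfg$transport$lymph_flow),
    nsec = nrow(sec),
    isec = unname(to_idx(sec$species)), qsec = as.double(sec$rate),
    nmt = nrow(mt),
    imt = unname(to_idx(mt$species)),
    mmode = ifelse(mt$mode == "tumor_cell", 1L, 0L),
    mrho = as.double(mt$rho), mk = as.double(mt$k_maint),
    nang = length(network$ang_species),
    iang = unname(to_idx(network$ang_species)),
    Vn = as.double(cfg$compartments$normal$volume),
    Vp = as.double(cfg$compartments$blood$volume),
    phin = as.double(cfg$compartments$normal$fluid_fraction),
    fvasc = as.double(tum$f_vasc), fint0 = as.double(tum$f_int0),
    fintmin = as.double(tum$f_int_min), lambda = as.double(tum$lambda),
    cellvol = as.double(tum$cell_volume_um3 * 1e-12),
    k0 = 1.0, k1 = 1.0, psi = 20.0, Ang0 = 1.0, CAng = 1.0,
    variant = 1L, growth_on = 1L,
    iinf = iinf
  )
}

get_packed <- function(network) {
  if (is.null(network$packed)) make_packed(network) else network$packed
}

fill_growth <- function(pack, growth, growth_on) {
  pack$k0 <- as.double(growth$k0)
  pack$k1 <- as.double(growth$k1)
  pack$psi <- as.double(growth$psi)
  pack$Ang0 <- as.double(if (is.null(growth$Ang0)) 1.0 else growth$Ang0)
  pack$CAng <- as.double(if (is.null(growth$C_Ang)) 1.0 else growth$C_Ang)
  pack$variant <- if (identical(growth$variant, "model2")) 2L else 1L
  pack$growth_on <- as.integer(growth_on)
  pack
}

install_model <- function(pack) {
  .Call(C_set_model, pack)
  invisible(NULL)
}

set_infusion <- function(rate) {
  .Call(C_set_infusion, as.double(rate))
  invisible(NULL)
}

default_solver_opts <- function(opts = list()) {
  base <- list(method = "lsodes", rtol = 1e-6, atol_species = 1e-22,
               atol_V = 1e-9, maxsteps = 50000)
  for (nm in names(opts)) base[[nm]] <- opts[[nm]]
  if (base$rtol <= 0 || base$atol_species <= 0 || base$atol_V <= 0)
    stop("solver tolerances must be positive")
  base
}

run_segment <- function(y, times, opts, n_species) {
  atol <- c(rep(opts$atol_species, n_species), opts$atol_V)
  out <- deSolve::ode(y = y, times = times, func = "angiofit_derivs",
                      parms = numeric(0), dllname = "angiofit",
                      initfunc = "angiofit_initmod",
                      nout = 1, outnames = "Ang",
                      method = opts$method, rtol = opts$rtol, atol = atol,
                      maxsteps = opts$maxsteps, verbose = FALSE)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop("ODE solver failed at t = ", signif(out[nrow(out), 1], 6),
         " s (istate ", istate[1], ")")
  if (nrow(out) < length(times))
    stop("ODE solver stopped early; last valid time ",
         signif(out[nrow(out), 1], 6), " s")
  out
}

#' Evaluate the model right-hand side once
#'
#' Returns the time derivative of the full state (species + tumor volume)
#' for diagnostics and testing.  The angiogenic signal evaluated from the
#' state is attached as attribute `"Ang"`.
#'
#' @param network an `angiofit_network`.
#' @param t time (s).
#' @param state named state vector (species concentrations followed by `V`,
#'   or any order matching `c(network$species$name, "V")`).
#' @param growth growth-parameter list (defaults to the network config;
#'   `Ang0 = NULL` is replaced by 1 since a single derivative evaluation
#'   cannot resolve the basal signal).
#' @param growth_on logical; freeze the tumor volume if `FALSE`.
#' @return named derivative vector with attribute `Ang`.
#' @export
model_rhs <- function(network, t, state, growth = NULL, growth_on = TRUE) {
  nm <- c(network$species$name, "V")
  if (!is.null(names(state))) state <- state[nm]
  if (length(state) != length(nm))
    stop("state has ", length(state), " entries; model needs ", length(nm))
  bad <- which(!is.finite(state))
  if (length(bad))
    stop("non-finite state value for species ", nm[bad[1]])
  g <- resolve_growth(network, growth, allow_null_ang0 = TRUE)
  if (is.null(g$Ang0)) g$Ang0 <- 1.0
  install_model(fill_growth(get_packed(network), g, growth_on))
  out <- .Call(C_eval_rhs, as.double(t), as.double(state))
  d <- out[seq_along(nm)]
  names(d) <- nm
  attr(d, "Ang") <- out[length(out)]
  d
}

resolve_growth <- function(network, growth, allow_null_ang0 = FALSE) {
  g <- network$config$growth
  if (!is.null(growth)) for (nmm in names(growth)) g[[nmm]] <- growth[[nmm]]
  if (is.null(g$Ang0) && !allow_null_ang0)
    stop("Ang0 unresolved; use simulate() or supply growth$Ang0")
  g
}

#' Steady state of the species network at fixed tumor volume
#'
#' Integrates the species system with the tumor volume frozen at `V0`
#' until the angiogenic signal settles (relative drift below `tol` across
#' the final interval), starting from bare receptors at their target
#' densities and no free ligand.  This is the drug-free initial condition
#' used by [simulate()].
#'
#' @param network an `angiofit_network`.
#' @param V0 tumor volume (cm^3); default from the config.
#' @param duration integration horizon (s).
#' @param tol relative drift tolerance on the angiogenic signal.
#' @param solver_opts see [simulate()].
#' @return named state vector (species + `V`) with attribute `Ang` (basal
#'   angiogenic signal).
#' @export
steady_state <- function(network, V0 = NULL, duration = 60 * DAY,
                         tol = 1e-4, solver_opts = list()) {
  cfg <- network$config
  if (is.null(V0)) V0 <- cfg$growth$V0
  opts <- default_solver_opts(solver_opts)
  g0 <- list(k0 = 1e-6, k1 = 1e-6, psi = 20, Ang0 = 1, C_Ang = 1,
             variant = "model1")
  pack <- fill_growth(get_packed(network), g0, growth_on = FALSE)
  install_model(pack)
  set_infusion(0)
  y0 <- initial_state(network, V0)
  times <- seq(0, duration, length.out = 25)
  out <- run_segment(y0, times, opts, nrow(network$species))
  nsp <- nrow(network$species)
  ang_col <- ncol(out)
  a_last <- out[nrow(out), ang_col]
  a_prev <- out[nrow(out) - 1L, ang_col]
  if (a_last > 0 && abs(a_last - a_prev) / a_last > tol) {
    out <- run_segment(out[nrow(out), 1L + seq_len(nsp + 1)],
                       seq(0, duration, length.out = 25), opts, nsp)
    a_last <- out[nrow(out), ang_col]
  }
  st <- out[nrow(out), 1L + seq_len(nsp + 1)]
  st[st < 0 & st > -1e-15] <- 0
  names(st) <- c(network$species$name, "V")
  attr(st, "Ang") <- a_last
  st
}

# bare initial condition: maintained species at target density, V = V0
initial_state <- function(network, V0) {
  sp <- network$species
  y0 <- stats::setNames(numeric(nrow(sp)), sp$name)
  geo <- update_tumor_geometry(V0, network$config)
  cellvol <- network$config$compartments$tumor$cell_volume_um3 * 1e-12
  mt <- network$maintenance
  for (i in seq_len(nrow(mt))) {
    tgt <- if (mt$mode[i] == "tumor_cell")
      mt$rho[i] * geo$f_cell / cellvol else mt$rho[i]
    y0[mt$species[i]] <- tgt
  }
  # plasma a2m at its held concentration
  if ("blood.a2m" %in% names(y0))
    y0[["blood.a2m"]] <- network$config$soluble$a2m_conc
  c(y0, V = V0)
}

#' Simulate the coupled VEGF network and tumor growth
#'
#' Integrates the full system with a stiff-capable solver.  Drug infusion
#' windows are handled as exact segment boundaries: the integration is
#' restarted at the start and end of every infusion so no dose is smeared
#' by step control.
#'
#' @param network an `angiofit_network`.
#' @param growth named list overriding the config growth parameters
#'   (`k0`, `k1`, `psi`, `Ang0`, `C_Ang`, `variant`, `V0`).  `Ang0 = NULL`
#'   (the default) resolves to the basal angiogenic signal of the drug-free
#'   steady state at `V0`.
#' @param t_span numeric length-2, start and end time (s).
#' @param n_out number of output grid points (ignored when `times` given).
#' @param times explicit output grid (s).
#' @param schedule a [dose_schedule()] or `NULL` for no treatment.
#' @param init_state optional initial state (named, species + `V`); defaults
#'   to the drug-free steady state at `V0` frozen volume.
#' @param growth_on logical; `FALSE` freezes the tumor volume.
#' @param solver_opts list: `method`, `rtol`, `atol_species`, `atol_V`,
#'   `maxsteps`.
#' @return object of class `angiofit_trajectory`: `time` (s), `V` (cm^3),
#'   `Ang` (mol/cm^3 tissue), `state` (time x species matrix), `events`
#'   (data.frame), `growth` (resolved parameters), `species`, `network`.
#' @export
simulate_model <- function(network, growth = NULL,
                           t_span = c(0, 8 * WEEK), n_out = 200,
                           times = NULL, schedule = NULL,
                           init_state = NULL, growth_on = TRUE,
                           solver_opts = list()) {
  opts <- default_solver_opts(solver_opts)
  g <- resolve_growth(network, growth, allow_null_ang0 = TRUE)
  nsp <- nrow(network$species)
  if (is.null(init_state)) {
    ss <- steady_state(network, V0 = g$V0, solver_opts = solver_opts)
    init_state <- ss
    if (is.null(g$Ang0)) g$Ang0 <- attr(ss, "Ang")
  } else if (is.null(g$Ang0)) {
    inv <- init_state[network$ang_species]
    g$Ang0 <- sum(inv)
  }
  if (is.null(g$Ang0) || g$Ang0 <= 0) {
    if (growth_on)
      stop("basal angiogenic signal is zero; cannot gate growth (Ang0 = 0)")
    g$Ang0 <- 1   # inert: the growth law is not evaluated
  }
  if (is.null(times))
    times <- seq(t_span[1], t_span[2], length.out = n_out)
  times <- sort(unique(as.double(times)))
  y0 <- as.double(init_state[c(network$species$name, "V")])
  if (any(!is.finite(y0))) stop("non-finite initial state")
  if (y0[nsp + 1] <= 0) stop("initial tumor volume must be positive")

  segs <- infusion_segments(schedule, range(times), network$config$drug)
  install_model(fill_growth(get_packed(network), g, growth_on))

  res <- matrix(NA_real_, nrow = length(times), ncol = nsp + 2)
  y <- y0
  for (k in seq_len(nrow(segs))) {
    t0 <- segs$from[k]; t1 <- segs$to[k]
    inner <- times[times > t0 & times < t1]
    tt <- unique(c(t0, inner, t1))
    if (length(tt) < 2) tt <- c(t0, t1)
    set_infusion(segs$rate[k])
    out <- run_segment(y, tt, opts, nsp)
    y <- out[nrow(out), 1L + seq_len(nsp + 1)]
    hit <- match(round(out[, 1], 6), round(times, 6))
    ok <- !is.na(hit)
    res[hit[ok], ] <- out[ok, -1, drop = FALSE]
  }
  set_infusion(0)
  # columns of deSolve output after time: nsp species, V, Ang
  colnames(res) <- c(network$species$name, "V", "Ang")
  if (anyNA(res[, "V"]))
    stop("internal error: output grid not fully covered")
  V <- res[, "V"]
  if (any(V <= 0))
    stop("tumor volume reached zero at t = ",
         signif(times[which(V <= 0)[1]], 6), " s")
  state <- res[, seq_len(nsp), drop = FALSE]
  neg_floor <- -1e3 * opts$atol_species
  state[state < 0 & state > neg_floor] <- 0
  events <- segs[segs$rate > 0, c("from", "to", "rate")]
  structure(list(time = times, V = V, Ang = res[, "Ang"],
                 state = state, events = events, growth = g,
                 species = network$species$name, network = network),
            class = "angiofit_trajectory")
}

# split [t0,t1] into constant-infusion segments
infusion_segments <- function(schedule, t_range, drug_cfg) {
  t0 <- t_range[1]; t1 <- t_range[2]
  if (is.null(schedule) || schedule$dose <= 0)
    return(data.frame(from = t0, to = t1, rate = 0))
  rate <- infusion_rate(schedule$dose, drug_cfg)
  starts <- seq(schedule$T_start, schedule$T_start + schedule$horizon,
                by = schedule$interval)
  starts <- starts[starts < t1]
  bounds <- sort(unique(c(t0, t1,
                          starts[starts > t0 & starts < t1],
                          pmin(starts + schedule$infusion_duration, t1))))
  bounds <- bounds[bounds >= t0 & bounds <= t1]
  from <- bounds[-length(bounds)]
  to <- bounds[-1]
  in_window <- vapply(from, function(f)
    any(f >= starts - 1e-9 & f < starts + schedule$infusion_duration - 1e-9),
    logical(1))
  data.frame(from = from, to = to, rate = ifelse(in_window, rate, 0))
}

#' @export
print.angiofit_trajectory <- function(x, ...) {
  cat("angiofit trajectory:", length(x$time), "time points over",
      signif(diff(range(x$time)) / DAY, 4), "days\n")
  cat("  V: ", signif(x$V[1], 4), "->", signif(x$V[length(x$V)], 4),
      "cm^3 | Ang0 =", format(x$growth$Ang0, digits = 4), "\n")
  if (nrow(x$events)) cat("  infusions:", nrow(x$events), "\n")
  invisible(x)
}

#' @export
as.data.frame.angiofit_trajectory <- function(x, ...) {
  data.frame(time_s = x$time, time_days = x$time / DAY, V_cm3 = x$V,
             Ang = x$Ang, x$state, check.names = FALSE)
}

#' Total moles of each VEGF isoform across compartments
#'
#' Sums free ligand and every complex containing the isoform, weighted by
#' the volume of the compartment each species lives in (tumor volume taken
#' from the trajectory).  Used for conservation checks.
#'
#' @param traj an `angiofit_trajectory`.
#' @return matrix (time x isoform) of moles.
#' @export
ligand_totals <- function(traj) {
  net <- traj$network
  sp <- net$species
  cfg <- net$config
  vols <- cbind(normal = cfg$compartments$normal$volume,
                blood = cfg$compartments$blood$volume,
                tumor = traj$V)
  ligs <- names(cfg$ligands)
  out <- sapply(ligs, function(L) {
    members <- sp$name[!is.na(sp$ligand) & sp$ligand == L]
    tot <- numeric(length(traj$time))
    for (m in members) {
      cc <- sp$compartment[sp$name == m]
      v <- if (cc == "tumor") traj$V else
        cfg$compartments[[cc]]$volume
      tot <- tot + traj$state[, m] * v
    }
    tot
  })
  out
}
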