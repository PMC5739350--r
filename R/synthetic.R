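#' Generate a synthetic xenograft growth dataset
#'
#' Simulates control and (optionally) bevacizumab-treated tumor growth
#' with the full mechanistic model and known growth parameters, then
#' applies multiplicative lognormal measurement noise:
#' `V_obs = scale * V_true * exp(eps)`, `eps ~ N(0, sigma)` with
#' `sigma = log(1 + CV)` (caliper error scales with tumor size).  The
#' observation `scale` encodes the caliper volume-formula variant.  Ground
#' truth (parameters, seed, noiseless volumes) is recorded for recovery
#' experiments.
#'
#' @param network an `angiofit_network`.
#' @param true_params growth-parameter list (`k0`, `k1`, optional `psi`,
#'   `Ang0`; `Ang0 = NULL` resolves to the basal signal).
#' @param design list: `times_days` (measurement times, >= 3), `V0`
#'   (initial volume, cm^3), `arms` (subset of `c("control", "treated")`),
#'   `dose` (mg/kg, treated arm), `treat_start_day` (first dose; `NULL`
#'   starts treatment when the simulated volume reaches 0.1 cm^3),
#'   optional `obs_scale` and `volume_formula`.
#' @param noise_cv coefficient of variation of the measurement noise.
#' @param seed RNG seed (noise only; the model is deterministic).
#' @param id dataset identifier.
#' @return list of class `angiofit_dataset`.
#' @export
generate_growth_dataset <- function(network, true_params, design,
                                    noise_cv = 0.05, seed = 1,
                                    id = "synthetic") {
  if (length(design$times_days) < 3)
    stop("design needs at least 3 measurement time points")
  if (noise_cv < 0) stop("noise CV must be nonnegative")
  tms <- design$times_days
  if (is.unsorted(tms)) stop("design time points must be nondecreasing")
  arms <- if (is.null(design$arms)) "control" else design$arms
  obs_scale <- if (is.null(design$obs_scale)) 1 else design$obs_scale
  g <- resolve_growth(network, true_params, allow_null_ang0 = TRUE)
  g$V0 <- design$V0
  ss <- steady_state(network, V0 = design$V0)
  if (is.null(g$Ang0)) g$Ang0 <- attr(ss, "Ang")

  sim_times <- sort(unique(c(0, tms * DAY)))
  ctrl_sim <- simulate_model(network, growth = g, times = sim_times,
                             init_state = ss)
  v_true_ctrl <- ctrl_sim$V[match(tms * DAY, sim_times)]
  sigma <- log(1 + noise_cv)
  set.seed(seed)
  ctrl <- data.frame(
    time_days = tms,
    volume_cm3 = obs_scale * v_true_ctrl * exp(stats::rnorm(length(tms),
                                                            0, sigma)))
  treated <- NULL
  t_start <- NA_real_
  if ("treated" %in% arms) {
    t_start <- if (!is.null(design$treat_start_day))
      design$treat_start_day * DAY else detect_t_start(ctrl_sim)
    sched <- dose_schedule(design$dose, T_start = t_start,
                           horizon = max(tms) * DAY - t_start)
    trt_sim <- simulate_model(network, growth = g, times = sim_times,
                              init_state = ss, schedule = sched)
    v_true_trt <- trt_sim$V[match(tms * DAY, sim_times)]
    treated <- data.frame(
      time_days = tms,
      volume_cm3 = obs_scale * v_true_trt * exp(stats::rnorm(length(tms),
                                                             0, sigma)))
  }
  structure(list(
    id = id, control = ctrl, treated = treated,
    dose = if ("treated" %in% arms) design$dose else NA_real_,
    treat_start_day = if (is.na(t_start)) NA_real_ else t_start / DAY,
    V0 = design$V0, obs_scale = obs_scale,
    volume_formula = if (is.null(design$volume_formula)) "LxW2/2" else
      design$volume_formula,
    provenance = list(source = "synthetic", seed = seed, noise_cv = noise_cv,
                      truth = g[c("k0", "k1", "psi", "Ang0")],
                      v_true_control = v_true_ctrl)),
    class = "angiofit_dataset")
}

#' Six preset xenograft study templates
#'
#' A library of dataset designs spanning the qualitative diversity of
#' published MDA-MB-231 xenograft studies: different measurement cadences,
#' initial volumes, noise levels, doses (2 or 10 mg/kg), treatment starts,
#' and caliper volume-formula variants; the true growth parameters are
#' chosen so final control volumes span roughly 0.8-2.5 cm^3.  At least
#' two templates provide >= 3 pre-treatment measurements (for the
#' early-fitting protocol).
#'
#' @return named list of six design lists, each with a `true_growth`
#'   entry.
#' @export
preset_designs <- function() {
  list(
    slow_weekly = list(
      times_days = seq(0, 56, by = 7), V0 = 0.03, noise_cv = 0.08,
      arms = c("control", "treated"), dose = 2, treat_start_day = 15,
      volume_formula = "LxW2/2", obs_scale = 1,
      true_growth = list(k0 = 1.4e-6, k1 = 3.5e-7)),
    fast_saturating = list(
      times_days = seq(0, 42, by = 6), V0 = 0.05, noise_cv = 0.05,
      arms = c("control", "treated"), dose = 10, treat_start_day = 6,
      volume_formula = "LxW2/2", obs_scale = 1,
      true_growth = list(k0 = 2.0e-6, k1 = 2.5e-7)),
    short_dense = list(
      times_days = seq(0, 35, by = 5), V0 = 0.08, noise_cv = 0.06,
      arms = c("control", "treated"), dose = 10, treat_start_day = 5,
      volume_formula = "pi/6-LWH", obs_scale = 0.95,
      true_growth = list(k0 = 1.0e-6, k1 = 6.0e-7)),
    aggressive_exponential = list(
      times_days = seq(0, 49, by = 7), V0 = 0.02, noise_cv = 0.10,
      arms = c("control", "treated"), dose = 2, treat_start_day = 10,
      volume_formula = "LxW2/2", obs_scale = 1,
      true_growth = list(k0 = 2.5e-6, k1 = 3.0e-7)),
    long_late_treatment = list(
      times_days = seq(0, 63, by = 7), V0 = 0.01, noise_cv = 0.07,
      arms = c("control", "treated"), dose = 10, treat_start_day = 21,
      volume_formula = "LxW2/2", obs_scale = 1,
      true_growth = list(k0 = 1.8e-6, k1 = 5.0e-7)),
    twice_weekly_sampling = list(
      times_days = seq(0, 49, by = 3.5), V0 = 0.015, noise_cv = 0.05,
      arms = c("control", "treated"), dose = 10, treat_start_day = 14,
      volume_formula = "pi/6-LW2", obs_scale = 1.05,
      true_growth = list(k0 = 2.2e-6, k1 = 4.5e-7))
  )
}

#' Write / read a growth dataset (CSV + JSON sidecar)
#'
#' The CSV holds `dataset_id`, `arm`, `time_days`, `volume_cm3` (12
#' significant digits); a JSON sidecar (`<path>.json`) holds dose,
#' schedule, initial volume, observation scale, volume-formula tag, and
#' provenance.  Reading validates the schema: missing columns, unknown
#' arm labels and nonpositive volumes are schema errors naming the
#' offending row; unsorted times are accepted, sorted, and warned about.
#'
#' @param dataset an `angiofit_dataset`.
#' @param path CSV file path.
#' @return `read_growth_dataset()` returns an `angiofit_dataset`.
#' @export
write_growth_dataset <- function(dataset, path) {
  rows <- data.frame(dataset_id = dataset$id, arm = "control",
                     time_days = dataset$control$time_days,
                     volume_cm3 = dataset$control$volume_cm3)
  if (!is.null(dataset$treated))
    rows <- rbind(rows, data.frame(dataset_id = dataset$id, arm = "treated",
                                   time_days = dataset$treated$time_days,
                                   volume_cm3 = dataset$treated$volume_cm3))
  rows$time_days <- sprintf("%.12g", rows$time_days)
  rows$volume_cm3 <- sprintf("%.12g", rows$volume_cm3)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  meta <- dataset[c("id", "dose", "treat_start_day", "V0", "obs_scale",
                    "volume_formula", "provenance")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_growth_dataset
#' @export
read_growth_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dataset_id", "arm", "time_days", "volume_cm3")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("dataset file is missing columns: ", paste(miss, collapse = ", "))
  bad_arm <- which(!df$arm %in% c("control", "treated"))
  if (length(bad_arm))
    stop("unknown arm label '", df$arm[bad_arm[1]], "' at row ",
         bad_arm[1])
  bad_v <- which(!is.finite(df$volume_cm3) | df$volume_cm3 <= 0)
  if (length(bad_v))
    stop("nonpositive or missing volume at row ", bad_v[1])
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  arms <- split(df, df$arm)
  fix_arm <- function(a) {
    if (is.null(a)) return(NULL)
    if (is.unsorted(a$time_days)) {
      warning("unsorted measurement times; sorting")
      a <- a[order(a$time_days), ]
    }
    data.frame(time_days = a$time_days, volume_cm3 = a$volume_cm3)
  }
  structure(list(
    id = if (!is.null(meta$id)) meta$id else df$dataset_id[1],
    control = fix_arm(arms$control), treated = fix_arm(arms$treated),
    dose = if (!is.null(meta$dose)) meta$dose else NA_real_,
    treat_start_day = if (!is.null(meta$treat_start_day))
      meta$treat_start_day else NA_real_,
    V0 = if (!is.null(meta$V0)) meta$V0 else
      arms$control$volume_cm3[which.min(arms$control$time_days)],
    obs_scale = if (!is.null(meta$obs_scale)) meta$obs_scale else 1,
    volume_formula = if (!is.null(meta$volume_formula))
      meta$volume_formula else "unknown",
    provenance = if (!is.null(meta$provenance)) meta$provenance else
      list(source = "external")),
    class = "angiofit_dataset")
}

#' @export
print.angiofit_dataset <- function(x, ...) {
  cat("growth dataset '", x$id, "': ", nrow(x$control),
      " control points", sep = "")
  if (!is.null(x$treated))
    cat(",", nrow(x$treated), "treated points (", x$dose, "mg/kg )")
  cat("\n")
  invisible(x)
}
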