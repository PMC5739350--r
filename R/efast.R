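#' Extended FAST sampling design
#'
#' Builds the search-curve samples for the extended Fourier Amplitude
#' Sensitivity Test.  For each parameter of interest, one search curve per
#' random-phase resample assigns the maximum frequency to that parameter
#' and low complementary frequencies to all others; every parameter is
#' sampled along the curve as
#' `x(s) = lower + (upper - lower) * (1/2 + arcsin(sin(omega * s + phi))/pi)`
#' with `s` spanning `(-pi, pi)` over `NS` points.  Parameters flagged
#' `log = TRUE` are sampled in log10 space between the log bounds.
#'
#' The frequency of interest is `omega_max = floor((NS - 1) / (2 * Mi))`,
#' so the `Mi` harmonics used for the first-order index reach exactly the
#' Nyquist frequency `(NS - 1)/2`.  The complementary set cycles through
#' `2..max(1, floor(omega_max / (2 Mi)))` -- frequency 1 is avoided because
#' a complementary factor that traverses its range only once per curve
#' makes the along-curve variance (hence the total-order index) very noisy
#' for interacting models.  A dummy parameter (range 0..1, no effect on
#' any model) is appended automatically to calibrate index significance.
#'
#' @param ranges named list; each element `c(lower, upper)` or
#'   `list(min =, max =, log = TRUE/FALSE)`.
#' @param NS samples per search curve (>= 4 * Mi * omega_max + 1;
#'   default 257).
#' @param Mi interference factor (default 4).
#' @param n_resample random-phase resamples (default 5).
#' @param seed RNG seed; phases are drawn deterministically from it.
#' @param add_dummy append the inert dummy parameter (default TRUE).
#' @return list of class `angiofit_efast_design`: `par_names`, `ranges`,
#'   `NS`, `Mi`, `n_resample`, `omega_max`, `omega_comp`, and `samples` --
#'   a nested list `samples[[interest]][[resample]]` of NS x k matrices.
#' @export
efast_design <- function(ranges, NS = 257, Mi = 4, n_resample = 5,
                         seed = 1, add_dummy = TRUE) {
  ranges <- lapply(ranges, function(r) {
    if (is.list(r)) r else list(min = r[1], max = r[2], log = FALSE)
  })
  if (add_dummy)
    ranges$dummy <- list(min = 0, max = 1, log = FALSE)
  k <- length(ranges)
  if (k < 2) stop("eFAST needs at least two parameters")
  omega_max <- floor((NS - 1) / (2 * Mi))
  if (omega_max < 8)
    stop("NS = ", NS, " violates the frequency constraint; need NS >= ",
         16 * Mi + 1)
  omega_comp_max <- max(1, floor(omega_max / (2 * Mi)))
  comp_freqs <- if (omega_comp_max >= 2) 2:omega_comp_max else 1
  nms <- names(ranges)
  s <- pi * (2 * seq_len(NS) - 1 - NS) / NS
  samples <- vector("list", k)
  names(samples) <- nms
  phase_seed <- function(i, r) as.integer((seed * 1009L + i * 131L + r) %% .Machine$integer.max)
  for (i in seq_len(k)) {
    omega <- rep(0, k)
    omega[i] <- omega_max
    others <- setdiff(seq_len(k), i)
    omega[others] <- rep(comp_freqs, length.out = length(others))
    samples[[i]] <- lapply(seq_len(n_resample), function(r) {
      set.seed(phase_seed(i, r))
      phi <- stats::runif(k, 0, 2 * pi)
      X <- matrix(NA_real_, NS, k, dimnames = list(NULL, nms))
      for (j in seq_len(k)) {
        g <- 0.5 + asin(sin(omega[j] * s + phi[j])) / pi
        rj <- ranges[[j]]
        X[, j] <- if (isTRUE(rj$log))
          10^(log10(rj$min) + (log10(rj$max) - log10(rj$min)) * g)
        else rj$min + (rj$max - rj$min) * g
      }
      X
    })
  }
  structure(list(par_names = nms, ranges = ranges, NS = NS, Mi = Mi,
                 n_resample = n_resample, omega_max = omega_max,
                 omega_comp_max = omega_comp_max, seed = seed,
                 samples = samples),
            class = "angiofit_efast_design")
}

# first-order and total-order index from one search curve's outputs
fast_spectrum_indices <- function(Y, omega_i, Mi) {
  NS <- length(Y)
  if (any(!is.finite(Y))) stop("non-finite model output in eFAST curve")
  if (stats::var(Y) == 0)
    return(c(Si = 0, STi = 0, zero_variance = 1))
  A <- stats::fft(Y)
  P <- Mod(A[2:((NS - 1) %/% 2 + 1)])^2  # power at frequencies 1..(NS-1)/2
  Vtot <- sum(P)
  harm <- omega_i * seq_len(Mi)
  harm <- harm[harm <= length(P)]
  Vi <- sum(P[harm])
  Vcomp <- sum(P[seq_len(max(1, floor(omega_i / 2)))])
  c(Si = Vi / Vtot, STi = 1 - Vcomp / Vtot, zero_variance = 0)
}

#' eFAST sensitivity indices from model outputs
#'
#' Computes first-order (`Si`) and total-order (`STi`) indices for every
#' parameter from the Fourier spectrum of the model outputs along each
#' search curve: `Si` from the power at the interest frequency and its
#' first `Mi` harmonics, `STi` as one minus the fraction of variance at
#' the complementary low frequencies.
#'
#' @param Y nested list `Y[[interest]][[resample]]` of NS-vectors, as
#'   produced by evaluating a model over `design$samples`.
#' @param design an `angiofit_efast_design`.
#' @return data.frame with one row per (parameter, resample) plus
#'   per-parameter means; class `angiofit_efast`.
#' @export
efast_indices <- function(Y, design) {
  rows <- list()
  for (i in seq_along(design$par_names)) {
    for (r in seq_len(design$n_resample)) {
      y <- Y[[i]][[r]]
      if (length(y) != design$NS)
        stop("output length ", length(y), " != NS = ", design$NS)
      v <- fast_spectrum_indices(y, design$omega_max, design$Mi)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = design$par_names[i], resample = r,
        Si = unname(v["Si"]), STi = unname(v["STi"]),
        zero_variance = v["zero_variance"] == 1)
    }
  }
  per <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(Si, STi) ~ parameter, per, mean)
  sds <- stats::aggregate(cbind(Si, STi) ~ parameter, per, stats::sd)
  names(sds)[2:3] <- c("Si_sd", "STi_sd")
  summary <- merge(agg, sds, by = "parameter", sort = FALSE)
  summary <- summary[match(design$par_names, summary$parameter), ]
  structure(list(per_resample = per, summary = summary, design = design),
            class = "angiofit_efast")
}

#' Run eFAST on the tumor growth model
#'
#' Varies the tumor growth kinetic parameters (plus an inert dummy) over
#' their uncertainty ranges and measures the variance contribution of each
#' to the untreated tumor volume at the requested output times.  The
#' drug-free steady state of the species network is computed once (it does
#' not depend on the growth parameters) and reused for every model
#' evaluation.
#'
#' @param network an `angiofit_network`.
#' @param ranges named list of parameter ranges; defaults to the study
#'   ranges: `k0`, `k1` in `1e-8..1e-2` (log-sampled), `psi` in `0.1..50`
#'   (linear), `Ang0` in `1e-16..1e-14` (log-sampled).
#' @param output_times times (s) at which the untreated volume is the
#'   analyzed output; default the final simulated time (8 weeks).
#' @param NS,Mi,n_resample,seed see [efast_design()].
#' @param solver_opts see [simulate_model()].
#' @return list of class `angiofit_efast_run`: one `angiofit_efast` per
#'   output time (`indices`), `failed_curves` log, and the design.
#' @export
run_efast_on_model <- function(network, ranges = NULL,
                               output_times = 8 * WEEK, NS = 257, Mi = 4,
                               n_resample = 5, seed = 1,
                               solver_opts = list()) {
  if (is.null(ranges))
    ranges <- list(
      k0 = list(min = 1e-8, max = 1e-2, log = TRUE),
      k1 = list(min = 1e-8, max = 1e-2, log = TRUE),
      psi = list(min = 0.1, max = 50, log = FALSE),
      Ang0 = list(min = 1e-16, max = 1e-14, log = TRUE))
  design <- efast_design(ranges, NS = NS, Mi = Mi,
                         n_resample = n_resample, seed = seed)
  g0 <- resolve_growth(network, NULL, allow_null_ang0 = TRUE)
  ss <- steady_state(network, V0 = g0$V0, solver_opts = solver_opts)
  opts <- default_solver_opts(solver_opts)
  tmax <- max(output_times)
  times <- sort(unique(c(0, output_times)))
  out_idx <- match(output_times, times)
  growth_pars <- setdiff(design$par_names, "dummy")
  failed <- list()

  Y <- lapply(seq_along(design$par_names), function(i) {
    lapply(seq_len(design$n_resample), function(r) {
      X <- design$samples[[i]][[r]]
      out <- matrix(NA_real_, nrow(X), length(output_times))
      for (jj in seq_len(nrow(X))) {
        g <- g0
        for (p in growth_pars) g[[p]] <- X[jj, p]
        sim <- try(simulate_model(network, growth = g, times = times,
                                  init_state = ss, solver_opts = solver_opts),
                   silent = TRUE)
        if (inherits(sim, "try-error")) {
          failed[[length(failed) + 1L]] <<- list(interest = i, resample = r,
                                                 row = jj)
          next
        }
        out[jj, ] <- sim$V[out_idx]
      }
      out
    })
  })

  indices <- lapply(seq_along(output_times), function(ti) {
    Yt <- lapply(seq_along(design$par_names), function(i)
      lapply(seq_len(design$n_resample), function(r) {
        y <- Y[[i]][[r]][, ti]
        if (anyNA(y)) {
          # impute failed curve points by the curve median (logged)
          y[is.na(y)] <- stats::median(y, na.rm = TRUE)
        }
        y
      }))
    efast_indices(Yt, design)
  })
  names(indices) <- paste0("t_", output_times)
  structure(list(indices = indices, output_times = output_times,
                 failed_curves = failed, design = design),
            class = "angiofit_efast_run")
}

#' Compare parameter indices to the dummy parameter
#'
#' Two-sample Wilcoxon rank-sum test of each parameter's per-resample
#' total-order indices against the dummy's.
#'
#' @param efast an `angiofit_efast` (one output time).
#' @return data.frame `parameter`, `p_vs_dummy`, `significant` (p < 0.05).
#' @export
efast_significance <- function(efast) {
  per <- efast$per_resample
  dum <- per$STi[per$parameter == "dummy"]
  pars <- setdiff(unique(per$parameter), "dummy")
  p <- vapply(pars, function(pp) {
    x <- per$STi[per$parameter == pp]
    if (length(unique(c(x, dum))) == 1) return(1)
    suppressWarnings(stats::wilcox.test(x, dum,
                                        alternative = "greater")$p.value)
  }, numeric(1))
  data.frame(parameter = pars, p_vs_dummy = p, significant = p < 0.05)
}

#' @export
print.angiofit_efast <- function(x, ...) {
  cat("eFAST indices (NS =", x$design$NS, ", Mi =", x$design$Mi,
      ",", x$design$n_resample, "resamples)\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
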