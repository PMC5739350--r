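#' Default parameter bounds for fitting
#'
#' Each free parameter spans at least one order of magnitude:
#' `1e-8..1e-2` for `k0` (s^-1) and `k1` (cm^3/s), `1e-16..1e-14` for
#' `Ang0` (mol/cm^3 tissue).
#'
#' @return named list of `c(lower, upper)` pairs.
#' @export
default_bounds <- function() {
  list(k0 = c(1e-8, 1e-2), k1 = c(1e-8, 1e-2), Ang0 = c(1e-16, 1e-14))
}

#' Define a fitting problem
#'
#' Packages a control-arm growth dataset together with the model, the set
#' of free parameters, their bounds, and the multistart settings.  The
#' drug-free steady state at the dataset's initial volume is computed once
#' and reused by every objective evaluation; the basal angiogenic signal
#' of that steady state is the fixed `Ang0` whenever `Ang0` is not freed.
#'
#' The default frees `k0` and `k1` only: the growth law is invariant under
#' the joint rescaling (k0, k1, Ang0) -> (c k0, c k1, c Ang0), so freeing
#' all three leaves the parameters identified only up to that ray (see the
#' methods vignette).  Freeing `Ang0` as well reproduces the original
#' three-parameter protocol.
#'
#' @param dataset an `angiofit_dataset` (see [generate_growth_dataset()]
#'   or [read_growth_dataset()]); the control arm is used.
#' @param network an `angiofit_network`.
#' @param free character subset of `c("k0", "k1", "Ang0")`.
#' @param bounds named list of `c(lower, upper)`; see [default_bounds()].
#' @param n_starts number of multistart runs (default 30).
#' @param seed base seed; run `i` uses `seed + i`.
#' @return list of class `angiofit_fit_problem`.
#' @export
fit_problem <- function(dataset, network, free = c("k0", "k1"),
                        bounds = default_bounds(), n_starts = 30,
                        seed = 1) {
  stopifnot(inherits(dataset, "angiofit_dataset"))
  free <- match.arg(free, c("k0", "k1", "Ang0"), several.ok = TRUE)
  ctrl <- dataset$control
  if (nrow(ctrl) < 3) stop("control arm needs at least 3 data points")
  for (p in free) {
    b <- bounds[[p]]
    if (is.null(b) || b[1] <= 0 || b[1] >= b[2])
      stop("bounds for ", p, " must be positive with lower < upper")
  }
  V0 <- dataset$V0
  ss <- steady_state(network, V0 = V0)
  structure(list(dataset = dataset, network = network, free = free,
                 bounds = bounds[free], n_starts = n_starts, seed = seed,
                 V0 = V0, init_state = ss, Ang0_basal = attr(ss, "Ang"),
                 log = new.env(parent = emptyenv())),
            class = "angiofit_fit_problem")
}

# residual vector V_exp - V_sim at the measurement times
fit_residuals <- function(theta, problem) {
  g <- problem$network$config$growth
  g$V0 <- problem$V0
  g$Ang0 <- problem$Ang0_basal
  for (p in names(theta)) g[[p]] <- theta[[p]]
  ctrl <- problem$dataset$control
  tmeas <- ctrl$time_days * DAY
  sim <- try(simulate_model(problem$network, growth = g,
                            times = sort(unique(c(0, tmeas))),
                            init_state = problem$init_state),
             silent = TRUE)
  if (inherits(sim, "try-error")) {
    n_fail <- get0("n_fail", envir = problem$log, ifnotfound = 0L)
    assign("n_fail", n_fail + 1L, envir = problem$log)
    return(structure(rep(1e6, nrow(ctrl)), failed = TRUE))
  }
  Vs <- sim$V[match(round(tmeas, 6), round(sim$time, 6))]
  sc <- if (is.null(problem$dataset$obs_scale)) 1 else
    problem$dataset$obs_scale
  ctrl$volume_cm3 - sc * Vs
}

#' Sum of squared residuals
#'
#' Unweighted SSR between measured and simulated control-arm volumes,
#' with simulated volumes evaluated at the exact measurement times.  A
#' simulation failure yields a large finite penalty (1e12 plus a
#' bound-distance term) and is counted in `problem$log$n_fail`, so
#' bounded optimizers can continue.
#'
#' @param theta named vector of free-parameter values (natural scale).
#' @param problem an `angiofit_fit_problem`.
#' @return SSR (cm^6).
#' @export
sum_squared_residuals <- function(theta, problem) {
  r <- fit_residuals(theta, problem)
  if (isTRUE(attr(r, "failed"))) {
    d <- 0
    for (p in names(problem$bounds)) {
      b <- problem$bounds[[p]]
      x <- log10(theta[[p]])
      d <- d + max(0, log10(b[1]) - x, x - log10(b[2]))
    }
    return(1e12 * (1 + d))
  }
  sum(r^2)
}

#' Multistart bounded least-squares fit
#'
#' Runs `n_starts` bounded Levenberg-Marquardt minimizations of the SSR,
#' each initialized log-uniformly within the bounds from a run-indexed
#' seed, so the full ensemble is bit-reproducible.  Optimization is
#' performed in log10 parameter space (bounds span decades).
#'
#' @param problem an `angiofit_fit_problem`.
#' @return object of class `angiofit_fit_ensemble`: data.frame `runs`
#'   (start and fitted values, SSR, convergence), `best` (row index of
#'   the minimum-SSR run), and the problem.
#' @export
fit_dataset <- function(problem) {
  free <- problem$free
  lb <- log10(vapply(problem$bounds, `[`, numeric(1), 1))
  ub <- log10(vapply(problem$bounds, `[`, numeric(1), 2))
  runs <- vector("list", problem$n_starts)
  for (i in seq_len(problem$n_starts)) {
    set.seed(problem$seed + i)
    x0 <- stats::runif(length(free), lb, ub)
    names(x0) <- free
    fn <- function(x) {
      th <- stats::setNames(10^x, free)
      fit_residuals(th, problem)
    }
    # convergence status is recorded per run; iteration-limit warnings
    # from lmdif would otherwise flood multistart output
    res <- try(withCallingHandlers(
      minpack.lm::nls.lm(
        par = x0, lower = lb, upper = ub, fn = fn,
        control = minpack.lm::nls.lm.control(maxiter = 60, ftol = 1e-10,
                                             ptol = 1e-8)),
      warning = function(w) {
        if (grepl("lmdif|iterations", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
      silent = TRUE)
    if (inherits(res, "try-error")) {
      runs[[i]] <- data.frame(run = i, seed = problem$seed + i,
                              t(stats::setNames(10^x0, paste0("start_", free))),
                              t(stats::setNames(rep(NA_real_, length(free)),
                                                free)),
                              ssr = NA_real_, converged = FALSE)
      next
    }
    th <- stats::setNames(10^res$par, free)
    runs[[i]] <- data.frame(run = i, seed = problem$seed + i,
                            t(stats::setNames(10^x0, paste0("start_", free))),
                            t(th), ssr = sum(res$fvec^2),
                            converged = res$info %in% 1:4)
  }
  runs <- do.call(rbind, runs)
  if (all(is.na(runs$ssr)))
    stop("all ", problem$n_starts, " fitting runs failed; see problem$log")
  structure(list(runs = runs, best = which.min(runs$ssr),
                 problem = problem),
            class = "angiofit_fit_ensemble")
}

#' Select the best-fit subset of a multistart ensemble
#'
#' Keeps runs with SSR within a relative tolerance of the minimum:
#' `SSR <= (1 + tol) * min(SSR)`.
#'
#' @param ensemble an `angiofit_fit_ensemble`.
#' @param tol relative SSR tolerance (default 0.10).
#' @return the ensemble, with `runs` restricted to the selected subset and
#'   the selection rule recorded in `$selection`.
#' @export
select_best_fits <- function(ensemble, tol = 0.10) {
  ssr <- ensemble$runs$ssr
  smin <- min(ssr, na.rm = TRUE)
  keep <- !is.na(ssr) & ssr <= (1 + tol) * smin
  out <- ensemble
  out$runs <- ensemble$runs[keep, , drop = FALSE]
  out$best <- which.min(out$runs$ssr)
  out$selection <- list(rule = "ssr <= (1 + tol) * min(ssr)", tol = tol,
                        n_selected = sum(keep), ssr_min = smin)
  out
}

#' Pointwise confidence band of a fitted ensemble
#'
#' Two constructions are available:
#'
#' * `"covariance"` (default): the linearized least-squares covariance of
#'   the best fit -- `sigma^2 (J'J)^{-1}` in log10 parameter space, with
#'   `J` the finite-difference residual Jacobian and
#'   `sigma^2 = SSR/(n - p)` -- is sampled (`n_draws` parameter draws,
#'   truncated at the bounds), each draw is simulated, and the pointwise
#'   2.5th/97.5th percentiles of V(t) are returned.  This estimates
#'   sampling uncertainty and is the band used for coverage statements.
#' * `"members"`: pointwise percentiles across the ensemble members'
#'   trajectories (type-7 quantiles).  This visualizes multistart spread
#'   only; converged starts cluster, so the band can be degenerate.  A
#'   singleton ensemble yields a band equal to its trajectory.
#'
#' @param ensemble an `angiofit_fit_ensemble` (typically after
#'   [select_best_fits()]).
#' @param times output grid (s); defaults to 80 points spanning the data.
#' @param level confidence level (default 0.95).
#' @param method `"covariance"` or `"members"`.
#' @param n_draws parameter draws for the covariance band.
#' @param seed RNG seed for the draws.
#' @return data.frame `time`, `lower`, `median`, `upper`, `best`.
#' @export
confidence_band <- function(ensemble, times = NULL, level = 0.95,
                            method = c("covariance", "members"),
                            n_draws = 200, seed = 1) {
  method <- match.arg(method)
  pr <- ensemble$problem
  if (is.null(times)) {
    tmax <- max(pr$dataset$control$time_days) * DAY
    times <- seq(0, tmax, length.out = 80)
  }
  a <- (1 - level) / 2
  if (method == "members") {
    sims <- apply_ensemble(ensemble, times)
    return(data.frame(
      time = times,
      lower = apply(sims, 1, stats::quantile, probs = a),
      median = apply(sims, 1, stats::median),
      upper = apply(sims, 1, stats::quantile, probs = 1 - a),
      best = sims[, ensemble$best]))
  }
  free <- pr$free
  best <- ensemble$runs[ensemble$best, ]
  th <- log10(unlist(best[free]))
  resid_log <- function(x) fit_residuals(stats::setNames(10^x, free), pr)
  r0 <- resid_log(th)
  n <- length(r0); p <- length(free)
  h <- 1e-4
  J <- vapply(seq_len(p), function(j) {
    xp <- th; xp[j] <- xp[j] + h
    (resid_log(xp) - r0) / h
  }, numeric(n))
  sigma2 <- sum(r0^2) / max(1, n - p)
  Sigma <- tryCatch(sigma2 * solve(crossprod(J)),
                    error = function(e) diag(1e-8, p))
  # small-sample inflation: scale the sampled region so its `level`
  # contour matches the F-based likelihood region (Beale correction)
  infl <- sqrt(p * stats::qf(level, p, max(1, n - p)) /
                 stats::qchisq(level, p))
  ev <- eigen(Sigma, symmetric = TRUE)
  L <- infl * ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)
  lb <- log10(vapply(pr$bounds, `[`, numeric(1), 1))
  ub <- log10(vapply(pr$bounds, `[`, numeric(1), 2))
  set.seed(seed)
  draws <- t(pmin(pmax(th + L %*% matrix(stats::rnorm(p * n_draws), p),
                       lb), ub))
  tt <- sort(unique(c(0, times)))
  idx <- match(times, tt)
  sims <- vapply(seq_len(n_draws), function(i) {
    g <- pr$network$config$growth
    g$V0 <- pr$V0
    g$Ang0 <- pr$Ang0_basal
    for (jj in seq_len(p)) g[[free[jj]]] <- 10^draws[i, jj]
    sim <- try(simulate_model(pr$network, growth = g, times = tt,
                              init_state = pr$init_state), silent = TRUE)
    if (inherits(sim, "try-error")) rep(NA_real_, length(times)) else
      sim$V[idx]
  }, numeric(length(times)))
  best_v <- apply_ensemble(ensemble, times)[, ensemble$best]
  data.frame(
    time = times,
    lower = apply(sims, 1, stats::quantile, probs = a, na.rm = TRUE),
    median = apply(sims, 1, stats::median, na.rm = TRUE),
    upper = apply(sims, 1, stats::quantile, probs = 1 - a, na.rm = TRUE),
    best = best_v)
}

# matrix of V(t) columns, one per ensemble member
apply_ensemble <- function(ensemble, times) {
  pr <- ensemble$problem
  runs <- ensemble$runs
  vapply(seq_len(nrow(runs)), function(i) {
    g <- pr$network$config$growth
    g$V0 <- pr$V0
    g$Ang0 <- pr$Ang0_basal
    for (p in pr$free) g[[p]] <- runs[[p]][i]
    simulate_model(pr$network, growth = g,
                   times = sort(unique(c(0, times))),
                   init_state = pr$init_state)$V[match(times,
                     sort(unique(c(0, times))))]
  }, numeric(length(times)))
}

#' Nonparametric comparison of parameter sets across datasets
#'
#' Omnibus Kruskal-Wallis rank test (with tie correction) across all
#' groups, followed by pairwise two-group Kruskal-Wallis (equivalently
#' Wilcoxon rank-sum) tests with Benjamini-Hochberg false-discovery-rate
#' adjustment across all pairs.  Significance bins: `***` p <= 0.001,
#' `**` p <= 0.01, `*` p < 0.05.
#'
#' @param groups named list of numeric vectors (one per dataset), each of
#'   length >= 2.
#' @return list: `omnibus_p`, `omnibus_H`, `pairwise` (data.frame with
#'   raw and adjusted p and significance bin), `adjusted_matrix`.
#' @export
compare_parameter_sets <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least two values")
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1) {
    nm <- names(groups)
    pairs <- utils::combn(nm, 2)
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     p = 1, p_adj = 1, signif = "")
    return(list(omnibus_p = 1, omnibus_H = 0, pairwise = pw,
                adjusted_matrix = build_p_matrix(pw, nm)))
  }
  kw <- stats::kruskal.test(groups)
  nm <- names(groups)
  pairs <- utils::combn(nm, 2)
  p_raw <- apply(pairs, 2, function(pr) {
    g2 <- groups[pr]
    if (length(unique(unlist(g2))) == 1) return(1)
    stats::kruskal.test(g2)$p.value
  })
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  bins <- ifelse(p_adj <= 0.001, "***",
                 ifelse(p_adj <= 0.01, "**",
                        ifelse(p_adj < 0.05, "*", "")))
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   p = p_raw, p_adj = p_adj, signif = bins)
  list(omnibus_p = kw$p.value, omnibus_H = unname(kw$statistic),
       pairwise = pw, adjusted_matrix = build_p_matrix(pw, nm))
}

build_p_matrix <- function(pw, nm) {
  m <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_len(nrow(pw))) {
    m[pw$group1[i], pw$group2[i]] <- pw$p_adj[i]
    m[pw$group2[i], pw$group1[i]] <- pw$p_adj[i]
  }
  diag(m) <- 1
  m
}

#' @export
print.angiofit_fit_ensemble <- function(x, ...) {
  cat("angiofit multistart fit:", nrow(x$runs), "runs, free parameters:",
      paste(x$problem$free, collapse = ", "), "\n")
  b <- x$runs[x$best, ]
  cat("  best SSR:", signif(b$ssr, 5), "at",
      paste(sprintf("%s = %.4g", x$problem$free,
                    unlist(b[x$problem$free])), collapse = ", "), "\n")
  if (!is.null(x$selection))
    cat("  selected:", x$selection$n_selected, "runs (tol",
        x$selection$tol, ")\n")
  invisible(x)
}
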