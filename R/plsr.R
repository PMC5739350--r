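#' Fit a PLSR model by NIPALS
#'
#' Partial least squares regression (PLS2) via the nonlinear iterative
#' partial least squares algorithm.  Columns of X and Y are autoscaled
#' (mean 0, unit variance).  Per component: the weight vector is iterated
#' to convergence (tolerance 1e-12, max 500 iterations), scores/loadings
#' extracted, and both blocks deflated.  The sign of each component is
#' fixed so its largest-magnitude weight element is positive.
#'
#' @param X n x p numeric matrix or data.frame of predictors.
#' @param Y n x m numeric matrix or data.frame of responses.
#' @param n_components number of latent components (0 allowed: the model
#'   predicts column means).
#' @return list of class `angiofit_plsr`: centers/scales, `W` (weights),
#'   `T` (X-scores), `P` (X-loadings), `Q` (Y-loadings), `B` (regression
#'   coefficients, scaled space), `r2x`/`r2y` per component,
#'   `ssy_explained` per component, and dimensions.
#' @export
nipals_fit <- function(X, Y, n_components) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  n <- nrow(X)
  if (n < 2 || nrow(Y) != n) stop("X and Y need the same n >= 2 rows")
  if (anyNA(X) || anyNA(Y)) stop("missing values are not supported")
  p <- ncol(X); m <- ncol(Y)
  if (n_components > min(n - 1, p))
    stop("n_components exceeds the rank bound min(n - 1, p)")
  sdx <- apply(X, 2, stats::sd); sdy <- apply(Y, 2, stats::sd)
  if (any(sdx == 0))
    stop("zero-variance predictor column: ",
         colnames(X)[which(sdx == 0)[1]])
  if (any(sdy == 0))
    stop("zero-variance response column: ",
         colnames(Y)[which(sdy == 0)[1]])
  mx <- colMeans(X); my <- colMeans(Y)
  Xs <- scale(X, center = mx, scale = sdx)
  Ys <- scale(Y, center = my, scale = sdy)
  ssx0 <- sum(Xs^2); ssy0 <- sum(Ys^2)

  W <- matrix(0, p, 0); TT <- matrix(0, n, 0)
  P <- matrix(0, p, 0); Q <- matrix(0, m, 0)
  r2x <- r2y <- ssy_expl <- numeric(0)
  Xa <- Xs; Ya <- Ys
  for (a in seq_len(n_components)) {
    u <- Ya[, which.max(apply(Ya, 2, stats::var))]
    t_old <- rep(Inf, n)
    iter <- 0
    repeat {
      iter <- iter + 1
      w <- crossprod(Xa, u)
      w <- w / sqrt(sum(w^2))
      tt <- Xa %*% w
      q <- crossprod(Ya, tt) / sum(tt^2)
      u <- Ya %*% q / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) < 1e-12 * sqrt(sum(tt^2))) break
      if (iter >= 500)
        stop("NIPALS failed to converge in ", iter, " iterations")
      t_old <- tt
    }
    # sign convention: largest |w| element positive
    s <- sign(w[which.max(abs(w))])
    w <- s * w; tt <- s * tt; q <- s * q
    pp <- crossprod(Xa, tt) / sum(tt^2)
    ssy_a <- sum((tt %*% t(q))^2)
    Xa <- Xa - tt %*% t(pp)
    Ya <- Ya - tt %*% t(q)
    W <- cbind(W, w); TT <- cbind(TT, tt); P <- cbind(P, pp)
    Q <- cbind(Q, q)
    r2x <- c(r2x, sum((tt %*% t(pp))^2) / ssx0)
    r2y <- c(r2y, ssy_a / ssy0)
    ssy_expl <- c(ssy_expl, ssy_a)
  }
  B <- if (n_components > 0)
    W %*% solve(crossprod(P, W)) %*% t(Q) else matrix(0, p, m)
  dimnames(B) <- list(colnames(X), colnames(Y))
  structure(list(mx = mx, my = my, sdx = sdx, sdy = sdy,
                 W = W, T = TT, P = P, Q = Q, B = B,
                 r2x = r2x, r2y = r2y, ssy_explained = ssy_expl,
                 n_components = n_components, n = n, p = p, m = m,
                 x_names = colnames(X), y_names = colnames(Y)),
            class = "angiofit_plsr")
}

#' Predict from a fitted PLSR model
#'
#' @param object an `angiofit_plsr`.
#' @param newdata matrix/data.frame with the model's predictor columns.
#' @param ... unused.
#' @return matrix of predicted responses on the original scale.
#' @export
predict.angiofit_plsr <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)
  Xs <- scale(Xn, center = object$mx, scale = object$sdx)
  Ys <- Xs %*% object$B
  sweep(sweep(Ys, 2, object$sdy, `*`), 2, object$my, `+`)
}

#' PLSR fitness metrics
#'
#' R2X and R2Y from the full fit, and leave-one-out cross-validated Q2Y.
#' Inside each fold the centering and scaling are re-estimated from the
#' training rows only; `Q2Y = 1 - PRESS / TSS` with PRESS the sum of
#' squared LOO prediction errors and TSS the sum of squared deviations of
#' each left-out response from its training-fold mean (both in original
#' units).
#'
#' @param X,Y as in [nipals_fit()].
#' @param n_components number of components.
#' @return list of class `angiofit_plsr_metrics`: `r2x`, `r2y`, `q2y`,
#'   `vip`, `press`, `tss`.
#' @export
plsr_metrics <- function(X, Y, n_components) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 3) stop("leave-one-out cross-validation needs n >= 3")
  if (n_components >= n - 1)
    stop("n_components must be < n - 1 for leave-one-out CV")
  fit <- nipals_fit(X, Y, n_components)
  press <- 0; tss <- 0
  for (i in seq_len(n)) {
    f <- nipals_fit(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                    n_components)
    yhat <- predict(f, X[i, , drop = FALSE])
    press <- press + sum((Y[i, ] - yhat)^2)
    tss <- tss + sum((Y[i, ] - colMeans(Y[-i, , drop = FALSE]))^2)
  }
  structure(list(r2x = sum(fit$r2x), r2y = sum(fit$r2y),
                 q2y = 1 - press / tss, vip = vip_scores(fit),
                 press = press, tss = tss, fit = fit),
            class = "angiofit_plsr_metrics")
}

#' Variable importance of projection (VIP) scores
#'
#' `VIP_j = sqrt(p * sum_a(SSY_a * w_ja^2) / sum_a(SSY_a))` with `SSY_a`
#' the Y-variance explained by component `a` and `w` the (unit-norm)
#' component weights.  The mean of the squared VIPs over predictors is 1
#' by construction; predictors with VIP > 1 are important.
#'
#' @param model a fitted `angiofit_plsr` with at least one component.
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  if (model$n_components == 0)
    stop("VIP scores need at least one component")
  ssy <- model$ssy_explained
  w2 <- model$W^2
  v <- sqrt(model$p * as.vector(w2 %*% ssy) / sum(ssy))
  stats::setNames(v, model$x_names)
}

#' PLSR model-selection sweep
#'
#' Fits PLSR models for every requested component count and predictor
#' subset and reports the fitness metrics, as a report for manual model
#' selection (no automatic selection is performed).
#'
#' @param X,Y as in [nipals_fit()].
#' @param components integer vector of component counts.
#' @param subsets list of character vectors of predictor names; default
#'   the full set and all leave-one-out / leave-two-out subsets.
#' @return data.frame with columns `subset`, `n_components`, `r2x`,
#'   `r2y`, `q2y`.
#' @export
plsr_model_sweep <- function(X, Y, components = 1:4, subsets = NULL) {
  X <- as.matrix(X)
  if (is.null(subsets)) {
    nms <- colnames(X)
    subsets <- list(nms)
    for (d in 1:2)
      if (length(nms) - d >= 2)
        subsets <- c(subsets, utils::combn(nms, length(nms) - d,
                                           simplify = FALSE))
  }
  rows <- list()
  for (sb in subsets) for (nc in components) {
    nc_eff <- min(nc, length(sb), nrow(X) - 2)
    if (nc_eff < 1) next
    mt <- try(plsr_metrics(X[, sb, drop = FALSE], Y, nc_eff),
              silent = TRUE)
    if (inherits(mt, "try-error")) next
    rows[[length(rows) + 1L]] <- data.frame(
      subset = paste(sb, collapse = "+"), n_components = nc_eff,
      r2x = mt$r2x, r2y = mt$r2y, q2y = mt$q2y)
  }
  unique(do.call(rbind, rows))
}

#' @export
print.angiofit_plsr <- function(x, ...) {
  cat("PLSR (NIPALS):", x$n_components, "components,", x$n, "x", x$p,
      "predictors,", x$m, "responses\n")
  if (x$n_components > 0) {
    cat("  cumulative R2X:", signif(cumsum(x$r2x), 3), "\n")
    cat("  cumulative R2Y:", signif(cumsum(x$r2y), 3), "\n")
  }
  invisible(x)
}
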