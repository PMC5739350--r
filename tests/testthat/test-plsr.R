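test_that("NIPALS reproduces an SVD-based PLS oracle up to sign", {
  set.seed(14)
  for (rep in 1:5) {
    X <- matrix(rnorm(24), 6, 4)
    Y <- matrix(rnorm(12), 6, 2)
    fit <- nipals_fit(X, Y, 2)
    ora <- svd_pls_oracle(X, Y, 2)
    for (a in 1:2) {
      # same sign convention on both sides: compare directly
      expect_lt(max(abs(fit$W[, a] - ora$W[, a])), 1e-6)
      expect_lt(max(abs(fit$T[, a] - ora$T[, a])), 1e-6)
      expect_lt(max(abs(fit$P[, a] - ora$P[, a])), 1e-6)
      expect_lt(max(abs(fit$Q[, a] - ora$Q[, a])), 1e-6)
    }
    # successive X-scores are orthogonal
    ip <- crossprod(fit$T[, 1], fit$T[, 2]) /
      sqrt(sum(fit$T[, 1]^2) * sum(fit$T[, 2]^2))
    expect_lt(abs(ip), 1e-8)
  }
})

test_that("a response equal to an orthogonal predictor is fit in one
           component", {
  # with mutually orthogonal predictors the first weight vector selects
  # the matching column exactly (for correlated predictors one component
  # is not enough -- that case is covered by the full-rank fit below)
  set.seed(3)
  # orthogonalize against the intercept too, so the columns stay
  # orthogonal after autoscaling
  X <- qr.Q(qr(cbind(1, matrix(rnorm(30), 6, 5))))[, 2:5]
  colnames(X) <- paste0("x", 1:4)
  Y <- X[, 2, drop = FALSE]
  fit <- nipals_fit(X, Y, 1)
  expect_equal(sum(fit$r2y), 1, tolerance = 1e-8)
  expect_equal(unname(predict(fit, X)[, 1]), unname(Y[, 1]),
               tolerance = 1e-6)
})

test_that("zero components predict column means with zero R2Y", {
  set.seed(4)
  X <- matrix(rnorm(18), 6, 3)
  Y <- matrix(rnorm(12), 6, 2)
  fit <- nipals_fit(X, Y, 0)
  expect_equal(sum(fit$r2y), 0)
  pred <- predict(fit, X)
  expect_equal(unname(pred), matrix(colMeans(Y), 6, 2, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("degenerate inputs are rejected with named errors", {
  X <- cbind(a = rnorm(6), b = rep(2, 6))
  Y <- matrix(rnorm(6), 6, 1)
  expect_error(nipals_fit(X, Y, 1), "b")
  X2 <- matrix(rnorm(12), 6, 2)
  expect_error(nipals_fit(X2, Y, 5), "rank")
  expect_error(plsr_metrics(X2[1:2, ], Y[1:2, , drop = FALSE], 1),
               "n >= 3")
  expect_error(plsr_metrics(X2, Y, 5), "< n - 1")
})

test_that("exact linear maps give R2Y = 1 and Q2Y near 1", {
  set.seed(6)
  X <- matrix(rnorm(40), 10, 4)
  B <- matrix(c(1, -2, 0.5, 3, 0.2, -1, 2, 0.7), 4, 2)
  Y <- X %*% B
  m <- plsr_metrics(X, Y, 4)
  expect_equal(m$r2y, 1, tolerance = 1e-8)
  expect_gt(m$q2y, 0.95)
})

test_that("pure-noise responses cross-validate at or below zero", {
  q2 <- vapply(1:8, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(28), 7, 4)
    Y <- matrix(rnorm(7), 7, 1)
    plsr_metrics(X, Y, 2)$q2y
  }, numeric(1))
  expect_lt(mean(q2), 0)
})

test_that("Q2Y depends on in-fold rescaling (documented convention)", {
  set.seed(8)
  X <- matrix(rnorm(32), 8, 4)
  Y <- matrix(X %*% rnorm(4) + rnorm(8, sd = 0.5), 8, 1)
  m <- plsr_metrics(X, Y, 2)
  # naive variant: center/scale once on the full data and keep that
  # scaling fixed inside every fold (a minimal PLS without re-scaling)
  Xs <- scale(X); Ys <- scale(Y)
  pls_raw <- function(Xa, Ya, ncomp) {   # no internal autoscaling
    B <- matrix(0, ncol(Xa), 1)
    W <- P <- NULL; Q <- NULL
    X0 <- Xa; Y0 <- Ya
    for (a in seq_len(ncomp)) {
      w <- crossprod(X0, Y0)[, 1]; w <- w / sqrt(sum(w^2))
      tt <- X0 %*% w
      pp <- crossprod(X0, tt) / sum(tt^2)
      q <- crossprod(Y0, tt) / sum(tt^2)
      X0 <- X0 - tt %*% t(pp); Y0 <- Y0 - tt %*% t(q)
      W <- cbind(W, w); P <- cbind(P, pp); Q <- cbind(Q, q)
    }
    W %*% solve(crossprod(P, W)) %*% t(Q)
  }
  press <- 0; tss <- 0
  for (i in 1:8) {
    B <- pls_raw(Xs[-i, , drop = FALSE], Ys[-i, , drop = FALSE], 2)
    yh <- Xs[i, , drop = FALSE] %*% B
    press <- press + sum((Ys[i, ] - yh)^2)
    tss <- tss + sum((Ys[i, ] - mean(Ys[-i, ]))^2)
  }
  q2_naive <- 1 - press / tss
  expect_false(isTRUE(all.equal(m$q2y, q2_naive, tolerance = 1e-6)))
})

test_that("VIP scores obey their algebraic identities", {
  set.seed(9)
  X <- matrix(rnorm(30), 6, 5)
  Y <- matrix(rnorm(12), 6, 2)
  fit <- nipals_fit(X, Y, 2)
  v <- vip_scores(fit)
  expect_equal(mean(v^2), 1, tolerance = 1e-10)
  # single predictor: VIP identically 1
  f1 <- nipals_fit(matrix(rnorm(6), 6, 1), Y, 1)
  expect_equal(unname(vip_scores(f1)), 1, tolerance = 1e-12)
  # a predictor that alone drives Y dominates the VIP ranking
  x1 <- rnorm(20)
  X2 <- cbind(x1 = x1, x2 = rnorm(20))
  Y2 <- matrix(2 * x1 + rnorm(20, sd = 0.05), 20, 1)
  v2 <- vip_scores(nipals_fit(X2, Y2, 2))
  expect_gt(v2[["x1"]], 1)
  expect_lt(v2[["x2"]], 1)
})

test_that("the model-selection sweep reports all requested variants", {
  set.seed(10)
  X <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, c("k0", "k1",
                                                       "Ang0", "ratio")))
  Y <- matrix(rnorm(12), 6, 2)
  sw <- plsr_model_sweep(X, Y, components = 1:2)
  expect_true(all(c("subset", "n_components", "r2x", "r2y", "q2y") %in%
                    names(sw)))
  expect_true("k0+k1+Ang0+ratio" %in% sw$subset)
  expect_gt(nrow(sw), 10)
})
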