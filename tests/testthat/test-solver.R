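# ADMM update steps and the full fitting loop.

test_that("soft_threshold matches the analytic l1 proximal operator", {
  expect_equal(soft_threshold(0.5, 0.2), 0.3)
  expect_equal(soft_threshold(-0.1, 0.2), 0)
  x <- rnorm(100)
  expect_equal(soft_threshold(x, 0), x)
  # randomized grid against the closed form
  set.seed(21)
  for (t in c(0.01, 0.5, 2)) {
    x <- runif(1000, -5, 5)
    expect_equal(soft_threshold(x, t), sign(x) * pmax(abs(x) - t, 0))
  }
  expect_error(soft_threshold(x, -0.1), "nonnegative")
})

test_that("shrinkage is non-expansive elementwise", {
  set.seed(22)
  x <- rnorm(1e5, sd = 3)
  t <- runif(1, 0, 2)
  expect_true(all(abs(soft_threshold(x, t)) <= abs(x)))
})

# small consistent problem pieces used by several update tests
make_state <- function(V = 12, T = 7, K = 3, N = 2, seed = 23) {
  set.seed(seed)
  list(X = array(rnorm(V * T * K), c(V, T, K)),
       E = array(rnorm(V * T * K, sd = 0.1), c(V, T, K)),
       U = array(rnorm(V * T * K, sd = 0.1), c(V, T, K)),
       S = matrix(rnorm(V * N), V, N),
       B = matrix(rnorm(T * N), T, N),
       R = array(rnorm(N * N * K), c(N, N, K)),
       G = array(rnorm(N * N * K), c(N, N, K)),
       W = array(rnorm(N * N * K, sd = 0.1), c(N, N, K)),
       Y = matrix(rnorm(V * N), V, N),
       Q = matrix(rnorm(V * N, sd = 0.1), V, N))
}

test_that("update_B solves its normal equations and minimizes the quadratic model", {
  st <- make_state()
  alpha <- 0.7
  B <- slcTKD:::update_B(st$X, st$E, st$U, st$S, st$R, alpha, mu_B = 1)
  # normal equations
  StS <- crossprod(st$S)
  num <- Reduce(`+`, lapply(1:3, function(k) {
    crossprod(alpha * (st$X[, , k] - st$E[, , k]) + st$U[, , k] / 2,
              st$S %*% st$R[, , k])
  }))
  den <- diag(2) + alpha * Reduce(`+`, lapply(1:3, function(k) {
    crossprod(st$R[, , k], StS %*% st$R[, , k])
  }))
  expect_equal(B %*% den, num, tolerance = 1e-9)
  # perturbation probe on the augmented-Lagrangian terms involving B
  Lq <- function(Bm) {
    v <- sum(Bm^2)
    for (k in 1:3) {
      resid <- st$X[, , k] - st$S %*% st$R[, , k] %*% t(Bm) - st$E[, , k]
      v <- v + alpha * sum(resid^2) + sum(resid * st$U[, , k])
    }
    v
  }
  L0 <- Lq(B)
  set.seed(24)
  for (probe in 1:20) {
    Bp <- B
    ij <- c(sample(nrow(B), 1), sample(ncol(B), 1))
    Bp[ij[1], ij[2]] <- Bp[ij[1], ij[2]] + sample(c(-1, 1), 1) * 1e-4
    expect_gte(Lq(Bp), L0 - 1e-12)
  }
})

test_that("update_B degenerate cases: zero numerator and orthonormal closed form", {
  st <- make_state()
  z <- array(0, dim(st$X))
  expect_equal(slcTKD:::update_B(st$X, st$X, z, st$S, st$R, 0.5),
               matrix(0, 7, 2))
  # orthonormal S, identity core slices: closed form
  Sorth <- qr.Q(qr(st$S))
  Rid <- array(0, c(2, 2, 3)); for (k in 1:3) Rid[, , k] <- diag(2)
  alpha <- 0.9
  B <- slcTKD:::update_B(st$X, st$E, z, Sorth, Rid, alpha)
  closed <- Reduce(`+`, lapply(1:3, function(k) {
    alpha * crossprod(st$X[, , k] - st$E[, , k], Sorth)
  })) / (1 + alpha * 3)
  expect_equal(B, closed, tolerance = 1e-10)
})

test_that("update_S solves its normal equations; alpha = 0 reduces to the HQS pull", {
  st <- make_state()
  alpha <- 0.6; delta <- 2.5
  S <- slcTKD:::update_S(st$X, st$E, st$U, st$B, st$R, st$Y, st$Q,
                         alpha, delta)
  BtB <- crossprod(st$B)
  num <- delta * st$Y + st$Q + Reduce(`+`, lapply(1:3, function(k) {
    (alpha * (st$X[, , k] - st$E[, , k]) + st$U[, , k] / 2) %*%
      (st$B %*% t(st$R[, , k]))
  }))
  den <- (delta + 1) * diag(2) + alpha * Reduce(`+`, lapply(1:3, function(k) {
    st$R[, , k] %*% BtB %*% t(st$R[, , k])
  }))
  expect_equal(S %*% den, num, tolerance = 1e-9)
  # zero numerator
  z <- array(0, dim(st$X))
  expect_equal(slcTKD:::update_S(st$X, st$X, z, st$B, st$R,
                                 st$Y * 0, st$Q * 0, 0.5, delta),
               matrix(0, 12, 2))
  # alpha = 0, Q = 0: pure pull toward Y
  expect_equal(slcTKD:::update_S(st$X, st$E, st$U * 0, st$B, st$R,
                                 st$Y, st$Q * 0, 0, delta),
               delta * st$Y / (delta + 1), tolerance = 1e-10)
})

test_that("Y Newton step: quadratic limit, p = 1 hand check, stationarity", {
  st <- make_state()
  delta <- 2.5
  # xi = 0: Newton on a quadratic lands exactly at S - Q/delta in one step
  Y1 <- slcTKD:::update_Y_newton(st$Y, st$S, st$Q, delta, p = 0.3, xi = 0,
                                 iter_y = 1)
  expect_equal(Y1, st$S - st$Q / delta, tolerance = 1e-12)
  # p = 1, |Y| well away from zero: hand-computed single step
  Y <- matrix(c(0.5, -1.2, 2, -0.7), 2, 2)
  S <- matrix(0.3, 2, 2); Q <- matrix(0.05, 2, 2); xi <- 0.4
  Yd <- xi * sign(Y) + delta * (S - Y) - Q
  step <- Y - Yd / (-delta)
  expect_equal(slcTKD:::update_Y_newton(Y, S, Q, delta, p = 1, xi = xi,
                                        iter_y = 1), step)
  # a stationary point is returned unchanged
  Sfix <- Y - (xi * 0.3 * sign(Y) * abs(Y)^(0.3 - 1)) / delta + Q / delta
  Yfix <- slcTKD:::update_Y_newton(Y, Sfix, Q, delta, p = 0.3, xi = xi,
                                   iter_y = 5)
  expect_equal(Yfix, Y, tolerance = 1e-8)
  expect_error(slcTKD:::update_Y_newton(Y, S, Q, delta, p = 1.5, xi = xi,
                                        iter_y = 1), "p must")
})

test_that("core shrinkage: no-op, constant shrink, total shrinkage", {
  st <- make_state()
  expect_equal(slcTKD:::update_G_shrink(st$R, st$W * 0, beta = 1, lambda = 0),
               st$R)
  Rones <- array(1, c(2, 2, 3))
  G <- slcTKD:::update_G_shrink(Rones, Rones * 0, beta = 0.5, lambda = 0.4)
  expect_true(all(G == 0.6))
  G2 <- slcTKD:::update_G_shrink(st$R, st$W * 0, beta = 1,
                                 lambda = 2 * max(abs(st$R)) + 1)
  expect_true(all(G2 == 0))
  expect_error(slcTKD:::update_G_shrink(st$R, st$W, beta = 0, lambda = 1),
               "beta")
})

test_that("split-core Sylvester solve matches the Kronecker-vectorized oracle", {
  for (seed in 1:8) {
    st <- make_state(V = 10, T = 9, K = 3, N = 4, seed = 30 + seed)
    alpha <- runif(1, 0.1, 2); beta <- runif(1, 0.1, 2)
    for (coupling in c("attract", "repel")) {
      R <- slcTKD:::solve_R_sylvester(st$X, st$E, st$U, st$S, st$B,
                                      st$G, st$W, alpha, beta, coupling)
      sgn <- if (coupling == "attract") 1 else -1
      StS <- crossprod(st$S); BtB <- crossprod(st$B)
      A <- alpha * kronecker(t(BtB), StS) + beta * diag(16)
      for (k in 1:3) {
        Ak <- alpha * (st$X[, , k] - st$E[, , k]) + st$U[, , k] / 2
        rhs <- crossprod(st$S, Ak %*% st$B) +
          sgn * (beta * st$G[, , k] + st$W[, , k] / 2)
        expect_equal(as.numeric(R[, , k]), solve(A, as.numeric(rhs)),
                     tolerance = 1e-8)
        # residual of the matrix equation itself
        lhs <- alpha * StS %*% R[, , k] %*% BtB + beta * R[, , k]
        expect_lt(slcTKD:::fnorm(lhs - rhs), 1e-9 * slcTKD:::fnorm(rhs) + 1e-12)
      }
    }
  }
})

test_that("Sylvester solve limits: orthonormal factors and alpha -> 0", {
  st <- make_state(V = 10, T = 9, K = 2, N = 3, seed = 40)
  Sorth <- qr.Q(qr(st$S)); Borth <- qr.Q(qr(st$B))
  alpha <- 0.8; beta <- 0.6
  R <- slcTKD:::solve_R_sylvester(st$X, st$E, st$U, Sorth, Borth,
                                  st$G, st$W, alpha, beta)
  for (k in 1:2) {
    Ak <- alpha * (st$X[, , k] - st$E[, , k]) + st$U[, , k] / 2
    rhs <- crossprod(Sorth, Ak %*% Borth) + beta * st$G[, , k] + st$W[, , k] / 2
    expect_equal(R[, , k], rhs / (alpha + beta), tolerance = 1e-10)
  }
  R0 <- slcTKD:::solve_R_sylvester(st$X, st$E, st$U, st$S, st$B,
                                   st$G, st$W, 0, beta)
  for (k in 1:2) {
    rhs <- crossprod(st$S, (st$U[, , k] / 2) %*% st$B) +
      beta * st$G[, , k] + st$W[, , k] / 2
    expect_equal(R0[, , k], rhs / beta, tolerance = 1e-10)
  }
})

test_that("residual shrinkage: exact recovery, no shrink, total shrink", {
  st <- make_state()
  alpha <- 1.2
  # X equals the model exactly, U = 0: zero pre-shrink residual
  Xm <- tucker2_reconstruct(st$R, st$S, st$B)
  E <- slcTKD:::update_E_shrink(Xm, st$U * 0, st$S, st$R, st$B, alpha, 0.5)
  expect_true(all(E == 0))
  # gamma = 0: exact residual
  E2 <- slcTKD:::update_E_shrink(st$X, st$U * 0, st$S, st$R, st$B, alpha, 0)
  expect_equal(E2, st$X - Xm, tolerance = 1e-12)
  # threshold above everything: zero residual
  Emax <- max(abs(st$X - Xm))
  E3 <- slcTKD:::update_E_shrink(st$X, st$U * 0, st$S, st$R, st$B, 1,
                                 gamma = 2 * (Emax + 1))
  expect_true(all(E3 == 0))
  expect_error(slcTKD:::update_E_shrink(st$X, st$U, st$S, st$R, st$B, 0, 0.5),
               "alpha")
})

test_that("multiplier updates: ascent step, feasibility and zero-penalty no-ops", {
  st <- make_state()
  alpha <- 0.9; beta <- 0.7; delta <- 1.5
  out <- slcTKD:::update_multipliers(st$X, st$S, st$B, st$G, st$R, st$E,
                                     st$Y, st$U, st$W, st$Q,
                                     alpha, beta, delta)
  expect_equal(out$U, st$U + alpha * (st$X - tucker2_reconstruct(st$R, st$S, st$B) - st$E))
  expect_equal(out$W, st$W + beta * (st$G - st$R))
  expect_equal(out$Q, st$Q + delta * (st$Y - st$S))
  # exact feasibility leaves multipliers unchanged
  Xf <- tucker2_reconstruct(st$R, st$S, st$B) + st$E
  outf <- slcTKD:::update_multipliers(Xf, st$S, st$B, st$R, st$R, st$E,
                                      st$S, st$U, st$W, st$Q,
                                      alpha, beta, delta)
  expect_equal(outf$U, st$U); expect_equal(outf$W, st$W)
  expect_equal(outf$Q, st$Q)
  # zero step sizes
  out0 <- slcTKD:::update_multipliers(st$X, st$S, st$B, st$G, st$R, st$E,
                                      st$Y, st$U, st$W, st$Q, 0, 0, 0)
  expect_equal(out0$U, st$U); expect_equal(out0$W, st$W)
  expect_equal(out0$Q, st$Q)
})

test_that("penalty growth is geometric", {
  expect_equal(slcTKD:::update_penalties(1, 2, 1.3),
               c(alpha = 1.3, beta = 2.6))
  a <- 0.4
  for (i in 1:10) a <- slcTKD:::update_penalties(a, a, 1.3)[["alpha"]]
  expect_equal(a, 0.4 * 1.3^10, tolerance = 1e-12)
  expect_error(slcTKD:::update_penalties(1, 1, 1), "eta")
})

test_that("slctkd loop control: one iteration does one pass of every update", {
  sim <- tiny_sim()
  fit <- slctkd(sim$X, order = 3, control = slctkd_control(iter_max = 1))
  expect_length(fit$eps_trace, 1)
  expect_identical(fit$converged_reason, "max_iter")
  expect_equal(dim(fit$S), c(196L, 3L))
  expect_equal(dim(fit$G), c(3L, 3L, 4L))
})

test_that("slctkd is deterministic: identical runs give bitwise-equal traces", {
  sim <- tiny_sim()
  f1 <- slctkd(sim$X, order = 3, control = slctkd_control(iter_max = 15))
  f2 <- slctkd(sim$X, order = 3, control = slctkd_control(iter_max = 15))
  expect_identical(f1$eps_trace, f2$eps_trace)
  expect_identical(f1$S, f2$S)
})

test_that("on noiseless low-rank data the residual drops at least tenfold", {
  fit <- tiny_fit()
  expect_lt(fit$eps_trace[length(fit$eps_trace)], fit$eps_trace[1] / 10)
})

test_that("delta, lambda, gamma -> 0 reduce updates to unconstrained forms", {
  st <- make_state()
  # lambda = 0: G update returns the shifted split core unshrunk
  expect_equal(slcTKD:::update_G_shrink(st$R, st$W, 0.8, 0),
               st$R - st$W / 1.6)
  # gamma = 0 handled in the E tests; delta = 0 drops the Y coupling:
  S0 <- slcTKD:::update_S(st$X, st$E, st$U, st$B, st$R, st$Y, st$Q * 0,
                          0.7, delta = 0)
  BtB <- crossprod(st$B)
  num <- Reduce(`+`, lapply(1:3, function(k) {
    (0.7 * (st$X[, , k] - st$E[, , k]) + st$U[, , k] / 2) %*%
      (st$B %*% t(st$R[, , k]))
  }))
  den <- diag(2) + 0.7 * Reduce(`+`, lapply(1:3, function(k) {
    st$R[, , k] %*% BtB %*% t(st$R[, , k])
  }))
  expect_equal(S0 %*% den, num, tolerance = 1e-9)
})

test_that("invalid control parameters are rejected", {
  expect_error(slctkd_control(p = 0), "p must")
  expect_error(slctkd_control(p = 1.2), "p must")
  expect_error(slctkd_control(eta = 1), "eta")
  expect_error(slctkd_control(eps_min = 0), "positive")
  expect_error(slctkd(array(0, c(4, 4, 2)), 2), "zero")
  x <- rand_tensor(6, 5, 2)
  expect_error(slctkd(x, 10), "model order")
})
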