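# slcTKD solver: ADMM with half-quadratic splitting for the Tucker-2
# model with lp-sparse spatial maps, Frobenius-penalized factors, and
# l1-sparse core and residual tensors.
#
# Objective:
#   min  ||X - G x1 S x2 B - E||_F^2 + mu_S ||S||_F^2 + mu_B ||B||_F^2
#        + delta ||S||_p + lambda ||G||_1 + gamma ||E||_1
#
# handled by splitting the core (G = R) and the spatial factor (Y = S,
# half-quadratic splitting with weight xi), with Lagrange multipliers
# U (data fit), W (core split), Q (spatial split) and geometrically
# growing penalties alpha, beta.

#' Control parameters for the slcTKD solver
#'
#' Collects the sparsity, low-rank and optimizer settings. Defaults are
#' the published operating point for sparse (simulated-like) data:
#' \code{delta = 2.5}; for experimental fMRI data with less sparse
#' activations \code{delta = 0.4} is the recommended choice.
#'
#' @param delta Weight of the lp spatial-sparsity penalty on the shared
#'   spatial maps (larger for sparser activations).
#' @param p Exponent of the lp penalty, in (0, 1].
#' @param lambda l1 penalty weight on the core tensor.
#' @param gamma l1 penalty weight on the residual tensor.
#' @param eta Growth rate of the ADMM penalties alpha and beta, > 1.
#' @param xi Half-quadratic-splitting weight coupling the auxiliary
#'   sparse map variable Y to the lp penalty.
#' @param mu_S,mu_B Weights of the Frobenius (low-rank) penalties on the
#'   spatial and temporal factors; 1 by default.
#' @param iter_y Number of elementwise Newton steps on Y per outer
#'   iteration.
#' @param iter_max Maximum number of outer ADMM iterations.
#' @param eps_min Stop when the relative residual falls below this.
#' @param deps_min Stop when the relative change of the residual falls
#'   below this.
#' @param eps_num Floor applied to |Y| before the fractional powers
#'   |Y|^(p-1), |Y|^(p-2), which diverge at zero for p < 1.
#' @param y_descent Two derivative conventions are in circulation for
#'   the elementwise Newton step on the auxiliary sparse map Y. The
#'   default (FALSE) uses the fixed-point form, whose stationary points
#'   inflate sub-threshold entries mildly and which preserves good
#'   solutions at the default parameter values; TRUE uses the exact
#'   gradient/Hessian of the half-quadratic subproblem (a true descent
#'   direction), whose lp proximal threshold is aggressive at the
#'   default \code{delta}, \code{xi}. See the methods vignette.
#' @param core_coupling Sign convention of the split-core Sylvester
#'   update: \code{"attract"} (default) solves the update derived from
#'   the augmented Lagrangian, in which the split core R is pulled
#'   toward the shrunk core G; \code{"repel"} flips the sign of the
#'   G and W terms on the right-hand side. The repel form is provided
#'   for comparison only: it destabilizes the decomposition (see the
#'   methods vignette).
#' @param verbose If TRUE, message the (iter, eps, deps, alpha, beta)
#'   trace each iteration.
#' @return A list of class \code{"slctkd_control"}.
#' @export
slctkd_control <- function(delta = 2.5, p = 0.3, lambda = 0.4, gamma = 0.6,
                           eta = 1.3, xi = 0.4, mu_S = 1, mu_B = 1,
                           iter_y = 10L, iter_max = 300L,
                           eps_min = 1e-7, deps_min = 1e-4,
                           eps_num = 1e-8, y_descent = FALSE,
                           core_coupling = c("attract", "repel"),
                           verbose = FALSE) {
  if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
  if (eta <= 1) stop("eta must be > 1")
  if (delta < 0 || lambda < 0 || gamma < 0 || xi < 0) {
    stop("delta, lambda, gamma, xi must be nonnegative")
  }
  if (mu_S <= 0 || mu_B <= 0) stop("mu_S and mu_B must be positive")
  if (iter_y < 1L || iter_max < 1L) stop("iter_y and iter_max must be >= 1")
  if (eps_min <= 0 || deps_min <= 0 || eps_num <= 0) {
    stop("tolerances must be positive")
  }
  structure(list(delta = delta, p = p, lambda = lambda, gamma = gamma,
                 eta = eta, xi = xi, mu_S = mu_S, mu_B = mu_B,
                 iter_y = as.integer(iter_y), iter_max = as.integer(iter_max),
                 eps_min = eps_min, deps_min = deps_min, eps_num = eps_num,
                 y_descent = isTRUE(y_descent),
                 core_coupling = match.arg(core_coupling),
                 verbose = isTRUE(verbose)),
            class = "slctkd_control")
}

#' Soft-thresholding (l1 proximal) operator
#'
#' Elementwise \code{sign(x) * pmax(abs(x) - t, 0)}.
#'
#' @param x Numeric array or vector.
#' @param t Nonnegative scalar threshold.
#' @return Object shaped like \code{x}.
#' @export
soft_threshold <- function(x, t) {
  if (length(t) != 1L || !is.finite(t) || t < 0) {
    stop("threshold t must be a single nonnegative number")
  }
  sign(x) * pmax(abs(x) - t, 0)
}

# --- single update steps (internal; exercised directly by the tests) ---

# Solve num %*% den^{-1} for a symmetric matrix den known to satisfy
# den >= floor * I. Uses the symmetric eigendecomposition with the
# eigenvalues floored at that bound, which only corrects roundoff: once
# the ADMM penalties have grown by many orders of magnitude the system
# is too ill-conditioned for a plain LU solve.
solve_right_sympd <- function(num, den, floor) {
  e <- eigen((den + t(den)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, floor)
  (num %*% e$vectors) %*% (t(e$vectors) / ev)
}

# A_k = alpha (X_k - E_k) + U_k / 2, shared by the B, S and R updates.
admm_data_term <- function(X, E, U, alpha) alpha * (X - E) + U / 2

# B = [sum_k A_k' S R_k] [mu_B I + alpha sum_k R_k' S'S R_k]^{-1},
# solved as a symmetric linear system. A = alpha (X - E) + U/2 may be
# passed precomputed to avoid rebuilding it in every update of an
# iteration.
update_B <- function(X, E, U, S, R, alpha, mu_B = 1, A = NULL) {
  K <- dim(X)[3L]; N <- ncol(S)
  if (is.null(A)) A <- admm_data_term(X, E, U, alpha)
  StS <- crossprod(S)
  num <- matrix(0, dim(X)[2L], N)
  den <- mu_B * diag(N)
  for (k in seq_len(K)) {
    num <- num + crossprod(A[, , k], S %*% R[, , k])
    den <- den + alpha * crossprod(R[, , k], StS %*% R[, , k])
  }
  if (!all(is.finite(num)) || !all(is.finite(den))) {
    stop("update_B: non-finite values encountered")
  }
  solve_right_sympd(num, den, mu_B)
}

# S = [sum_k A_k B R_k' + delta Y + Q]
#     [(delta + mu_S) I + alpha sum_k R_k B'B R_k']^{-1}
update_S <- function(X, E, U, B, R, Y, Q, alpha, delta, mu_S = 1, A = NULL) {
  K <- dim(X)[3L]; N <- ncol(B)
  if (is.null(A)) A <- admm_data_term(X, E, U, alpha)
  BtB <- crossprod(B)
  num <- delta * Y + Q
  den <- (delta + mu_S) * diag(N)
  for (k in seq_len(K)) {
    num <- num + A[, , k] %*% (B %*% t(R[, , k]))
    den <- den + alpha * R[, , k] %*% BtB %*% t(R[, , k])
  }
  if (!all(is.finite(num)) || !all(is.finite(den))) {
    stop("update_S: non-finite values encountered")
  }
  solve_right_sympd(num, den, delta + mu_S)
}

# Elementwise Newton iterations on the auxiliary sparse-map variable Y.
# The default (fixed-point) convention uses
#   Yd  = xi p sgn(Y) |Y|^(p-1) + delta (S - Y) - Q
#   Ydd = xi p (p-1) |Y|^(p-2) - delta
# with |Y| floored at eps_num before the fractional powers; descent =
# TRUE swaps in the analytic gradient/Hessian of the HQS subproblem.
update_Y_newton <- function(Y, S, Q, delta, p, xi, iter_y, eps_num = 1e-8,
                            descent = FALSE) {
  if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
  if (iter_y < 1L) stop("iter_y must be >= 1")
  for (i in seq_len(iter_y)) {
    aY <- pmax(abs(Y), eps_num)
    if (!descent) {
      Yd <- xi * p * sign(Y) * aY^(p - 1) + delta * (S - Y) - Q
      Ydd <- xi * p * (p - 1) * aY^(p - 2) - delta
    } else {
      # analytic gradient/Hessian of xi ||Y||_p + delta ||S - Y||_F^2 + <S - Y, Q>
      Yd <- xi * p * sign(Y) * aY^(p - 1) - 2 * delta * (S - Y) - Q
      Ydd <- xi * p * (p - 1) * aY^(p - 2) + 2 * delta
    }
    Ydd[Ydd == 0] <- -eps_num   # degenerate only when xi*p*(p-1) and delta are both 0
    Y <- Y - Yd / Ydd
  }
  if (!all(is.finite(Y))) stop("update_Y_newton: non-finite Y")
  Y
}

# Core shrinkage: G_k = soft(R_k - W_k / (2 beta), lambda / (2 beta)).
update_G_shrink <- function(R, W, beta, lambda) {
  if (beta <= 0) stop("beta must be positive")
  soft_threshold(R - W / (2 * beta), lambda / (2 * beta))
}

# Split-core update: each slice solves the discrete-time Sylvester
# equation  alpha S'S R_k B'B + beta R_k = Rt_k + beta G_k + W_k/2
# with Rt_k = S' A_k B (coupling = "attract", the form derived from the
# augmented Lagrangian; "repel" flips the sign of the G and W terms).
# Both Gram matrices are symmetric PSD, so the system diagonalizes
# under their eigenbases and each slice is solved by an elementwise
# division by (alpha * ls_i * lb_j + beta).
solve_R_sylvester <- function(X, E, U, S, B, G, W, alpha, beta,
                              coupling = c("attract", "repel"), A = NULL) {
  if (alpha < 0 || beta <= 0) stop("need alpha >= 0 and beta > 0")
  sgn <- if (match.arg(coupling) == "attract") 1 else -1
  if (is.null(A)) A <- admm_data_term(X, E, U, alpha)
  K <- dim(X)[3L]; N <- ncol(S)
  es <- eigen(crossprod(S), symmetric = TRUE)
  eb <- eigen(crossprod(B), symmetric = TRUE)
  den <- alpha * outer(pmax(es$values, 0), pmax(eb$values, 0)) + beta
  if (any(den <= 0)) stop("solve_R_sylvester: singular system")  # cannot occur for beta > 0
  R <- array(0, dim = dim(G))
  for (k in seq_len(K)) {
    rhs <- crossprod(S, A[, , k] %*% B) + sgn * (beta * G[, , k] + W[, , k] / 2)
    R[, , k] <- es$vectors %*% ((crossprod(es$vectors, rhs %*% eb$vectors)) / den) %*%
      t(eb$vectors)
  }
  R
}

# Residual shrinkage: E_k = soft(X_k - S R_k B' + U_k/(2 alpha), gamma/(2 alpha)).
# recon = R x1 S x2 B may be passed precomputed.
update_E_shrink <- function(X, U, S, R, B, alpha, gamma, recon = NULL) {
  if (alpha <= 0) stop("alpha must be positive")
  if (is.null(recon)) recon <- tucker2_reconstruct(R, S, B)
  soft_threshold(X - recon + U / (2 * alpha), gamma / (2 * alpha))
}

# Multiplier ascent with the current (pre-growth) penalties.
update_multipliers <- function(X, S, B, G, R, E, Y, U, W, Q,
                               alpha, beta, delta, recon = NULL) {
  if (is.null(recon)) recon <- tucker2_reconstruct(R, S, B)
  list(U = U + alpha * (X - recon - E),
       W = W + beta * (G - R),
       Q = Q + delta * (Y - S))
}

# Geometric penalty growth.
update_penalties <- function(alpha, beta, eta) {
  if (eta <= 1) stop("eta must be > 1")
  c(alpha = eta * alpha, beta = eta * beta)
}

#' Fit the sparse low-rank Tucker-2 (slcTKD) model
#'
#' Decomposes a three-way (voxel x time x subject) tensor into shared
#' spatial maps \code{S}, shared time courses \code{B}, a sparse core
#' tensor \code{G} holding subject-specific intensities, and a sparse
#' residual tensor \code{E}, by ADMM with half-quadratic splitting on
#' the lp-constrained spatial factor.
#'
#' Starting from a truncated HOSVD of \code{X} (with \code{Y = S},
#' \code{R = G}, \code{E = X - G x1 S x2 B}, zero multipliers,
#' \code{alpha0 = K / ||X||_F}, \code{beta0 = K / ||R||_F}), each outer
#' iteration updates, in order: the temporal factor \code{B}; the
#' spatial factor \code{S}; \code{iter_y} Newton steps on the auxiliary
#' sparse map \code{Y}; the core \code{G} (soft-shrinkage); the split
#' core \code{R} (per-slice discrete-time Sylvester solve); the residual
#' \code{E} (soft-shrinkage); the three multipliers; and the penalties
#' (growth by \code{eta}). Iteration stops when the relative residual
#' \code{eps = ||X - G x1 S x2 B - E||_F / ||X||_F} drops below
#' \code{eps_min}, its relative change drops below \code{deps_min}, or
#' \code{iter_max} is reached. The pipeline is deterministic given
#' \code{X} and the control settings.
#'
#' @param X Data tensor (\code{V x T x K} array, or the result of
#'   \code{\link{load_fmri_tensor}} / \code{\link{simulate_fmri}}).
#' @param order Model order \code{N} (number of shared components),
#'   at most \code{min(V, T)}.
#' @param control A \code{\link{slctkd_control}} list.
#' @param keep_data Keep \code{X} inside the returned object (needed by
#'   \code{residuals()} and the core-feature extractors); default TRUE.
#' @return An object of class \code{"slctkd"}: a list with factors
#'   \code{S}, \code{B}, core \code{G}, residual \code{E}, split core
#'   \code{R}, auxiliary map \code{Y}, the per-iteration residual trace
#'   \code{eps_trace}, a diagnostic \code{trace} data frame (iter, eps,
#'   deps, alpha, beta), \code{converged_reason} (one of
#'   \code{"eps_min"}, \code{"deps_min"}, \code{"max_iter"}),
#'   \code{dims}, \code{control} and the matched \code{call}.
#' @examples
#' sim <- simulate_fmri(fmri_sim_spec(grid = c(12, 12), n_sources = 3,
#'                                    n_timepoints = 30, n_subjects = 3,
#'                                    snr_db = Inf, seed = 1))
#' fit <- slctkd(sim$X, order = 3,
#'               control = slctkd_control(iter_max = 20))
#' fit
#' @export
slctkd <- function(X, order, control = slctkd_control(), keep_data = TRUE) {
  cl <- match.call()
  meta <- if (inherits(X, "fmri_data")) X[c("voxel_index", "grid")] else NULL
  X <- as_data_tensor(X)
  stopifnot(inherits(control, "slctkd_control"))
  d <- dim(X)
  V <- d[1L]; Tn <- d[2L]; K <- d[3L]
  normX <- fnorm(X)
  if (normX == 0) stop("slctkd: ||X||_F is zero; nothing to decompose")
  N <- as.integer(order)

  ctl <- control
  init <- hosvd_init(X, N)
  S <- init$S; B <- init$B; G <- init$G
  Y <- S
  R <- G
  E <- X - tucker2_reconstruct(G, S, B)
  U <- array(0, dim = d)
  W <- array(0, dim = dim(G))
  Q <- matrix(0, V, N)
  alpha <- K / normX
  beta <- K / max(fnorm(R), .Machine$double.eps)

  eps_prev <- 1
  eps_trace <- numeric(0)
  trace <- vector("list", ctl$iter_max)
  reason <- "max_iter"

  for (iter in seq_len(ctl$iter_max)) {
    A <- admm_data_term(X, E, U, alpha)      # shared by the B, S, R updates
    B <- update_B(X, E, U, S, R, alpha, ctl$mu_B, A = A)
    S <- update_S(X, E, U, B, R, Y, Q, alpha, ctl$delta, ctl$mu_S, A = A)
    if (ctl$delta > 0) {
      Y <- update_Y_newton(Y, S, Q, ctl$delta, ctl$p, ctl$xi,
                           ctl$iter_y, ctl$eps_num, ctl$y_descent)
    }
    G <- update_G_shrink(R, W, beta, ctl$lambda)
    R <- solve_R_sylvester(X, E, U, S, B, G, W, alpha, beta,
                           ctl$core_coupling, A = A)
    recon <- tucker2_reconstruct(R, S, B)
    E <- update_E_shrink(X, U, S, R, B, alpha, ctl$gamma, recon = recon)
    mult <- update_multipliers(X, S, B, G, R, E, Y, U, W, Q,
                               alpha, beta, ctl$delta, recon = recon)
    U <- mult$U; W <- mult$W; Q <- mult$Q
    pen <- update_penalties(alpha, beta, ctl$eta)
    alpha <- pen[["alpha"]]; beta <- pen[["beta"]]

    eps <- relative_residual(X, G, S, B, E)
    if (!is.finite(eps)) {
      stop(sprintf(
        "slctkd diverged at iteration %d (last finite eps = %.6g)",
        iter, if (length(eps_trace)) eps_trace[length(eps_trace)] else 1))
    }
    deps <- abs(eps_prev - eps) / eps_prev
    eps_trace <- c(eps_trace, eps)
    trace[[iter]] <- c(iter = iter, eps = eps, deps = deps,
                       alpha = alpha, beta = beta)
    if (ctl$verbose) {
      message(sprintf("iter %3d  eps %.3e  deps %.3e  alpha %.3e  beta %.3e",
                      iter, eps, deps, alpha, beta))
    }
    eps_prev <- eps
    if (eps <= ctl$eps_min) { reason <- "eps_min"; break }
    if (deps <= ctl$deps_min) { reason <- "deps_min"; break }
  }

  out <- list(S = S, B = B, G = G, E = E, R = R, Y = Y,
              eps_trace = eps_trace,
              trace = as.data.frame(do.call(rbind, trace[!vapply(trace, is.null, TRUE)])),
              converged_reason = reason,
              dims = c(V = V, T = Tn, K = K, N = N),
              control = ctl, meta = meta, call = cl)
  if (keep_data) out$X <- X
  class(out) <- "slctkd"
  out
}
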