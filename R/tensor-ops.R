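# Tensor algebra for third-order (voxel x time x subject) arrays.
#
# Unfolding convention used throughout the package: the mode-n unfolding
# arranges the remaining modes in increasing order with the earlier mode
# varying fastest, so the mode-1 unfolding of a V x T x K tensor is
# V x (T*K) with the subject index varying slowest.

#' Mode-n unfolding of a third-order tensor
#'
#' Matricizes a three-way array along one mode. The remaining modes are
#' ordered increasingly, with the lower-numbered mode varying fastest
#' (so \code{tensor_unfold(X, 1)} on a \code{V x T x K} array is
#' \code{V x (T*K)} with subject varying slowest).
#'
#' @param x A numeric three-dimensional array.
#' @param mode Integer in \code{1:3}.
#' @return A matrix with \code{dim(x)[mode]} rows.
#' @export
tensor_unfold <- function(x, mode) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  mode <- check_mode(mode)
  d <- dim(x)
  perm <- switch(mode, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  y <- aperm(x, perm)
  dim(y) <- c(d[mode], prod(d[-mode]))
  y
}

#' Refold a mode-n unfolding into a third-order tensor
#'
#' Inverse of \code{\link{tensor_unfold}}.
#'
#' @param m Matrix holding the unfolding.
#' @param mode Integer in \code{1:3}, the unfolded mode.
#' @param dims Length-3 integer vector, the target tensor dimensions.
#' @return A three-dimensional array with \code{dim = dims}.
#' @export
tensor_fold <- function(m, mode, dims) {
  mode <- check_mode(mode)
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, nrow(m) == dims[mode],
            ncol(m) == prod(dims[-mode]))
  perm <- switch(mode, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  y <- array(m, dim = c(dims[mode], dims[-mode]))
  aperm(y, order(perm))
}

#' Mode-n product of a tensor with a matrix
#'
#' Multiplies every mode-\code{n} fiber of a third-order tensor by a
#' matrix: \code{(X x_n M)} has the size of \code{X} with mode \code{n}
#' replaced by \code{nrow(M)}.
#'
#' @param x A numeric three-dimensional array.
#' @param m A numeric matrix with \code{ncol(m) == dim(x)[mode]}.
#' @param mode Integer in \code{1:3}.
#' @return A three-dimensional array.
#' @export
mode_n_product <- function(x, m, mode) {
  stopifnot(is.array(x), length(dim(x)) == 3L, is.matrix(m))
  mode <- check_mode(mode)
  d <- dim(x)
  if (ncol(m) != d[mode]) {
    stop(sprintf(
      "mode-%d product: matrix has %d columns but tensor has size %d along mode %d",
      mode, ncol(m), d[mode], mode))
  }
  newd <- d
  newd[mode] <- nrow(m)
  tensor_fold(m %*% tensor_unfold(x, mode), mode, newd)
}

#' Tucker-2 reconstruction from core and factor matrices
#'
#' Computes \code{G x_1 S x_2 B}, i.e. the tensor whose k-th frontal
#' slice is \code{S \%*\% G[,,k] \%*\% t(B)}.
#'
#' @param G Core tensor, \code{N x N x K}.
#' @param S Spatial factor, \code{V x N}.
#' @param B Temporal factor, \code{T x N}.
#' @return A \code{V x T x K} array.
#' @export
tucker2_reconstruct <- function(G, S, B) {
  stopifnot(is.array(G), length(dim(G)) == 3L, is.matrix(S), is.matrix(B))
  if (ncol(S) != dim(G)[1L] || ncol(B) != dim(G)[2L]) {
    stop(sprintf(
      "tucker2_reconstruct: core is %d x %d x %d but S has %d and B has %d columns",
      dim(G)[1L], dim(G)[2L], dim(G)[3L], ncol(S), ncol(B)))
  }
  K <- dim(G)[3L]
  out <- array(0, dim = c(nrow(S), nrow(B), K))
  tB <- t(B)
  for (k in seq_len(K)) out[, , k] <- S %*% G[, , k] %*% tB
  out
}

#' Truncated HOSVD initialization for the Tucker-2 model
#'
#' Sets the spatial factor to the \code{N} leading left singular vectors
#' of the mode-1 unfolding, the temporal factor to the \code{N} leading
#' left singular vectors of the mode-2 unfolding, and the core to
#' \code{G_k = t(S) X_k B}. Singular-vector signs are fixed by forcing
#' the largest-magnitude entry of each column nonnegative, so the result
#' is reproducible run to run. If an unfolding has rank below \code{N}
#' the missing columns are zero-padded with a warning, keeping all
#' downstream shapes at \code{N}; an all-zero tensor accordingly yields
#' zero factors (with warnings), while the solver itself rejects it.
#'
#' @param X Data tensor, \code{V x T x K}, all entries finite.
#' @param N Model order, \code{N <= min(V, T)}.
#' @return List with components \code{S} (\code{V x N}), \code{B}
#'   (\code{T x N}) and \code{G} (\code{N x N x K}).
#' @export
hosvd_init <- function(X, N) {
  X <- as_data_tensor(X)
  d <- dim(X)
  N <- as.integer(N)
  if (N < 1L || N > min(d[1L], d[2L])) {
    stop(sprintf("model order N = %d must lie in [1, min(V, T)] = [1, %d]",
                 N, min(d[1L], d[2L])))
  }
  S <- leading_left_sv(tensor_unfold(X, 1L), N, "mode-1")
  B <- leading_left_sv(tensor_unfold(X, 2L), N, "mode-2")
  G <- array(0, dim = c(N, N, d[3L]))
  for (k in seq_len(d[3L])) G[, , k] <- crossprod(S, X[, , k] %*% B)
  list(S = S, B = B, G = G)
}

# N leading left singular vectors with deterministic signs; zero-pads
# (with a warning) when the numerical rank falls below N.
leading_left_sv <- function(m, N, what) {
  sv <- svd(m, nu = min(N, min(dim(m))), nv = 0L)
  tol <- max(dim(m)) * .Machine$double.eps * max(sv$d[1L], 0)
  r <- sum(sv$d > tol)
  U <- sv$u[, seq_len(min(N, ncol(sv$u))), drop = FALSE]
  if (r < N) {
    warning(sprintf(
      "%s unfolding has numerical rank %d < N = %d; padding with zero columns",
      what, r, N))
    if (ncol(U) > r) U[, (r + 1L):ncol(U)] <- 0
    if (ncol(U) < N) U <- cbind(U, matrix(0, nrow(U), N - ncol(U)))
  }
  fix_sv_signs(U)
}

# Flip each column so its largest-magnitude entry is nonnegative.
fix_sv_signs <- function(U) {
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (length(i) && U[i, j] < 0) U[, j] <- -U[, j]
  }
  U
}

#' Relative Frobenius residual of a Tucker-2 fit
#'
#' Returns \code{||X - G x_1 S x_2 B - E||_F / ||X||_F}, the
#' convergence measure tracked by the solver.
#'
#' @param X Data tensor, nonzero.
#' @param G,S,B Core tensor and factor matrices.
#' @param E Residual tensor, same shape as \code{X}; defaults to zero.
#' @return A nonnegative scalar.
#' @export
relative_residual <- function(X, G, S, B, E = NULL) {
  nx <- fnorm(X)
  if (nx == 0) stop("relative_residual: ||X||_F is zero")
  R <- X - tucker2_reconstruct(G, S, B)
  if (!is.null(E)) R <- R - E
  fnorm(R) / nx
}

fnorm <- function(x) sqrt(sum(x * x))

check_mode <- function(mode) {
  mode <- as.integer(mode)
  if (length(mode) != 1L || is.na(mode) || mode < 1L || mode > 3L) {
    stop("mode must be a single integer in 1:3")
  }
  mode
}

# Coerce/validate a V x T x K data tensor (plain array or fmri_data).
as_data_tensor <- function(X) {
  if (inherits(X, "fmri_data")) X <- X$X
  if (inherits(X, "slctkd_sim")) X <- X$X
  if (!is.array(X) || length(dim(X)) != 3L) {
    stop("X must be a three-dimensional (voxel x time x subject) array")
  }
  if (!all(is.finite(X))) stop("X contains non-finite entries")
  X
}
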