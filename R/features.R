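# Core-tensor feature extraction: subject-specific intensities and
# spatial/temporal feature matrices, plus k-means subject clustering.
#
# All three extractors are views of the same algebra: with
# St = pinv(S) (N x V) and Bt = pinv(t(B)) (T x N),
#   core slice      G_k       = St (X_k - E_k) Bt
#   spatial feats   G_S(i, k) = St[i, ] %*% Z_k[, j],  Z_k = (X_k - E_k) Bt
#   temporal feats  G_B(j, k) = M_k[i, ] %*% Bt[, j],  M_k = St (X_k - E_k)
# so G_S is the column-j read-out and G_B the row-i read-out of the
# reconstructed core.

# Moore-Penrose pseudo-inverse via SVD with a relative cutoff.
pinv <- function(M, tol_rel = 1e-10) {
  sv <- svd(M)
  keep <- sv$d > tol_rel * sv$d[1L]
  if (!all(keep)) {
    warning(sprintf(
      "rank-deficient matrix in pseudo-inverse (condition number %.3g); truncating",
      sv$d[1L] / sv$d[length(sv$d)]))
  }
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

# Accept either a fitted slctkd object or explicit (X, E, S, B).
resolve_fit_args <- function(X, E, S, B) {
  if (inherits(X, "slctkd")) {
    fit <- X
    if (is.null(fit$X)) stop("fit was made with keep_data = FALSE")
    list(X = fit$X, E = fit$E, S = fit$S, B = fit$B)
  } else {
    list(X = as_data_tensor(X), E = E, S = S, B = B)
  }
}

#' Reconstruct the core tensor from data and factors
#'
#' Computes \code{G_k = pinv(S) (X_k - E_k) pinv(t(B))} slice by slice,
#' using SVD-based pseudo-inverses. This re-derives the core directly
#' from the data and is the common root of the intensity and feature
#' extractors.
#'
#' @param X Data tensor (\code{V x T x K}) or a fitted \code{"slctkd"}
#'   object (in which case \code{E}, \code{S}, \code{B} are taken from
#'   the fit).
#' @param E Residual tensor, same shape as \code{X}.
#' @param S,B Spatial (\code{V x N}) and temporal (\code{T x N}) factor
#'   matrices, full column rank (a warning with the condition number is
#'   emitted otherwise and a truncated pseudo-inverse used).
#' @return An \code{N x N x K} array.
#' @export
core_from_data <- function(X, E = NULL, S = NULL, B = NULL) {
  a <- resolve_fit_args(X, E, S, B)
  St <- pinv(a$S)
  Bt <- pinv(t(a$B))
  K <- dim(a$X)[3L]; N <- ncol(a$S)
  G <- array(0, dim = c(N, N, K))
  for (k in seq_len(K)) G[, , k] <- St %*% (a$X[, , k] - a$E[, , k]) %*% Bt
  G
}

#' Subject-specific intensities from the core tensor
#'
#' Reads the mode-3 fiber \code{G[i, j, ]}: the intensity of every
#' subject under spatial component \code{i} and temporal component
#' \code{j}.
#'
#' @param G Core tensor (\code{N x N x K}) or a fitted \code{"slctkd"}
#'   object (its \code{G} is used).
#' @param i,j Spatial and temporal component indices in \code{1:N}.
#'   For a component of interest the diagonal pair \code{i = j} is the
#'   usual choice.
#' @param normalize If TRUE, scale to \code{[-1, 1]} by the maximum
#'   absolute value.
#' @return Numeric vector of length \code{K}.
#' @export
subject_intensities <- function(G, i, j = i, normalize = FALSE) {
  if (inherits(G, "slctkd")) G <- G$G
  stopifnot(is.array(G), length(dim(G)) == 3L)
  N1 <- dim(G)[1L]; N2 <- dim(G)[2L]
  if (i < 1 || i > N1 || j < 1 || j > N2) {
    stop(sprintf("component indices (%d, %d) out of range [1, %d] x [1, %d]",
                 i, j, N1, N2))
  }
  v <- G[i, j, ]
  if (normalize) {
    m <- max(abs(v))
    if (m > 0) v <- v / m
  }
  v
}

#' Spatial feature matrix from the core tensor
#'
#' For a fixed temporal component \code{j}, row \code{i} and column
#' \code{k} hold \code{pinv(S)[i, ] \%*\% Z_k[, j]} with
#' \code{Z_k = (X_k - E_k) pinv(t(B))}: the spatial fingerprint of every
#' subject along component \code{j}. Identical to reading column
#' \code{j} of each \code{\link{core_from_data}} slice.
#'
#' @inheritParams core_from_data
#' @param j Temporal component index.
#' @return An \code{N x K} matrix (subjects in columns).
#' @export
spatial_features <- function(X, E = NULL, S = NULL, B = NULL, j) {
  a <- resolve_fit_args(X, E, S, B)
  N <- ncol(a$S)
  if (j < 1 || j > N) stop(sprintf("temporal component j = %d out of 1:%d", j, N))
  St <- pinv(a$S)
  Bt <- pinv(t(a$B))
  K <- dim(a$X)[3L]
  out <- matrix(0, N, K,
                dimnames = list(NULL, paste0("subject", seq_len(K))))
  for (k in seq_len(K)) {
    Zkj <- (a$X[, , k] - a$E[, , k]) %*% Bt[, j]
    out[, k] <- St %*% Zkj
  }
  attr(out, "component") <- c(j = j)
  attr(out, "feature_source") <- "spatial"
  out
}

#' Temporal feature matrix from the core tensor
#'
#' For a fixed spatial component \code{i}, row \code{j} and column
#' \code{k} hold \code{M_k[i, ] \%*\% pinv(t(B))[, j]} with
#' \code{M_k = pinv(S) (X_k - E_k)}: the temporal fingerprint of every
#' subject along component \code{i}. Identical to reading row \code{i}
#' of each \code{\link{core_from_data}} slice.
#'
#' @inheritParams core_from_data
#' @param i Spatial component index.
#' @return An \code{N x K} matrix (subjects in columns).
#' @export
temporal_features <- function(X, E = NULL, S = NULL, B = NULL, i) {
  a <- resolve_fit_args(X, E, S, B)
  N <- ncol(a$S)
  if (i < 1 || i > N) stop(sprintf("spatial component i = %d out of 1:%d", i, N))
  St <- pinv(a$S)
  Bt <- pinv(t(a$B))
  K <- dim(a$X)[3L]
  out <- matrix(0, N, K,
                dimnames = list(NULL, paste0("subject", seq_len(K))))
  for (k in seq_len(K)) {
    Mki <- St[i, ] %*% (a$X[, , k] - a$E[, , k])
    out[, k] <- as.numeric(Mki %*% Bt)
  }
  attr(out, "component") <- c(i = i)
  attr(out, "feature_source") <- "temporal"
  out
}

#' Cluster subjects from a core-tensor feature matrix
#'
#' Runs k-means (squared-Euclidean, multiple restarts) on the columns of
#' a spatial or temporal feature matrix. Labels are canonicalized so
#' that subject 1 always belongs to cluster 1, making the partition
#' deterministic given the seed.
#'
#' @param features \code{N x K} feature matrix, subjects in columns
#'   (as returned by \code{\link{spatial_features}} or
#'   \code{\link{temporal_features}}).
#' @param n_clusters Number of clusters, at most \code{K}.
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Number of random restarts (default 50).
#' @return List of class \code{"slctkd_clusters"} with \code{labels}
#'   (length-K integer vector), \code{n_clusters}, \code{feature_source}
#'   and the within-cluster sum of squares \code{tot_withinss}.
#' @export
cluster_subjects <- function(features, n_clusters, seed = 1L, nstart = 50L) {
  stopifnot(is.matrix(features))
  K <- ncol(features)
  if (n_clusters > K) {
    stop(sprintf("n_clusters = %d exceeds the number of subjects K = %d",
                 n_clusters, K))
  }
  if (n_clusters == K) {
    # trivial partition: every subject its own cluster
    return(structure(list(labels = seq_len(K), n_clusters = n_clusters,
                          feature_source = attr(features, "feature_source"),
                          tot_withinss = 0),
                     class = "slctkd_clusters"))
  }
  pts <- t(features)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  km <- suppressWarnings(
    stats::kmeans(pts, centers = n_clusters, nstart = nstart))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  labels <- canonicalize_labels(km$cluster)
  structure(list(labels = labels, n_clusters = n_clusters,
                 feature_source = attr(features, "feature_source"),
                 tot_withinss = km$tot.withinss),
            class = "slctkd_clusters")
}

# Relabel clusters by order of first appearance (subject 1 -> cluster 1).
canonicalize_labels <- function(labels) {
  first <- unique(labels)
  as.integer(match(labels, first))
}

#' @export
print.slctkd_clusters <- function(x, ...) {
  cat(sprintf("k-means clustering of %d subjects into %d groups (%s features)\n",
              length(x$labels), x$n_clusters,
              if (is.null(x$feature_source)) "unknown" else x$feature_source))
  for (g in seq_len(x$n_clusters)) {
    cat(sprintf("  group %d: subjects {%s}\n", g,
                paste(which(x$labels == g), collapse = ", ")))
  }
  invisible(x)
}
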