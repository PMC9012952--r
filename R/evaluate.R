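# Performance measures: correlation-based matching of estimated
# components to references, time-course detrending/normalization, and
# Z-map thresholding with voxel counts.

#' Absolute Pearson correlation
#'
#' \code{|cor(x, y)|}; constant inputs yield 0 with a warning rather
#' than NA, so degenerate components score as unmatched.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return Scalar in [0, 1].
#' @export
pearson_abs <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("x and y must have equal length >= 2")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input to pearson_abs; returning 0")
    return(0)
  }
  abs(stats::cor(x, y))
}

#' Match estimated components to reference components
#'
#' Assigns each reference component the estimated component with the
#' highest absolute spatial Pearson correlation, uniquely (greedy on the
#' sorted correlation matrix by default, or the exactly optimal
#' assignment). Signs are fixed so that the matched spatial correlation
#' is nonnegative; temporal correlations are reported for the matched
#' pairs but do not drive the assignment.
#'
#' @param S_est,B_est Estimated spatial (\code{V x N_est}) and temporal
#'   (\code{T x N_est}) components; \code{N_est >= N_ref}.
#' @param S_ref,B_ref Reference spatial and temporal components.
#' @param method \code{"greedy"} or \code{"optimal"} (exhaustive best
#'   assignment, available for up to 8 references).
#' @return A list of class \code{"slctkd_match"} with
#'   \code{permutation} (estimate index per reference), \code{signs},
#'   \code{rho_sm} and \code{rho_tc} (absolute correlations per matched
#'   component).
#' @export
match_components <- function(S_est, B_est, S_ref, B_ref,
                             method = c("greedy", "optimal")) {
  method <- match.arg(method)
  S_est <- as.matrix(S_est); S_ref <- as.matrix(S_ref)
  B_est <- as.matrix(B_est); B_ref <- as.matrix(B_ref)
  n_ref <- ncol(S_ref); n_est <- ncol(S_est)
  if (n_est < n_ref) {
    stop(sprintf("need at least as many estimates (%d) as references (%d)",
                 n_est, n_ref))
  }
  rho <- abs(suppressWarnings(stats::cor(S_ref, S_est)))
  rho[!is.finite(rho)] <- 0

  perm <- if (method == "greedy") greedy_assign(rho) else optimal_assign(rho)

  signs <- integer(n_ref)
  rho_sm <- numeric(n_ref)
  rho_tc <- numeric(n_ref)
  for (i in seq_len(n_ref)) {
    j <- perm[i]
    r <- suppressWarnings(stats::cor(S_ref[, i], S_est[, j]))
    if (!is.finite(r)) r <- 0
    signs[i] <- if (r < 0) -1L else 1L
    rho_sm[i] <- abs(r)
    rho_tc[i] <- pearson_abs(B_ref[, i], B_est[, j])
  }
  structure(list(permutation = perm, signs = signs,
                 rho_sm = rho_sm, rho_tc = rho_tc, method = method),
            class = "slctkd_match")
}

# Greedy unique assignment: repeatedly take the global maximum of the
# remaining |rho| matrix.
greedy_assign <- function(rho) {
  n_ref <- nrow(rho)
  perm <- integer(n_ref)
  r <- rho
  for (step in seq_len(n_ref)) {
    ij <- arrayInd(which.max(r), dim(r))
    perm[ij[1L]] <- ij[2L]
    r[ij[1L], ] <- -Inf
    r[, ij[2L]] <- -Inf
  }
  perm
}

# Exhaustive optimal assignment (maximize the summed |rho|), by
# recursion over reference components; intended for small n_ref.
optimal_assign <- function(rho) {
  n_ref <- nrow(rho)
  if (n_ref > 8L) stop("optimal assignment supported for up to 8 references")
  best <- list(score = -Inf, perm = integer(n_ref))
  recurse <- function(i, used, score, perm) {
    if (i > n_ref) {
      if (score > best$score) best <<- list(score = score, perm = perm)
      return()
    }
    for (j in order(rho[i, ], decreasing = TRUE)) {
      if (used[j]) next
      used[j] <- TRUE
      perm[i] <- j
      recurse(i + 1L, used, score + rho[i, j], perm)
      used[j] <- FALSE
    }
  }
  recurse(1L, logical(ncol(rho)), 0, integer(n_ref))
  best$perm
}

#' @export
print.slctkd_match <- function(x, ...) {
  cat(sprintf("component matching (%s assignment)\n", x$method))
  for (i in seq_along(x$permutation)) {
    cat(sprintf("  ref %d -> est %d (sign %+d): |rho| SM %.3f, TC %.3f\n",
                i, x$permutation[i], x$signs[i], x$rho_sm[i], x$rho_tc[i]))
  }
  invisible(x)
}

#' Aggregate matching results across runs
#'
#' Computes the mean and standard deviation of the matched absolute
#' correlations per component and modality, the error-bar protocol used
#' when comparing decompositions across repeated runs.
#'
#' @param matches List of \code{\link{match_components}} results.
#' @return Data frame with one row per (component, modality) carrying
#'   \code{mean_rho} and \code{sd_rho}.
#' @export
aggregate_matches <- function(matches) {
  stopifnot(length(matches) >= 1L)
  sm <- do.call(rbind, lapply(matches, `[[`, "rho_sm"))
  tc <- do.call(rbind, lapply(matches, `[[`, "rho_tc"))
  n_ref <- ncol(sm)
  data.frame(
    component = rep(seq_len(n_ref), 2L),
    modality = rep(c("SM", "TC"), each = n_ref),
    mean_rho = c(colMeans(sm), colMeans(tc)),
    sd_rho = c(apply(sm, 2L, stats::sd), apply(tc, 2L, stats::sd)))
}

#' Detrend and normalize a time course
#'
#' Removes a least-squares linear baseline, then scales to \code{[-1, 1]}
#' by the maximum absolute value.
#'
#' @param tc Numeric vector, length >= 3.
#' @param degree Polynomial order of the baseline (default 1, linear).
#' @return Detrended vector with max |value| = 1, or all zeros (with a
#'   warning) if nothing remains after detrending.
#' @export
detrend_normalize <- function(tc, degree = 1L) {
  n <- length(tc)
  if (n < 3L) stop("time course must have length >= 3")
  t <- seq_len(n)
  X <- stats::poly(t, degree = degree, raw = TRUE)
  r <- stats::lsfit(X, tc)$residuals
  m <- max(abs(r))
  if (m < .Machine$double.eps^0.5 * max(1, max(abs(tc)))) {
    warning("time course is (numerically) zero after baseline removal")
    return(rep(0, n))
  }
  r / m
}

#' Threshold a Z-scored spatial map and count activated voxels
#'
#' Z-scores the map over in-mask voxels (subtract mean, divide by
#' standard deviation), counts entries with \code{|Z| > threshold}, and
#' counts the subset falling inside a reference mask.
#'
#' @param sm Numeric spatial map over in-brain voxels.
#' @param threshold Positive Z threshold (1.5 is a common display
#'   choice).
#' @param reference_mask Logical vector of the same length marking the
#'   spatial reference region.
#' @return Named vector \code{c(total_active, inside_reference)}.
#' @export
zmap_count <- function(sm, threshold, reference_mask) {
  if (threshold <= 0) stop("threshold must be positive")
  stopifnot(length(reference_mask) == length(sm))
  s <- stats::sd(sm)
  if (s == 0) stop("zmap_count: map has zero variance")
  z <- (sm - mean(sm)) / s
  act <- abs(z) > threshold
  c(total_active = sum(act),
    inside_reference = sum(act & as.logical(reference_mask)))
}
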