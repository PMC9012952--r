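# S3 methods for fitted slcTKD decompositions.

#' @export
print.slctkd <- function(x, ...) {
  d <- x$dims
  cat("Sparse low-rank Tucker-2 decomposition (slcTKD)\n")
  cat(sprintf("  data:  %d voxels x %d time points x %d subjects\n",
              d[["V"]], d[["T"]], d[["K"]]))
  cat(sprintf("  model order N = %d\n", d[["N"]]))
  cat(sprintf("  iterations: %d (stopped on %s)\n",
              length(x$eps_trace), x$converged_reason))
  cat(sprintf("  final relative residual: %.4g\n",
              x$eps_trace[length(x$eps_trace)]))
  invisible(x)
}

#' Summarize a fitted slcTKD decomposition
#'
#' Reports convergence diagnostics plus sparsity summaries of the
#' estimated spatial maps, core and residual.
#'
#' @param object A fitted \code{"slctkd"} object.
#' @param ... Unused.
#' @export
summary.slctkd <- function(object, ...) {
  d <- object$dims
  sfrac <- function(a, tol = 1e-8) mean(abs(a) > tol)
  out <- list(
    dims = d,
    iterations = length(object$eps_trace),
    converged_reason = object$converged_reason,
    final_eps = object$eps_trace[length(object$eps_trace)],
    control = object$control,
    nonzero_frac = c(S = sfrac(object$S), G = sfrac(object$G),
                     E = sfrac(object$E)),
    component_energy = colSums(object$S^2))
  class(out) <- "summary.slctkd"
  out
}

#' @export
print.summary.slctkd <- function(x, ...) {
  d <- x$dims
  cat("slcTKD fit summary\n")
  cat(sprintf("  tensor %d x %d x %d, model order %d\n",
              d[["V"]], d[["T"]], d[["K"]], d[["N"]]))
  cat(sprintf("  %d iterations, stopped on %s, final eps = %.4g\n",
              x$iterations, x$converged_reason, x$final_eps))
  cat(sprintf("  nonzero fractions: S %.3f, G %.3f, E %.3f\n",
              x$nonzero_frac[["S"]], x$nonzero_frac[["G"]],
              x$nonzero_frac[["E"]]))
  cat(sprintf("  control: delta=%.3g p=%.3g lambda=%.3g gamma=%.3g eta=%.3g xi=%.3g\n",
              x$control$delta, x$control$p, x$control$lambda,
              x$control$gamma, x$control$eta, x$control$xi))
  invisible(x)
}

#' Extract estimated factors from an slcTKD fit
#'
#' @param object A fitted \code{"slctkd"} object.
#' @param type \code{"spatial"} for the shared spatial maps (V x N),
#'   \code{"temporal"} for the shared time courses (T x N), or
#'   \code{"core"} for the N x N x K core tensor.
#' @param ... Unused.
#' @export
coef.slctkd <- function(object, type = c("spatial", "temporal", "core"), ...) {
  switch(match.arg(type),
         spatial = object$S, temporal = object$B, core = object$G)
}

#' @export
fitted.slctkd <- function(object, ...) {
  tucker2_reconstruct(object$G, object$S, object$B)
}

#' Residuals of an slcTKD fit
#'
#' @param object A fitted \code{"slctkd"} object (fitted with
#'   \code{keep_data = TRUE} for \code{type = "noise"}).
#' @param type \code{"sparse"} returns the model's own sparse residual
#'   tensor E; \code{"noise"} returns the unmodeled remainder
#'   \code{X - G x1 S x2 B - E}.
#' @param ... Unused.
#' @export
residuals.slctkd <- function(object, type = c("sparse", "noise"), ...) {
  type <- match.arg(type)
  if (type == "sparse") return(object$E)
  if (is.null(object$X)) {
    stop("fit was made with keep_data = FALSE; the data tensor is not stored")
  }
  object$X - fitted(object) - object$E
}

#' Plot convergence (and optionally a spatial map) of an slcTKD fit
#'
#' @param x A fitted \code{"slctkd"} object.
#' @param component Optional component index: if given and the fit
#'   carries grid geometry (from \code{\link{load_fmri_tensor}} or a
#'   simulation), the corresponding spatial map is drawn as an image
#'   next to the residual trace.
#' @param grid Optional \code{c(nx, ny)} grid to reshape the map when no
#'   geometry is stored.
#' @param ... Passed to \code{plot}.
#' @export
plot.slctkd <- function(x, component = NULL, grid = NULL, ...) {
  show_map <- !is.null(component)
  if (show_map) {
    if (is.null(grid) && !is.null(x$meta$grid)) grid <- x$meta$grid[1:2]
    if (is.null(grid)) stop("supply grid = c(nx, ny) to draw a spatial map")
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  graphics::plot(seq_along(x$eps_trace), x$eps_trace, type = "b", log = "y",
                 xlab = "iteration", ylab = "relative residual", ...)
  if (show_map) {
    graphics::image(matrix(x$S[, component], grid[1L], grid[2L]),
                    main = sprintf("spatial map %d", component),
                    xaxt = "n", yaxt = "n")
  }
  invisible(x)
}
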