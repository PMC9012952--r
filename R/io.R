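# I/O: building the voxel x time x subject tensor from per-subject
# 4-D NIfTI volumes plus a binary brain mask, writing spatial maps back
# to volume space, and saving/reloading fit results.
#
# Voxel flattening order: masked voxels are taken in the mask's natural
# column-major scan order (R array order), recorded in voxel_index so
# maps can be written back losslessly.

#' Load a multi-subject fMRI tensor from NIfTI volumes
#'
#' Reads K per-subject 4-D NIfTI volumes and a 3-D binary brain mask on
#' the same grid, and flattens each volume to the masked voxel rows.
#'
#' @param nifti_paths Character vector of K paths to 4-D volumes, all
#'   sharing grid and number of time points.
#' @param mask_path Path to a 3-D binary mask on the same grid with at
#'   least one nonzero voxel.
#' @return A list of class \code{"fmri_data"} with \code{X}
#'   (\code{V x T x K} array), \code{voxel_index} (column-major indices
#'   of in-mask voxels), \code{grid}, and \code{mask_path}.
#' @export
load_fmri_tensor <- function(nifti_paths, mask_path) {
  mask_img <- RNifti::readNifti(mask_path)
  mask <- as.array(mask_img)
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D volume")
  uq <- unique(as.numeric(mask))
  if (!all(uq %in% c(0, 1))) stop("mask must be binary (0/1)")
  vox <- which(mask != 0)
  if (length(vox) == 0L) stop("mask selects no voxels")
  grid <- dim(mask)

  X <- NULL
  for (k in seq_along(nifti_paths)) {
    vol <- as.array(RNifti::readNifti(nifti_paths[k]))
    if (length(dim(vol)) != 4L) {
      stop(sprintf("%s: expected a 4-D volume", nifti_paths[k]))
    }
    if (!identical(dim(vol)[1:3], grid)) {
      stop(sprintf("%s: grid %s does not match mask grid %s",
                   nifti_paths[k], paste(dim(vol)[1:3], collapse = "x"),
                   paste(grid, collapse = "x")))
    }
    Tn <- dim(vol)[4L]
    if (is.null(X)) {
      X <- array(0, dim = c(length(vox), Tn, length(nifti_paths)))
    } else if (Tn != dim(X)[2L]) {
      stop(sprintf("%s: %d time points, expected %d",
                   nifti_paths[k], Tn, dim(X)[2L]))
    }
    dim(vol) <- c(prod(grid), Tn)
    X[, , k] <- vol[vox, , drop = FALSE]
  }
  structure(list(X = X, voxel_index = vox, grid = grid,
                 mask_path = mask_path),
            class = "fmri_data")
}

#' @export
print.fmri_data <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("fMRI data tensor: %d in-mask voxels x %d time points x %d subjects\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  grid %s, mask %s\n", paste(x$grid, collapse = " x "),
              x$mask_path))
  invisible(x)
}

#' Embed a flattened map back into volume space
#'
#' @param map Numeric vector over in-mask voxels.
#' @param voxel_index Column-major indices of those voxels.
#' @param grid Volume dimensions, length 3 (or 2 for single-slice
#'   grids, padded with a singleton third dimension).
#' @return A numeric array of dimension \code{grid}.
#' @export
map_to_volume <- function(map, voxel_index, grid) {
  if (length(grid) == 2L) grid <- c(grid, 1L)
  stopifnot(length(voxel_index) == length(map), length(grid) == 3L)
  vol <- array(0, dim = grid)
  vol[voxel_index] <- map
  vol
}

#' Write a spatial map as a NIfTI volume
#'
#' Embeds the map via \code{\link{map_to_volume}} and writes it with the
#' mask volume as the header/affine template.
#'
#' @param map Numeric vector over in-mask voxels.
#' @param mask_path Path of the mask NIfTI used as geometry template.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_map_nifti <- function(map, mask_path, path) {
  mask_img <- RNifti::readNifti(mask_path)
  mask <- as.array(mask_img)
  vol <- map_to_volume(map, which(mask != 0), dim(mask))
  RNifti::writeNifti(RNifti::asNifti(vol, reference = mask_img), path)
  invisible(path)
}

#' Save a fitted slcTKD decomposition to disk
#'
#' Writes the fit as an RDS file together with plain-text side-cars:
#' the residual trace and control settings as TSV, and a provenance
#' record (R version, package version, call) so the run can be
#' reproduced.
#'
#' @param fit A fitted \code{"slctkd"} object.
#' @param prefix Output path prefix; files \code{<prefix>.rds},
#'   \code{<prefix>_trace.tsv} and \code{<prefix>_provenance.txt} are
#'   written.
#' @return The RDS path, invisibly.
#' @export
save_slctkd <- function(fit, prefix) {
  stopifnot(inherits(fit, "slctkd"))
  rds <- paste0(prefix, ".rds")
  saveRDS(fit, rds)
  utils::write.table(fit$trace, paste0(prefix, "_trace.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  prov <- c(sprintf("package: slcTKD %s",
                    as.character(utils::packageVersion("slcTKD"))),
            sprintf("R: %s", R.version.string),
            sprintf("call: %s", paste(deparse(fit$call), collapse = " ")),
            sprintf("control: %s",
                    paste(names(fit$control),
                          vapply(fit$control, function(v) format(v)[1L], ""),
                          sep = "=", collapse = " ")))
  writeLines(prov, paste0(prefix, "_provenance.txt"))
  invisible(rds)
}

#' Reload a fit written by \code{\link{save_slctkd}}
#'
#' @param prefix The path prefix used when saving.
#' @return The \code{"slctkd"} object.
#' @export
read_slctkd <- function(prefix) {
  fit <- readRDS(paste0(prefix, ".rds"))
  stopifnot(inherits(fit, "slctkd"))
  fit
}

#' Write a feature matrix or intensity vector as TSV
#'
#' Subjects are rows; the header records the component indices the
#' features were extracted at.
#'
#' @param features An \code{N x K} feature matrix (from
#'   \code{\link{spatial_features}} / \code{\link{temporal_features}})
#'   or a length-K intensity vector.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_features_tsv <- function(features, path) {
  if (is.matrix(features)) {
    df <- as.data.frame(t(features))
    names(df) <- paste0("component", seq_len(ncol(df)))
  } else {
    df <- data.frame(intensity = as.numeric(features))
  }
  df <- cbind(subject = seq_len(nrow(df)), df)
  comp <- attr(features, "component")
  hdr <- if (!is.null(comp)) {
    sprintf("# %s features at component %s = %d",
            attr(features, "feature_source"), names(comp)[1L], comp[[1L]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hdr)) writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
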