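#' Read one subject's trial features from NIfTI volumes
#'
#' Loads a 4D NIfTI (trials along the 4th axis) and a 3D mask, extracts
#' the in-mask voxels in mask linear order into a trials x voxels
#' matrix, and attaches +1/-1 labels from a CSV table.
#'
#' @param path_4d Path to the 4D feature NIfTI.
#' @param path_mask Path to the 3D mask NIfTI (non-zero = in mask).
#' @param path_labels Path to a CSV with one row per trial.
#' @param label_col Name of the label column.
#' @param positive Optional value of `label_col` mapped to +1 (when the
#'   column is not already +1/-1).
#' @param subject_id Subject identifier.
#' @return A list with `subject` (a [subject_features()]) and `mask`
#'   (the [voxel_mask()]).
#' @export
read_features <- function(path_4d, path_mask, path_labels,
                          label_col = "label", positive = NULL,
                          subject_id = "s1") {
  vol <- RNifti::readNifti(path_4d)
  msk <- RNifti::readNifti(path_mask)
  if (length(dim(vol)) != 4L) stop("`path_4d` must be a 4D volume")
  if (!all(dim(vol)[1:3] == dim(msk)[1:3]))
    stop("mask shape does not match the volume shape")
  mask <- voxel_mask(array(msk != 0, dim = dim(msk)[1:3]))
  tab <- read.csv(path_labels)
  if (!label_col %in% names(tab))
    stop("label column '", label_col, "' not found in ", path_labels)
  if (nrow(tab) != dim(vol)[4])
    stop("label rows do not match the number of trials")
  inside <- which(mask$index_array != 0)
  flat <- matrix(as.numeric(vol), nrow = prod(dim(vol)[1:3]))
  X <- t(flat[inside, , drop = FALSE])
  if (!all(is.finite(X))) stop("volume contains non-finite in-mask voxels")
  y <- tab[[label_col]]
  if (is.null(positive) && !all(y %in% c(1, -1)))
    stop("labels are not +1/-1; pass `positive` to declare the mapping")
  list(subject = subject_features(X, y, subject_id = subject_id,
                                  positive = positive),
       mask = mask)
}

#' Write a per-voxel map as a 3D NIfTI volume
#'
#' Out-of-mask voxels are written as 0; in-mask voxels receive `values`
#' in mask linear order. Values are written unthresholded. If
#' `reference` (a NIfTI path or image) is given its header/affine is
#' reused.
#'
#' @param values Numeric vector over in-mask voxels.
#' @param mask A [voxel_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param reference Optional NIfTI image or path supplying the header.
#' @return The path, invisibly.
#' @export
write_brain_map <- function(values, mask, path, reference = NULL) {
  if (length(values) != mask$n_voxels)
    stop("`values` must have one entry per in-mask voxel")
  arr <- array(0, dim = mask$shape)
  arr[mask$index_array != 0] <- values
  img <- if (!is.null(reference)) {
    ref <- if (is.character(reference)) RNifti::readNifti(reference) else reference
    RNifti::asNifti(arr, reference = ref)
  } else {
    RNifti::asNifti(arr)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a parcellation as a NIfTI label image plus a size table
#'
#' @param parc A [parcellation()].
#' @param mask The matching [voxel_mask()].
#' @param path_nii Output NIfTI path (0 outside the mask, cluster id
#'   inside).
#' @param path_csv Optional CSV path for the `(cluster_id, size)` table.
#' @param reference Optional NIfTI header source.
#' @return `path_nii`, invisibly.
#' @export
write_parcellation <- function(parc, mask, path_nii, path_csv = NULL,
                               reference = NULL) {
  write_brain_map(parc$labels, mask, path_nii, reference = reference)
  if (!is.null(path_csv)) {
    write.csv(data.frame(cluster_id = seq_len(parc$n_clusters),
                         size = lengths(parc$cluster_members)),
              path_csv, row.names = FALSE)
  }
  invisible(path_nii)
}

#' Read a parcellation from a NIfTI label image
#'
#' @param path Path to a 3D integer label image (0 = outside mask).
#' @return A list with `parcellation` and `mask`.
#' @export
read_parcellation <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(round(img)), dim = dim(img)[1:3])
  mask <- voxel_mask(array(arr != 0L, dim = dim(arr)))
  labs <- arr[arr != 0L]
  ids <- sort(unique(labs))
  list(parcellation = parcellation(match(labs, ids), length(ids)),
       mask = mask)
}

#' Serialize a fitted group model to CSV + JSON sidecar
#'
#' @param fit An `shv_group_fit`.
#' @param path_csv CSV of `(cluster_id, subject_id, weight)`.
#' @param path_json Sidecar with intercepts, penalty and convergence.
#' @return `path_csv`, invisibly.
#' @export
write_group_fit <- function(fit, path_csv, path_json = NULL) {
  write.csv(tidy(fit), path_csv, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(intercepts = setNames(as.list(fit$b), fit$subject_ids),
           lambda = fit$lambda, converged = fit$converged,
           iterations = fit$iterations, objective = fit$objective),
      path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(path_csv)
}

#' Write a run manifest sufficient to replay a run
#'
#' @param path Output JSON path.
#' @param config An [shv_config()] (or any list of settings).
#' @param inputs Named character vector of input file paths; MD5 digests
#'   are recorded for files that exist.
#' @param extra Optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, inputs = character(0),
                           extra = list()) {
  digests <- if (length(inputs)) {
    ex <- file.exists(inputs) & !dir.exists(inputs)
    d <- rep(NA_character_, length(inputs))
    d[ex] <- unname(tools::md5sum(inputs[ex]))
    setNames(as.list(d), names(inputs) %||% inputs)
  } else {
    list()
  }
  jsonlite::write_json(
    list(package = "shvote",
         version = as.character(utils::packageVersion("shvote")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = unclass(config), inputs = digests, extra = extra),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
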