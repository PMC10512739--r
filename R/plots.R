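#' @export
autoplot.shv_result <- function(object, truth = NULL, ...) {
  df <- tidy(object)
  df$planted <- if (is.null(truth)) FALSE else df$cluster_id %in% truth
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster_id,
                                        y = .data$vote_rate)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$cluster_id, yend = 0,
                                       colour = .data$planted)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$planted), size = 1.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = if (is.null(truth)) "none" else
                                   ggplot2::guide_legend("planted")) +
    ggplot2::labs(x = "cluster", y = "groupwise vote rate",
                  title = sprintf("Cluster vote rates (%s, lambda = %g)",
                                  object$method, object$lambda)) +
    ggplot2::theme_minimal()
  p
}

#' @export
autoplot.shv_accuracy_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("train_accuracy", "test_accuracy"),
                            names_to = "set", values_to = "accuracy")
  df$set <- sub("_accuracy", "", df$set)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_voxels, y = .data$accuracy,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "number of selected voxels", y = "accuracy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.shv_group_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject,
                                   y = factor(.data$cluster_id),
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "subject", y = "cluster",
                  title = sprintf("Cluster weights (lambda = %g)",
                                  object$lambda)) +
    ggplot2::theme_minimal()
}

#' Axial slice of a per-voxel brain map
#'
#' @param values Numeric vector over in-mask voxels.
#' @param mask The [voxel_mask()].
#' @param slice Index along the third axis; defaults to the middle.
#' @return A ggplot object.
#' @export
plot_brain_slice <- function(values, mask, slice = NULL) {
  if (length(values) != mask$n_voxels)
    stop("`values` must have one entry per in-mask voxel")
  slice <- slice %||% ceiling(mask$shape[3] / 2)
  arr <- array(NA_real_, dim = mask$shape)
  arr[mask$index_array != 0] <- values
  df <- expand.grid(x = seq_len(mask$shape[1]), y = seq_len(mask$shape[2]))
  df$value <- as.vector(arr[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("slice z = %d", slice)) +
    ggplot2::theme_void()
}
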