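#' Long-format composition matrix for visualization
#'
#' Rearranges a filtered, oriented dosage matrix into the long
#' marker-by-plant table behind the cohort heatmap: markers ordered by
#' chromosome set and physical position (rows), plants as columns, cells
#' carrying the score-implied composition label.
#'
#' @param dosage A filtered, oriented `DosageMatrix`.
#' @param marker_map Map rows matching the matrix markers.
#' @return Data frame with `marker_id`, `chrom_set`, `position`, `plant`,
#'   `score`, `composition`.
#' @export
composition_matrix <- function(dosage, marker_map = dosage$markers) {
  lin <- .lineage_cols(dosage)
  if (nrow(dosage$score) == 0 || length(lin) == 0)
    stop("empty dosage matrix")
  ord <- order(marker_map$chrom_set, marker_map$position)
  sc <- dosage$score[ord, lin, drop = FALSE]
  map <- marker_map[ord, , drop = FALSE]
  plants <- dosage$samples$plant[lin]
  out <- data.frame(
    marker_id = rep(map$marker_id, times = length(plants)),
    chrom_set = rep(map$chrom_set, times = length(plants)),
    position = rep(map$position, times = length(plants)),
    plant = rep(plants, each = nrow(map)),
    score = as.vector(sc),
    stringsAsFactors = FALSE
  )
  out$composition <- ifelse(is.na(out$score), NA_character_,
                            score_to_composition(ifelse(is.na(out$score),
                                                        2L, out$score)))
  out
}

#' Heatmap of the composition matrix
#'
#' Best-effort plotting layer over [composition_matrix()] (requires
#' ggplot2); dosage imbalances use the conventional palette — BBBB dark
#' red, ABBB light red, AAAB light blue, AAAA dark blue, AABB grey.
#'
#' @param cm A [composition_matrix()] result.
#' @return A ggplot object.
#' @export
plot_composition_matrix <- function(cm) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  cm$row <- stats::ave(seq_len(nrow(cm)), cm$plant, FUN = seq_along)
  pal <- c(BBBB = "#8b0000", ABBB = "#f08080", AABB = "grey85",
           AAAB = "#87cefa", AAAA = "#00008b")
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$plant, y = .data$row,
                                   fill = .data$composition)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = pal, na.value = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "plant", y = "markers (by set and position)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Principal component analysis of the genotype matrix
#'
#' Centered PCA of the plants x markers dosage-score matrix; missing
#' cells are mean-imputed per marker. A constant matrix yields the
#' defined zero-variance result (all coordinates zero) rather than an
#' error.
#'
#' @param dosage A filtered, oriented `DosageMatrix` (>= 3 plants,
#'   >= 2 markers).
#' @param n_axes Number of axes to return.
#' @return List with `coordinates` (data frame: plant, PC1, PC2, ...)
#'   and `var_explained` (fraction of total variance per axis).
#' @export
genotype_pca <- function(dosage, n_axes = 5) {
  lin <- .lineage_cols(dosage)
  if (length(lin) < 3) stop("at least 3 plants required")
  if (nrow(dosage$score) < 2) stop("at least 2 markers required")
  x <- t(dosage$score[, lin, drop = FALSE])
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- mean(x[, j], na.rm = TRUE)
  }
  x <- scale(x, center = TRUE, scale = FALSE)
  n_axes <- min(n_axes, nrow(x) - 1L, ncol(x))
  total_var <- sum(apply(x, 2, stats::var))
  if (total_var < .Machine$double.eps) {
    coords <- matrix(0, nrow(x), n_axes)
    ve <- rep(0, n_axes)
  } else {
    p <- stats::prcomp(x, center = FALSE)
    k <- min(n_axes, ncol(p$x))
    coords <- p$x[, seq_len(k), drop = FALSE]
    ve <- (p$sdev^2 / sum(p$sdev^2))[seq_len(k)]
    n_axes <- k
  }
  colnames(coords) <- paste0("PC", seq_len(n_axes))
  out <- data.frame(plant = dosage$samples$plant[lin], coords,
                    stringsAsFactors = FALSE)
  list(coordinates = out, var_explained = ve)
}
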