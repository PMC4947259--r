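#' Anchor scan results to the genetic map via a zipper table
#'
#' Every marker on a scaffold inherits that scaffold's linkage group and
#' cM position from the zipper; markers on scaffolds absent from the
#' zipper are flagged unanchored (rendered `--` in printed tables).
#'
#' @param results a `marker_test_result` data.frame (needs `scaffold`)
#' @param zipper a `zipper_table`
#' @return results with added `lg`, `pos_cm`, `anchored` columns;
#'   attribute `"n_unanchored"` counts markers with no zipper entry
#' @export
anchor_markers <- function(results, zipper) {
  m <- match(results$scaffold, zipper$scaffold)
  out <- results
  out$lg <- zipper$lg[m]
  out$pos_cm <- zipper$pos_cm[m]
  out$anchored <- !is.na(m)
  attr(out, "n_unanchored") <- sum(is.na(m))
  out
}

#' Format anchored positions the way printed tables show them
#' @param anchored output of [anchor_markers()]
#' @return character vector, `"<lg>"` / `"<cM>"` or `"--"` when unanchored
#' @export
format_anchor <- function(anchored) {
  ifelse(anchored$anchored,
         sprintf("LG%d-%.1fcM", anchored$lg, anchored$pos_cm), "--")
}

#' Bin anchored markers into linkage-map intervals
#'
#' The intervals are the gaps between consecutive markers of the genetic
#' linkage map on one linkage group: `[m_i, m_{i+1})`, with the final
#' interval closed on the right. Each anchored marker falls in one
#' interval by its cM position (positions outside the map extent are
#' clamped to the terminal intervals with a warning) and each cell
#' reports the median test statistic of its markers.
#'
#' @param anchored output of [anchor_markers()] (one family, one trait)
#' @param map a `genetic_map`
#' @param lg linkage group to bin
#' @param family optional family label for the cells (defaults to the
#'   family of the results)
#' @param statistic column of `anchored` to aggregate, default `"H"`
#' @return a `heatmap_cells` data.frame: `family_id`, `lg`, `left_cm`,
#'   `right_cm`, `median_H`, `n_markers`
#' @export
bin_by_map_intervals <- function(anchored, map, lg, family = NULL,
                                 statistic = "H") {
  mp <- map$pos_cm[map$lg == lg]
  if (length(mp) < 2) stop("map needs at least 2 markers on lg ", lg)
  mp <- sort(mp)
  if (is.null(family)) {
    family <- if ("family_id" %in% names(anchored))
      as.character(anchored$family_id[1]) else NA_character_
  }
  res <- anchored[!is.na(anchored$lg) & anchored$lg == lg, , drop = FALSE]
  pos <- res$pos_cm
  if (length(pos) > 0 && (any(pos < mp[1]) || any(pos > mp[length(mp)]))) {
    warning(sum(pos < mp[1] | pos > mp[length(mp)]),
            " marker(s) outside the map extent of lg ", lg,
            "; clamped to the terminal intervals")
  }
  # interval k is [mp[k], mp[k+1]); the last interval is closed
  k <- findInterval(pos, mp, rightmost.closed = TRUE)
  k <- pmin(pmax(k, 1L), length(mp) - 1L)
  stat <- res[[statistic]]
  cells <- data.frame(
    family_id = family, lg = lg,
    left_cm = mp[-length(mp)], right_cm = mp[-1],
    median_H = NA_real_, n_markers = 0L)
  if (length(pos) > 0) {
    med <- tapply(stat, factor(k, levels = seq_len(length(mp) - 1)),
                  stats::median, na.rm = TRUE)
    cnt <- tapply(stat, factor(k, levels = seq_len(length(mp) - 1)), length)
    cells$median_H <- as.numeric(med)
    cells$n_markers <- ifelse(is.na(cnt), 0L, as.integer(cnt))
    cells$median_H[cells$n_markers == 0] <- NA_real_
  }
  class(cells) <- c("heatmap_cells", "data.frame")
  cells
}

#' Assemble per-family heatmap cells into a plotting matrix
#'
#' @param cells list of `heatmap_cells` (one per family, same linkage
#'   group and map) or a single rbind-ed data.frame
#' @param families optional family order for the rows
#' @return list with `matrix` (families x intervals, NA where a cell has
#'   no markers), `intervals` (left/right cM) and `scale_bounds`
#'   (`c(0, max median)`, the colour range of the published heatmaps)
#' @export
heatmap_matrix <- function(cells, families = NULL) {
  if (is.data.frame(cells)) {
    cells <- split(cells, cells$family_id)
  }
  if (is.null(families)) families <- names(cells)
  ref <- cells[[1]]
  for (cl in cells) {
    if (!identical(cl$left_cm, ref$left_cm)) {
      stop("all families must be binned on the same map intervals")
    }
  }
  m <- do.call(rbind, lapply(families, function(f) cells[[f]]$median_H))
  rownames(m) <- families
  colnames(m) <- sprintf("%.1f-%.1f", ref$left_cm, ref$right_cm)
  upper <- if (all(is.na(m))) 0 else max(m, na.rm = TRUE)
  list(matrix = m,
       intervals = data.frame(left_cm = ref$left_cm, right_cm = ref$right_cm),
       scale_bounds = c(0, upper))
}
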