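#' @rdname icim_scan
#' @param x an `icim_scan` object.
#' @param ... unused.
#' @method tidy icim_scan
#' @export
tidy.icim_scan <- function(x, ...) {
  x$profile[, c("chrom", "pos", "lod", "add", "pve")]
}

#' @rdname icim_scan
#' @method glance icim_scan
#' @export
glance.icim_scan <- function(x, ...) {
  tibble::tibble(n_positions = nrow(x$profile),
                 n_cofactors = nrow(x$cofactors),
                 max_lod = max(x$profile$lod),
                 peak_pos = x$profile$pos[which.max(x$profile$lod)],
                 n = x$n)
}

#' Plot an ICIM LOD profile
#'
#' @param object an `icim_scan` object.
#' @param ... unused.
#' @return a ggplot: LOD against position, facetted by chromosome, with
#'   the calling threshold as a dashed line.
#' @method autoplot icim_scan
#' @export
autoplot.icim_scan <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$pos, y = .data$lod)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$settings$lod_threshold,
                        linetype = "dashed") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (cM)", y = "LOD")
}

#' Plot a consensus map
#'
#' @param object a `consensus_map` object.
#' @param ... unused.
#' @return a ggplot showing marker positions as rug ticks per linkage
#'   group.
#' @method autoplot consensus_map
#' @export
autoplot.consensus_map <- function(object, ...) {
  ggplot2::ggplot(object$map,
                  ggplot2::aes(x = .data$chrom, y = .data$pos)) +
    ggplot2::geom_point(shape = 95, size = 4) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Linkage group", y = "Position (cM)")
}

#' Plot per-QTL power of an experiment
#'
#' @param object a `qtl_experiment` object.
#' @param ... unused.
#' @return a ggplot bar chart of detection power per true QTL.
#' @method autoplot qtl_experiment
#' @export
autoplot.qtl_experiment <- function(object, ...) {
  ggplot2::ggplot(object$summary$per_qtl,
                  ggplot2::aes(x = .data$qtl, y = .data$power)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "True QTL", y = "Detection power (%)",
                  subtitle = sprintf("FDR %.1f%%", object$summary$fdr))
}
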