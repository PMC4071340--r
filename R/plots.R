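#' Plot an inducibility curve
#'
#' Activity versus inducer level on a logarithmic x axis.
#'
#' @param object An `"inducibility_curve"` tibble.
#' @param ... Additional curves to overlay, named for the legend.
#' @return A ggplot object.
#' @export
autoplot.inducibility_curve <- function(object, ...) {
  extra <- list(...)
  extra <- extra[vapply(extra, inherits, logical(1), "inducibility_curve")]
  curves <- c(list(object), extra)
  labels <- names(curves)
  if (is.null(labels)) labels <- rep("", length(curves))
  labels[!nzchar(labels)] <- paste0(
    "N = ", vapply(curves, function(cv) {
      n <- attr(cv, "N"); if (is.na(n)) "ref" else as.character(n)
    }, character(1)))[!nzchar(labels)]
  df <- dplyr::bind_rows(
    purrr::map2(curves, labels, function(cv, lab) {
      tibble::tibble(g = cv$g, f = cv$f_end, curve = lab)
    })
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$g, y = .data$f,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "inducer level g", y = "network activity f",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot penalty scatter of a sweep
#'
#' Inducibility penalty versus compensation penalty, one point per
#' network, with the classification thresholds marked. The lower-left
#' region holds the networks that are simultaneously dosage-compensated
#' and inducible.
#'
#' @param object A `"dosage_sweep"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dosage_sweep <- function(object, ...) {
  cfg <- attr(object, "config")
  ok <- object[!object$excluded, , drop = FALSE]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$compensation_penalty,
                                   y = .data$inducibility_penalty,
                                   colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_vline(xintercept = cfg$comp_threshold,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = cfg$induc_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "compensation penalty", y = "inducibility penalty",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a constrained-parameter histogram
#'
#' @param object A `"constrained_histogram"` from
#'   [constrained_parameter_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.constrained_histogram <- function(object, ...) {
  mids <- (utils::head(object$bin_edges, -1) +
             utils::tail(object$bin_edges, -1)) / 2
  df <- tibble::tibble(mid = mids, count = object$counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$bin_edges)[1] * 0.9) +
    ggplot2::labs(x = object$parameter, y = "networks") +
    ggplot2::theme_minimal()
}
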