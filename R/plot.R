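# ggplot2 views of simulation results: pressure panels, the atrial PV loop
# and the transmitral flow wave.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot simulated pressures over time
#'
#' Left-heart pressures (LA, LV, aorta) in the style of the classic Wiggers
#' diagram panel; set `chambers` to choose other traces.
#'
#' @param object A `cvs_simulation`.
#' @param chambers Character vector of pressure columns to draw.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot cvs_simulation
#' @export
autoplot.cvs_simulation <- function(object,
                                    chambers = c("P_la", "P_lv", "P_ao"),
                                    ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object$traces, "time", dplyr::all_of(chambers)),
    -"time", names_to = "chamber", values_to = "pressure"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$pressure,
                                   colour = .data$chamber)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "pressure (mmHg)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a pressure-volume loop with its lobe decomposition
#'
#' @param x A `pv_loop` from [extract_pv_loop()], or an object accepted by
#'   it (one-cycle traces / `cvs_simulation`).
#' @param ... Passed to [extract_pv_loop()] when `x` is not a `pv_loop`.
#' @return A ggplot object; the self-intersection (if any) is marked.
#' @export
plot_pv_loop <- function(x, ...) {
  pv <- if (inherits(x, "pv_loop")) x else extract_pv_loop(x, ...)
  gg <- ggplot2::ggplot(pv$loop, ggplot2::aes(.data$volume,
                                              .data$pressure)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "volume (ml)", y = "pressure (mmHg)") +
    ggplot2::theme_minimal()
  if (nrow(pv$crossing)) {
    gg <- gg + ggplot2::geom_point(data = pv$crossing, shape = 4, size = 3)
  }
  gg
}

#' Plot the transmitral flow wave
#'
#' @param x A `cvs_simulation` or one-cycle trace data frame with `time`,
#'   `Q_mt`.
#' @param ... Ignored.
#' @return A ggplot object with the E/A peaks annotated.
#' @export
plot_mitral_flow <- function(x, ...) {
  tr <- if (inherits(x, "cvs_simulation")) x$traces else as.data.frame(x)
  feats <- mitral_wave_features(tr)
  pk <- tibble::tibble(
    time = c(feats$e_time, feats$a_time),
    Q_mt = c(feats$e_flow, feats$a_flow),
    wave = c("E", "A")
  )
  pk <- pk[!is.na(pk$time), , drop = FALSE]
  ggplot2::ggplot(tr, ggplot2::aes(.data$time, .data$Q_mt)) +
    ggplot2::geom_line() +
    ggplot2::geom_text(data = pk, ggplot2::aes(label = .data$wave),
                       vjust = -0.6) +
    ggplot2::labs(x = "time (s)", y = "transmitral flow (ml/s)") +
    ggplot2::theme_minimal()
}
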