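#' Consistency scatter of two test statistics
#'
#' Scatter of one Z statistic against another (classical vs emulated, or LS vs
#' QLS) with the y = x reference line.
#'
#' @param data A data frame containing the two Z columns.
#' @param x,y Column names (strings).
#' @return A ggplot object.
#' @export
plot_consistency <- function(data, x = "z_ls", y = "z_qls") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::labs(x = x, y = y) +
    ggplot2::theme_minimal()
}

#' Chi-square(1) QQ plot of null statistics
#'
#' @param s Observed null chi-square statistics.
#' @param label Series label.
#' @return A ggplot object.
#' @export
plot_qq <- function(s, label = "statistic") {
  df <- qq_data(s)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theoretical, y = .data$observed)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::labs(x = expression(chi[1]^2 ~ "quantiles"), y = label) +
    ggplot2::theme_minimal()
}

#' @method autoplot kin_emulator
#' @export
autoplot.kin_emulator <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
}

#' @method autoplot kin_experiment
#' @export
autoplot.kin_experiment <- function(object, ...) {
  pw <- dplyr::filter(object$rates, .data$k > 0)
  ggplot2::ggplot(pw, ggplot2::aes(x = .data$k, y = .data$power,
                                   colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "effect level k", y = "empirical power") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
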