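# ggplot2 views of the main result types

#' Plot RMSD series
#'
#' Line plot of one or more RMSD series (combine replicates with
#' `dplyr::bind_rows()` after labelling them via the `label` argument of
#' [rmsd_series()]).
#'
#' @param series Tibble from [rmsd_series()] (optionally with a `label`
#'   column).
#' @return A ggplot.
#' @export
plot_rmsd_series <- function(series) {
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$time_ps / 1000, y = .data$rmsd))
  if ("label" %in% names(series)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$label))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "time (ns)", y = "RMSD (Å)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.phstab_stability <- function(object, ...) {
  nm <- attr(object, "model_names") %||% c("model 1", "model 2")
  df <- dplyr::mutate(tibble::as_tibble(object),
    domain = factor(.data$domain, levels = .data$domain)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$domain, y = .data$delta_rmsd)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$significant)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$delta_rmsd - .data$delta_sd,
        ymax = .data$delta_rmsd + .data$delta_sd
      ),
      width = 0.3
    ) +
    ggplot2::labs(
      y = sprintf("ΔRMSD (Å): %s − %s", nm[2], nm[1]),
      fill = "f ≤ threshold"
    )
}

#' @exportS3Method ggplot2::autoplot
autoplot.phstab_infit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(time = seq(min(d$time), max(d$time), length.out = 200))
  grid$activity <- object$A_0 * exp(-object$k_in * grid$time)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$activity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "time (min)", y = "residual activity")
}

#' @exportS3Method ggplot2::autoplot
autoplot.phstab_mmfit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(
    substrate = seq(min(d$substrate), max(d$substrate), length.out = 200)
  )
  grid$rate <- object$k_cat * object$enzyme_conc * grid$substrate /
    (object$K_M + grid$substrate)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$substrate, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "substrate (µM)", y = "initial rate")
}
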