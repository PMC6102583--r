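#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Similarity-distribution plot
#'
#' Histogram of per-ligand Tanimoto coefficients in the report's bins.
#'
#' @param object A `similarity_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.similarity_report <- function(object, ...) {
  bins <- object$bins |>
    dplyr::mutate(bin = sprintf("(%.1f, %.1f]", .data$lower, .data$upper))
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "Tanimoto coefficient", y = "ligands",
      title = paste("Similarity to", object$reference)
    ) +
    ggplot2::theme_minimal()
}

#' Cascade funnel plot
#'
#' Survivor counts per cascade stage.
#'
#' @param object A `cascade_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cascade_result <- function(object, ...) {
  st <- object$stages |>
    dplyr::mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(st, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "survivors", title = "Screening cascade") +
    ggplot2::theme_minimal()
}

#' Energy-component plot
#'
#' Component means with error bars (one standard deviation).
#'
#' @param object An `energy_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.energy_summary <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object)) |>
    dplyr::mutate(component = factor(.data$component, levels = .data$component))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$mean)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "energy (kJ/mol)") +
    ggplot2::theme_minimal()
}

#' Residue interaction-frequency column diagram
#'
#' The key-residue analysis plot: for each residue, the number of compounds
#' forming an interaction with it.
#'
#' @param freq Tibble from [interaction_frequency()].
#' @param top Show at most this many residues (default 15).
#' @return A ggplot.
#' @export
plot_interaction_frequency <- function(freq, top = 15) {
  df <- utils::head(freq, top) |>
    dplyr::mutate(residue = factor(.data$residue, levels = rev(.data$residue)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$residue)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "compounds", y = NULL, title = "Interaction frequency") +
    ggplot2::theme_minimal()
}

#' RMSD / RMSF quick plots
#'
#' @param series Tibble from [rmsd_series()].
#' @return A ggplot.
#' @export
plot_rmsd <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$frame, y = .data$rmsd)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "frame", y = "RMSD (Å)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_rmsd
#' @param rmsf Tibble from [rmsf_per_residue()].
#' @export
plot_rmsf <- function(rmsf) {
  df <- rmsf |>
    dplyr::mutate(residue = factor(.data$residue, levels = .data$residue))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$rmsf, group = 1)) +
    ggplot2::geom_line(color = "darkorange") +
    ggplot2::labs(x = NULL, y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}
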