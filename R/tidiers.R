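#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pharmacophore model
#'
#' @param x A `phore_model`.
#' @param ... Unused.
#' @return Tibble of spheres: `element` (`"feature"`/`"excluded_volume"`),
#'   `kind`, `x`, `y`, `z`, `radius` (tolerance for features), `weight`.
#' @export
tidy.phore_model <- function(x, ...) {
  dplyr::bind_rows(
    x$features |>
      dplyr::transmute(
        element = "feature", kind = .data$kind,
        x = .data$x, y = .data$y, z = .data$z,
        radius = .data$tolerance, weight = .data$weight
      ),
    x$excluded_volumes |>
      dplyr::transmute(
        element = "excluded_volume", kind = "Ev",
        x = .data$x, y = .data$y, z = .data$z,
        radius = .data$radius, weight = NA_real_
      )
  )
}

#' @rdname tidy.phore_model
#' @export
glance.phore_model <- function(x, ...) {
  comp <- table(factor(x$features$kind, levels = c("A", "D", "H", "R")))
  tibble::tibble(
    name = x$name,
    n_features = nrow(x$features),
    n_A = comp[["A"]], n_D = comp[["D"]], n_H = comp[["H"]], n_R = comp[["R"]],
    n_ev = nrow(x$excluded_volumes),
    max_fitvalue = sum(x$features$weight),
    rank_score = x$rank_score
  )
}

#' Tidy a cascade result
#'
#' @param x A `cascade_result`.
#' @param ... Unused.
#' @return The final ranked candidate tibble.
#' @export
tidy.cascade_result <- function(x, ...) x$candidates

#' @rdname tidy.cascade_result
#' @export
glance.cascade_result <- function(x, ...) {
  wide <- stats::setNames(as.list(x$stages$n), paste0("n_", x$stages$stage))
  tibble::as_tibble(wide)
}

#' Tidy an energy summary
#'
#' @param x An `energy_summary`.
#' @param ... Unused.
#' @return Tibble (`component`, `mean`, `sd`).
#' @export
tidy.energy_summary <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.energy_summary
#' @export
glance.energy_summary <- function(x, ...) {
  tot <- x[x$component == "total", ]
  tibble::tibble(
    binding_energy = tot$mean, sd = tot$sd, n_frames = attr(x, "n_frames")
  )
}

#' Tidy a similarity report
#'
#' @param x A `similarity_report`.
#' @param ... Unused.
#' @return Per-ligand tibble (`id`, `coefficient`).
#' @export
tidy.similarity_report <- function(x, ...) x$ligands

#' @rdname tidy.similarity_report
#' @export
glance.similarity_report <- function(x, ...) {
  tibble::tibble(
    reference = x$reference,
    n = nrow(x$ligands),
    mean = mean(x$ligands$coefficient),
    min = min(x$ligands$coefficient),
    max = max(x$ligands$coefficient),
    pct_above_0.7 = fraction_above(x, 0.7)
  )
}
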