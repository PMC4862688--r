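# ggplot2 autoplot methods for the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_raster labs theme_minimal scale_fill_viridis_c facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a free-energy profile
#'
#' @param object a `free_energy_profile`.
#' @param ... unused.
#' @export
autoplot.free_energy_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$Q, y = .data$F)) +
    geom_line() +
    labs(x = "Q (fraction of native contacts)", y = "F(Q) (kcal/mol)",
         title = sprintf("T = %g K", attr(object, "temperature"))) +
    theme_minimal()
}

#' Plot a contact map (native pairs below the diagonal mirrored above)
#'
#' @param object a `contact_map`.
#' @param ... unused.
#' @export
autoplot.contact_map <- function(object, ...) {
  tbl <- as_tibble(object)
  ggplot(bind_rows(tbl, tibble(i = tbl$j, j = tbl$i, r0 = tbl$r0,
                               eps = tbl$eps)),
         aes(x = .data$i, y = .data$j, fill = .data$eps)) +
    geom_raster() +
    scale_fill_viridis_c(name = "epsilon\n(kcal/mol)") +
    labs(x = "residue i", y = "residue j") +
    theme_minimal()
}

#' Plot campaign outcome populations
#'
#' @param object an `fp_campaign`.
#' @param ... unused.
#' @export
autoplot.fp_campaign <- function(object, ...) {
  s <- object$summary
  s$label <- factor(s$label, levels = s$label)
  ggplot(s, aes(x = .data$label, y = .data$fraction)) +
    geom_col() +
    labs(x = "final state", y = "fraction of trajectories") +
    theme_minimal()
}

#' Plot a WSME free-energy surface
#'
#' @param object a `wsme_surface`.
#' @param ... unused.
#' @export
autoplot.wsme_surface <- function(object, ...) {
  ggplot(filter(object, is.finite(.data$F)),
         aes(x = .data$Q_res, y = .data$ij_bar, fill = .data$F)) +
    geom_raster() +
    scale_fill_viridis_c(name = "F (kcal/mol)", direction = -1) +
    labs(x = expression(Q[res]), y = "nucleus position (residue)",
         title = sprintf("Ep = %g kcal/mol", attr(object, "Ep"))) +
    theme_minimal()
}

#' Plot alchemical destabilization against cut position
#'
#' @param object an `alchemical_result`.
#' @param ... unused.
#' @export
autoplot.alchemical_result <- function(object, ...) {
  ggplot(object, aes(x = .data$K, y = .data$ddG_tot)) +
    geom_point() +
    geom_line(linetype = "dashed") +
    labs(x = "cut position K",
         y = expression(Delta * Delta * G[tot] ~ "(kcal/mol)")) +
    theme_minimal()
}
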