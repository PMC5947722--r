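#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-snapshot rotation fits
#'
#' @param x A [ensemble_rotation_fits()] tibble.
#' @param ... Unused.
#' @return The per-(copy, snapshot) tibble.
#' @export
tidy.rotation_fit <- function(x, ...) tibble::as_tibble(x)

#' One-row-per-copy summary of rotation fits
#'
#' @param x A [ensemble_rotation_fits()] tibble.
#' @param ... Unused.
#' @return [rotation_statistics()] of `x`.
#' @export
glance.rotation_fit <- function(x, ...) rotation_statistics(x)

#' Tidy a diffuse map
#'
#' @param x A [diffuse_map()].
#' @param ... Unused.
#' @return A plain tibble of the measured points.
#' @export
tidy.diffuse_map <- function(x, ...) {
  tibble::as_tibble(x)[map_measured(x), ]
}

#' One-row summary of a diffuse map
#'
#' @param x A [diffuse_map()].
#' @param ... Unused.
#' @return A tibble: point counts, intensity moments, provenance.
#' @export
glance.diffuse_map <- function(x, ...) {
  meas <- map_measured(x)
  tibble::tibble(n_points = nrow(x), n_measured = sum(meas),
                 mean_intensity = mean(x$intensity[meas]),
                 sd_intensity = stats::sd(x$intensity[meas]),
                 d_min = attr(x, "d_min"),
                 provenance = map_provenance(x))
}

#' Tidy a map comparison
#'
#' @param x A [diffuse_compare()] result.
#' @param ... Unused.
#' @return The per-shell CC tibble.
#' @export
tidy.diffuse_comparison <- function(x, ...) x$shell_cc

#' @rdname tidy.diffuse_comparison
#' @export
glance.diffuse_comparison <- function(x, ...) {
  tibble::tibble(r_oc = x$r_oc, r_oc_aniso = x$r_oc_aniso,
                 cc_sym = x$cc_sym)
}

#' Plot a central section of a diffuse map
#'
#' Raster of the l = `at_l` plane (in integer supercell index units) of the
#' measured points.
#'
#' @param object A [diffuse_map()].
#' @param at_l Integer supercell l index of the section (default 0).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diffuse_map <- function(object, at_l = 0L, ...) {
  df <- tibble::as_tibble(object)
  df <- df[map_measured(object) & df$il == at_l, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$k,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s, l = %g section",
                                  map_provenance(object),
                                  at_l / attr(object, "sampling")[3]),
                  x = "h", y = "k", fill = "I")
}

#' Plot a radial intensity profile
#'
#' @param object A [radial_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radial_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$n_points > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s_mid, y = .data$intensity)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "|s| (1/Angstrom)", y = "shell mean intensity")
}

#' Plot Euler-angle trajectories of rotation fits
#'
#' @param object A [ensemble_rotation_fits()] tibble.
#' @param ... Unused.
#' @return A ggplot (angle vs snapshot, faceted by copy).
#' @export
autoplot.rotation_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("phi", "theta", "psi"),
                            names_to = "angle_name", values_to = "angle_deg")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$snapshot, y = .data$angle_deg,
                                   colour = .data$angle_name)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~copy) +
    ggplot2::labs(x = "snapshot", y = "angle (degrees)", colour = NULL)
}

#' Contour plot of a Patterson section
#'
#' @param pmap A `patterson_map` from [patterson_fft()].
#' @param axis,at Section selector, as in [patterson_section()].
#' @param sigma_scaled Contour in units of the map SD.
#' @return A ggplot.
#' @export
plot_patterson_section <- function(pmap, axis = "x", at = 0,
                                   sigma_scaled = TRUE) {
  pl <- patterson_section(pmap, axis, at, sigma_scaled = sigma_scaled)
  df <- tidyr::expand_grid(u = as.numeric(rownames(pl)),
                           v = as.numeric(colnames(pl)))
  df <- df[order(df$v, df$u), ]
  df$value <- as.vector(pl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   z = .data$value)) +
    ggplot2::geom_contour(breaks = seq(-10, 10, by = 0.5),
                          ggplot2::aes(colour = ggplot2::after_stat(
                            .data$level > 0))) +
    ggplot2::scale_colour_manual(values = c("red", "black"),
                                 guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "fractional", y = "fractional",
                  title = sprintf("Patterson %s = %.2f section", axis, at))
}
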