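# ggplot2 displays for maps, images and profiles.

#' @describeIn rasterize_cylinder_surface Heatmap of the unwrapped side
#'   surface (arc length vs z), optionally max-normalized.
#' @param object A `cylinder_surface_map`.
#' @param normalize Divide by the map maximum before plotting.
#' @param ... Ignored.
#' @export
autoplot.cylinder_surface_map <- function(object, normalize = TRUE, ...) {
  df <- tibble(arc = rep(object$arc_centers, each = nrow(object$map)),
               z = rep(object$z_centers, times = ncol(object$map)),
               value = as.numeric(object$map))
  if (normalize && max(df$value) > 0) df$value <- df$value / max(df$value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arc, y = .data$z,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (normalize) "J[n] / max" else
      "J[n] (W/mm^2)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "arc length (mm)", y = "z (mm)",
                  title = "Unwrapped side-surface flux density")
}

#' @describeIn render_detector Heatmap of the detector image.
#' @param object A `detector_image`.
#' @param normalize Divide by the image maximum before plotting.
#' @param ... Ignored.
#' @export
autoplot.detector_image <- function(object, normalize = TRUE, ...) {
  df <- as_tibble(object)
  if (normalize && max(df$power) > 0) df$power <- df$power / max(df$power)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (normalize) "P / max" else
      "P (W)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "detector u (mm)", y = "detector v (mm)",
                  title = sprintf("Detector image (%s mode)", object$mode))
}

#' Line plot of one or more constant-z profiles
#'
#' @param ... Profiles from [extract_profile()], optionally named.
#' @param normalize Divide each profile by its own maximum.
#' @return A ggplot object.
#' @export
plot_profile <- function(..., normalize = TRUE) {
  profs <- list(...)
  nm <- names(profs)
  if (is.null(nm)) nm <- rep("", length(profs))
  nm[nm == ""] <- paste0("profile ", which(nm == ""))
  df <- bind_rows(lapply(seq_along(profs), function(i) {
    p <- profs[[i]]
    v <- if (normalize && max(p$value) > 0) p$value / max(p$value) else p$value
    tibble(position = p$position, value = v, series = nm[i])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (mm)",
                  y = if (normalize) "normalized flux" else "flux",
                  colour = NULL)
}
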