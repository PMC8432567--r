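# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @exportS3Method generics::tidy
tidy.rigid_transform <- function(x, ...) {
  e <- euler_decompose(x$rotation)
  tibble(left_right = x$translation[1],
         advance_setback = x$translation[2],
         impaction_elongation = x$translation[3],
         pitch = e[["pitch"]], roll = e[["roll"]], yaw = e[["yaw"]])
}

#' @exportS3Method generics::tidy
tidy.registration_result <- function(x, ...) tidy(x$transform)

#' @exportS3Method generics::glance
glance.registration_result <- function(x, ...) {
  tibble(rms = x$rms, iterations = x$iterations,
         converged = isTRUE(x$converged), method = x$method)
}

#' @exportS3Method generics::tidy
tidy.pose_estimate <- function(x, ...) {
  e <- euler_decompose(x$rotation)
  tibble(pitch = e[["pitch"]], roll = e[["roll"]], yaw = e[["yaw"]],
         tx = x$translation[1], ty = x$translation[2], tz = x$translation[3])
}

#' @exportS3Method generics::glance
glance.pose_estimate <- function(x, ...) {
  tibble(residual_px = x$residual, iterations = x$iterations,
         converged = isTRUE(x$converged), n_landmarks = length(x$landmarks))
}

#' @exportS3Method generics::tidy
tidy.discrepancy_report <- function(x, ...) x$linear

#' @exportS3Method generics::glance
glance.discrepancy_report <- function(x, ...) {
  tibble(mean_abs_dx = mean(x$linear$adx),
         mean_abs_dy = mean(x$linear$ady),
         mean_abs_dz = mean(x$linear$adz),
         mean_rms = mean(x$linear$rms),
         pitch = x$angular$pitch, roll = x$angular$roll, yaw = x$angular$yaw,
         registration_rms = x$registration$rms)
}

#' Plot per-landmark discrepancies of a report
#'
#' Bars of the absolute per-axis discrepancies with the per-landmark RMS
#' overlaid as points.
#'
#' @param object a `discrepancy_report`
#' @param ... unused
#' @return a ggplot object
#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point labs
#'   position_dodge theme_minimal
#' @exportS3Method ggplot2::autoplot
autoplot.discrepancy_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$linear, "landmark", "adx", "ady", "adz"),
    cols = c("adx", "ady", "adz"),
    names_to = "axis", values_to = "discrepancy")
  long$axis <- c(adx = "left-right", ady = "advance-setback",
                 adz = "impaction-elongation")[long$axis]
  ggplot(long, aes(x = .data$landmark, y = .data$discrepancy,
                   fill = .data$axis)) +
    geom_col(position = position_dodge()) +
    geom_point(data = object$linear,
               aes(x = .data$landmark, y = .data$rms),
               inherit.aes = FALSE, shape = 18, size = 2) +
    labs(x = NULL, y = "absolute discrepancy (mm)",
         fill = NULL,
         title = "Per-landmark linear discrepancy (diamond = RMS)") +
    theme_minimal()
}

#' Plot a displacement summary table
#'
#' Signed and absolute means with SD error bars for each displacement
#' component.
#'
#' @param object the output of [summarize_displacements()]
#' @param ... unused
#' @importFrom ggplot2 geom_errorbar facet_wrap
#' @return a ggplot object
#' @export
plot_displacement_summary <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble(component = object$component, kind = "signed",
           mean = object$mean, sd = object$sd),
    tibble(component = object$component, kind = "absolute",
           mean = object$abs_mean, sd = object$abs_sd))
  ggplot(long, aes(x = .data$component, y = .data$mean)) +
    geom_col() +
    geom_errorbar(aes(ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd), width = 0.3) +
    facet_wrap(~ .data$kind) +
    labs(x = NULL, y = "displacement (mm or degrees)") +
    theme_minimal()
}
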