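# ggplot2 presentation of the package's result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   labs scale_y_log10 facet_wrap theme_minimal
NULL

#' Plot a hybridization curve
#'
#' @param object a `hyb_curve` from [hybridization_curve()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.hyb_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$hd, y = .data$fraction_bound)) +
    geom_line(linewidth = 0.4, colour = "grey30") +
    geom_point(size = 2) +
    labs(x = "Hamming distance", y = "Hybridization likelihood",
         title = "Hybridization likelihood vs address Hamming distance") +
    theme_minimal()
}

#' Plot competitive amplification trajectories
#'
#' @param object a `pcr_amplification` from [simulate_competitive_pcr()].
#' @param ... ignored.
#' @return a ggplot (log-scale abundance per cycle).
#' @export
autoplot.pcr_amplification <- function(object, ...) {
  ggplot(object$trajectory,
         aes(x = .data$cycle, y = .data$abundance, colour = .data$label)) +
    geom_line() +
    scale_y_log10() +
    labs(x = "Cycle", y = "Abundance (nM)", colour = "Species",
         title = sprintf("Competitive PCR at %.1f C, %g nM primer",
                         object$condition$annealing_temperature[1],
                         object$condition$primer_concentration[1])) +
    theme_minimal()
}

#' Plot tier amplification of an access simulation
#'
#' @param object an `access_result` from [simulate_access()].
#' @param ... ignored.
#' @return a ggplot of fold amplification per HD tier.
#' @export
autoplot.access_result <- function(object, ...) {
  ggplot(object$tiers, aes(x = factor(.data$hd_tier), y = .data$gain,
                           fill = .data$accessed)) +
    geom_col() +
    scale_y_log10() +
    labs(x = "Address HD tier", y = "Fold amplification", fill = "Accessed",
         title = paste0("PCR access: ", object$condition$label[1])) +
    theme_minimal()
}

#' Plot the Preview economics tradeoffs
#'
#' @param object a `preview_economics` from [economics_sweep()].
#' @param ... ignored.
#' @return a ggplot: density ratio and cost-to-find versus preview fraction.
#' @export
autoplot.preview_economics <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("density_ratio", "cost_preview"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$f, y = .data$value,
                   colour = factor(.data$c))) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "Preview fraction of unique strands", y = NULL,
         colour = "Copy ratio c") +
    theme_minimal()
}
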