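# ggplot2 views of the two result types.

#' Plot a multi-sample peak-calling result
#'
#' `type = "status"` shows per-replicate peak counts by decision status;
#' `type = "support"` shows how many replicates support each consensus
#' region.
#'
#' @param object An `mspc_result` from [run_mspc()].
#' @param type `"status"` or `"support"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mspc_result
#' @export
autoplot.mspc_result <- function(object, type = c("status", "support"), ...) {
  type <- match.arg(type)
  if (type == "status") {
    d <- object$decisions
    d$outcome <- ifelse(d$true_positive, "true positive", d$status)
    d$outcome <- factor(
      d$outcome,
      levels = c("background", "discarded", "confirmed", "true positive")
    )
    ggplot2::ggplot(d, ggplot2::aes(
      x = factor(.data$replicate), fill = .data$outcome
    )) +
      ggplot2::geom_bar(position = "stack") +
      ggplot2::labs(
        x = "replicate", y = "peaks", fill = NULL,
        title = "Peak decisions by replicate"
      ) +
      ggplot2::theme_minimal()
  } else {
    cons <- object$consensus
    ggplot2::ggplot(cons, ggplot2::aes(
      x = factor(.data$supporting_replicates)
    )) +
      ggplot2::geom_bar() +
      ggplot2::labs(
        x = "supporting replicates", y = "consensus regions",
        title = "Replicate support of consensus regions"
      ) +
      ggplot2::theme_minimal()
  }
}

#' Plot an enrichment panel
#'
#' Dot plot of the enrichment score z per annotation, coloured by peak
#' subset -- the common-versus-specific comparison at a glance.
#'
#' @param panel Output of [enrichment_panel()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(panel) {
  ggplot2::ggplot(panel, ggplot2::aes(
    x = .data$z, y = .data$label, colour = .data$subset
  )) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "enrichment score z", y = NULL, colour = "peak set",
      title = "Annotation enrichment by peak subset"
    ) +
    ggplot2::theme_minimal()
}
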