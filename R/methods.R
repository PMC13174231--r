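#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a metrics table into long form
#'
#' @param x An `irae_metrics` table.
#' @param ... Unused.
#' @return Tibble with columns `label_id`, `metric`
#'   (precision/recall/specificity/f1) and `value`.
#' @export
tidy.irae_metrics <- function(x, ...) {
  as_tibble(x) %>%
    select(label_id, precision, recall, specificity, f1) %>%
    tidyr::pivot_longer(-label_id, names_to = "metric", values_to = "value")
}

#' One-row summary of a metrics table
#'
#' @param x An `irae_metrics` table.
#' @param ... Unused.
#' @return One-row tibble with the micro- and macro-averaged metrics.
#' @export
glance.irae_metrics <- function(x, ...) {
  micro <- filter(x, label_id == "micro avg")
  macro <- filter(x, label_id == "macro avg")
  tibble(
    micro_precision = micro$precision, micro_recall = micro$recall,
    micro_specificity = micro$specificity, micro_f1 = micro$f1,
    macro_precision = macro$precision, macro_recall = macro$recall,
    macro_specificity = macro$specificity, macro_f1 = macro$f1,
    n_labels = sum(!x$label_id %in% c("micro avg", "macro avg"))
  )
}

#' @rdname tidy.irae_metrics
#' @export
tidy.irae_threshold_curve <- function(x, ...) {
  as_tibble(x) %>%
    tidyr::pivot_longer(-k, names_to = "metric", values_to = "value")
}

#' @rdname glance.irae_metrics
#' @export
glance.irae_threshold_curve <- function(x, ...) {
  kb <- attr(x, "k_best")
  best <- filter(as_tibble(x), k == kb)
  tibble(
    k_best = kb,
    micro_precision = best$micro_precision, micro_recall = best$micro_recall,
    micro_specificity = best$micro_specificity, micro_f1 = best$micro_f1,
    k_max = max(x$k)
  )
}

#' Plot a decision-threshold sweep
#'
#' Micro-averaged precision, recall and F1 against the decision threshold
#' `k`, with the F1-optimal threshold marked — the standard view for choosing
#' the note-count threshold that balances the precision/recall trade-off of
#' note-to-patient aggregation.
#'
#' @param object An `irae_threshold_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.irae_threshold_curve <- function(object, ...) {
  d <- as_tibble(object) %>%
    select(k, micro_precision, micro_recall, micro_f1) %>%
    tidyr::pivot_longer(-k, names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = k, y = value, colour = metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = attr(object, "k_best"), linetype = "dashed") +
    ggplot2::labs(
      x = "decision threshold k (positive notes required)",
      y = "micro-averaged score", colour = NULL,
      title = "Decision-threshold sweep",
      subtitle = paste0("k_best = ", attr(object, "k_best"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-label metrics
#'
#' Dot plot of precision, recall, specificity and F1 per label; average rows
#' are drawn separately.
#'
#' @param object An `irae_metrics` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.irae_metrics <- function(object, ...) {
  d <- tidy.irae_metrics(object) %>%
    mutate(avg = label_id %in% c("micro avg", "macro avg"))
  ggplot2::ggplot(d, ggplot2::aes(x = value, y = label_id, colour = metric, shape = avg)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17), guide = "none") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "score", y = NULL, colour = NULL,
                  title = "Per-label evaluation") +
    ggplot2::theme_minimal()
}
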