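#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a quantification table
#'
#' @param x A `"quant_table"`.
#' @param ... Unused.
#' @return The long S/N tibble (`peptide_id`, `channel_id`, `condition`,
#'   `is_ko`, `sn_raw`, `sn`, and when present `background`, `sn_adj`).
#' @method tidy quant_table
#' @export
tidy.quant_table <- function(x, ...) x$sn

#' @rdname tidy.quant_table
#' @method glance quant_table
#' @export
glance.quant_table <- function(x, ...) {
  tibble::tibble(
    n_peptides = length(unique(x$sn$peptide_id)),
    n_channels = nrow(x$channels),
    n_ms3 = sum(x$n_scans$n_scans),
    normalized = isTRUE(x$normalized)
  )
}

#' Tidy enrichment results
#'
#' @param x An `"enrichment_result"`.
#' @param ... Unused.
#' @return A plain tibble of per-protein statistics.
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.enrichment_result
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble::tibble(
    n_proteins = nrow(x),
    n_enriched = sum(x$enriched, na.rm = TRUE),
    fc_threshold = unname(th["fc"]),
    p_threshold = unname(th["p"])
  )
}

#' Reporter S/N bar panel per peptide and condition
#'
#' Draws the per-peptide quantification layout used for inhibitor
#' contrasts: one facet per peptide, channels as points grouped by
#' condition, knockout background channels alongside, mean bars per
#' condition.
#'
#' @param object A `"quant_table"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot quant_table
#' @export
autoplot.quant_table <- function(object, ...) {
  d <- object$sn
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$sn)) +
    ggplot2::stat_summary(fun = mean, geom = "bar",
                          fill = "grey80", colour = "grey30", width = 0.6) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_ko), size = 1.5) +
    ggplot2::facet_wrap(~peptide_id, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "firebrick"),
                                 name = "KO background") +
    ggplot2::labs(x = NULL, y = "reporter S/N")
}

#' Volcano plot of enrichment results
#'
#' @param object An `"enrichment_result"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  th <- attr(object, "thresholds")
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                               colour = .data$enriched)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = th["fc"], linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(th["p"]), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (bait / control)",
                  y = "-log10 p", colour = "enriched")
}

#' Acquisition log event timeline
#'
#' @param object An `"acquisition"`.
#' @param ... Unused.
#' @return A ggplot of decision events over retention time.
#' @method autoplot acquisition
#' @export
autoplot.acquisition <- function(object, ...) {
  ggplot2::ggplot(object$log,
                  ggplot2::aes(x = .data$rt_min, y = .data$event,
                               colour = .data$peptide_id)) +
    ggplot2::geom_point(shape = 124, size = 3) +
    ggplot2::labs(x = "retention time (min)", y = NULL, colour = "peptide")
}
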