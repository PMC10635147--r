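#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the main result types: the variance
#' partition (distribution of per-feature proportions), a fine-mapping fit
#' (PIP by variant with credible-set membership), and an enrichment table
#' (log2 fold versus significance, the usual volcano-style view).
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name popqtl-plots
NULL

#' @rdname popqtl-plots
#' @export
autoplot.variance_partition <- function(object, ...) {
  ggplot2::ggplot(object$per_feature, ggplot2::aes(x = .data$proportion)) +
    ggplot2::geom_histogram(bins = 40, fill = "#4477AA", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean_proportion,
                        linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("Proportion of variance explained by %s label", object$level),
      y = "Features",
      subtitle = sprintf("mean = %.3f, permutation p = %s",
                         object$mean_proportion,
                         format.pval(object$p_perm, digits = 2))) +
    ggplot2::theme_minimal()
}

#' @rdname popqtl-plots
#' @export
autoplot.susie_fit <- function(object, ...) {
  dat <- tidy(object)
  dat$idx <- seq_len(nrow(dat))
  dat$set <- factor(ifelse(is.na(dat$cs_id), "none", paste0("CS", dat$cs_id)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$idx, y = .data$pip,
                                    colour = .data$set)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "cis variant index", y = "posterior inclusion probability",
                  colour = "credible set") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname popqtl-plots
#' @param label_threshold Annotations with Bonferroni p below this are
#'   labelled.
#' @export
plot_enrichment <- function(object, label_threshold = 0.05, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$log2_fold,
                               y = -log10(pmax(.data$p, 1e-300)))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$p_bonferroni <= label_threshold)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "#AA3377"),
                                 name = sprintf("Bonferroni p <= %.2g", label_threshold)) +
    ggplot2::labs(x = "log2 fold enrichment", y = "-log10 p (Fisher)") +
    ggplot2::theme_minimal()
}
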