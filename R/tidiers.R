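#' Tidy and glance methods
#'
#' broom-style accessors for the package's fitted objects: `tidy()` returns
#' the per-unit table (features, variants, groups), `glance()` the one-row
#' model summary.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name popqtl-tidiers
NULL

#' @rdname popqtl-tidiers
#' @export
tidy.variance_partition <- function(x, ...) x$per_feature

#' @rdname popqtl-tidiers
#' @export
glance.variance_partition <- function(x, ...) {
  tibble::tibble(level = x$level, mean_proportion = x$mean_proportion,
                 p_perm = x$p_perm, n_perm = x$n_perm,
                 n_features = nrow(x$per_feature))
}

#' @rdname popqtl-tidiers
#' @export
tidy.group_variance_test <- function(x, ...) x$per_group

#' @rdname popqtl-tidiers
#' @export
glance.group_variance_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 n_obs = x$n_obs, family = x$family)
}

#' @rdname popqtl-tidiers
#' @export
tidy.susie_fit <- function(x, ...) {
  tibble::tibble(variant_id = x$variant_ids, pip = unname(x$pip)) |>
    dplyr::left_join(
      dplyr::select(x$sets, "variant_id", "cs_id", "inclusion", "lead"),
      by = "variant_id")
}

#' @rdname popqtl-tidiers
#' @export
glance.susie_fit <- function(x, ...) {
  tibble::tibble(
    n_variants = length(x$pip), n_effects_active = sum(x$V > 0),
    n_credible_sets = if (nrow(x$sets)) length(unique(x$sets$cs_id)) else 0L,
    elbo = tail(x$elbo, 1), niter = x$niter, converged = x$converged,
    sigma2 = x$sigma2)
}

#' @rdname popqtl-tidiers
#' @export
tidy.significance_call <- function(x, ...) x$features

#' @rdname popqtl-tidiers
#' @export
glance.significance_call <- function(x, ...) {
  tibble::tibble(fdr = x$fdr, n_features = nrow(x$features),
                 n_significant = x$n_significant, p_threshold = x$p_threshold,
                 n_pairs = if (is.null(x$pairs)) 0L else nrow(x$pairs))
}

#' @rdname popqtl-tidiers
#' @export
tidy.constraint_stats <- function(x, ...) x$tests

#' @rdname popqtl-tidiers
#' @export
glance.constraint_stats <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$genes), n_egenes = sum(x$genes$egene),
                 n_top_decile = sum(x$genes$top_decile))
}
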