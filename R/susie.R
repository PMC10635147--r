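#' Multi-signal fine-mapping by sum-of-single-effects regression
#'
#' Iterative Bayesian stepwise selection: the phenotype is modelled as a sum
#' of `L` "single effects", each a regression with exactly one non-zero
#' coefficient. At each pass, every effect's fitted contribution is removed
#' from the residuals and a single-effect regression is refitted: per-variant
#' Bayes factors under a normal effect prior (prior variance optimised per
#' effect by one-dimensional empirical-Bayes maximisation), softmaxed into
#' posterior inclusion weights. Iteration stops when the variational lower
#' bound (ELBO) changes by less than `tol`; the ELBO is non-decreasing across
#' iterations.
#'
#' Credible sets are built per effect as the smallest variant set, by
#' descending inclusion weight, whose cumulative mass reaches `coverage`;
#' sets whose purity (minimum absolute genotype correlation among members)
#' falls below `purity_min` are discarded and duplicate memberships collapsed.
#'
#' @param X Numeric matrix, samples in rows, cis variants in columns
#'   (column names = variant ids). Standardised internally.
#' @param y Numeric phenotype vector (residualized); centred internally.
#' @param L Maximum number of effects (default 10).
#' @param coverage Credible-set coverage level (default 0.95).
#' @param purity_min Minimum purity (default 0.5).
#' @param tol ELBO convergence tolerance (default 1e-3).
#' @param max_iter Maximum iterations (default 100).
#' @param variant_info Optional tibble (`id`, `maf`, `pos`) used for
#'   deterministic lead-variant tie-breaking.
#' @return A `susie_fit` object with elements `alpha` (L x p inclusion
#'   matrix), `mu`, `pip`, `V` (per-effect prior variances), `sigma2`,
#'   `elbo` (trace), `converged`, and `sets` (credible-set tibble with
#'   columns `cs_id`, `variant_id`, `inclusion`, `purity`, `lead`).
#' @export
susie_fit <- function(X, y, L = 10, coverage = 0.95, purity_min = 0.5,
                      tol = 1e-3, max_iter = 100, variant_info = NULL) {
  if (L < 1) abort("L must be >= 1")
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) abort("length(y) must match nrow(X)")
  if (sd(y) == 0) abort("zero-variance phenotype")
  ids <- colnames(X) %||% paste0("v", seq_len(p))
  csd <- apply(X, 2, sd)
  usable <- csd > 0
  Xs <- X
  Xs[, usable] <- scale(X[, usable, drop = FALSE])
  Xs[, !usable] <- 0
  y <- y - mean(y)
  d <- colSums(Xs^2)

  alpha <- matrix(1 / p, L, p)
  mu <- matrix(0, L, p)
  tau2 <- matrix(0, L, p)
  V <- rep(0, L)
  lbf_model <- rep(0, L)
  sigma2 <- var(y)
  XB <- matrix(0, n, L)          # per-effect fitted vectors X %*% (alpha*mu)
  elbo <- -Inf
  elbo_trace <- numeric(0)
  converged <- FALSE

  ser_loglik <- function(lV, bhat, shat2, ok) {
    v <- exp(lV)
    lbf <- 0.5 * log(shat2 / (shat2 + v)) +
      0.5 * bhat^2 / shat2 * v / (v + shat2)
    lbf[!ok] <- -Inf
    m <- max(lbf)
    m + log(mean(exp(lbf - m)))
  }

  kl <- rep(0, L)
  for (it in seq_len(max_iter)) {
    for (l in seq_len(L)) {
      r_l <- y - rowSums(XB[, -l, drop = FALSE])
      xtr <- as.vector(crossprod(Xs, r_l))
      bhat <- ifelse(usable, xtr / d, 0)
      shat2 <- ifelse(usable, sigma2 / d, Inf)
      opt <- optimize(ser_loglik, c(log(1e-8), log(2 * max(var(y), 1))),
                      bhat = bhat, shat2 = shat2, ok = usable, maximum = TRUE)
      v_new <- exp(opt$maximum); ll_new <- opt$objective
      if (V[l] > 0) {
        # optimize() can miss the mode; never do worse than the previous V
        ll_old <- ser_loglik(log(V[l]), bhat, shat2, usable)
        if (ll_old > ll_new) {
          v_new <- V[l]; ll_new <- ll_old
        }
      }
      if (ll_new <= 1e-12) {
        # empirical-Bayes prior variance collapses: effect is null
        V[l] <- 0
        alpha[l, ] <- 1 / p
        mu[l, ] <- 0; tau2[l, ] <- 0
        lbf_model[l] <- 0
        XB[, l] <- 0
        kl[l] <- 0
        next
      }
      V[l] <- v_new
      lbf <- 0.5 * log(shat2 / (shat2 + V[l])) +
        0.5 * bhat^2 / shat2 * V[l] / (V[l] + shat2)
      lbf[!usable] <- -Inf
      mx <- max(lbf)
      w <- exp(lbf - mx)
      alpha[l, ] <- w / sum(w)
      tau2[l, ] <- ifelse(usable, 1 / (1 / V[l] + d / sigma2), 0)
      mu[l, ] <- ifelse(usable, tau2[l, ] * xtr / sigma2, 0)
      lbf_model[l] <- mx + log(mean(w))
      XB[, l] <- Xs %*% (alpha[l, ] * mu[l, ])
      # KL(q_l || prior) via the SER identity, valid for the residual the
      # effect was just updated against
      eb2d_l <- sum(alpha[l, ] * (mu[l, ]^2 + tau2[l, ]) * d)
      kl[l] <- -lbf_model[l] +
        (2 * sum(r_l * XB[, l]) - eb2d_l) / (2 * sigma2)
    }
    fitted <- rowSums(XB)
    eb2d <- vapply(seq_len(L), function(l)
      sum(alpha[l, ] * (mu[l, ]^2 + tau2[l, ]) * d), numeric(1))
    erss <- sum((y - fitted)^2) + sum(eb2d) - sum(XB^2)
    # ELBO under the sigma2 the posteriors were computed with; the residual
    # variance update below is itself a coordinate-ascent step
    new_elbo <- -n / 2 * log(2 * pi * sigma2) - erss / (2 * sigma2) - sum(kl)
    elbo_trace <- c(elbo_trace, new_elbo)
    if (is.finite(elbo) && abs(new_elbo - elbo) < tol) {
      converged <- TRUE
      elbo <- new_elbo
      break
    }
    elbo <- new_elbo
    sigma2 <- max(erss / n, 1e-12)
  }
  if (!converged) warn(sprintf("susie_fit did not converge in %d iterations", max_iter))

  active <- V > 0
  pip <- if (any(active)) {
    1 - apply(1 - alpha[active, , drop = FALSE], 2, prod)
  } else rep(0, p)
  names(pip) <- ids

  sets <- build_credible_sets(alpha, active, Xs, ids, coverage, purity_min,
                              variant_info)
  structure(list(
    alpha = alpha, mu = mu, pip = pip, V = V, sigma2 = sigma2,
    elbo = elbo_trace, converged = converged, niter = length(elbo_trace),
    coverage = coverage, purity_min = purity_min,
    variant_ids = ids, sets = sets), class = "susie_fit")
}

#' @noRd
build_credible_sets <- function(alpha, active, Xs, ids, coverage, purity_min,
                                variant_info = NULL) {
  out <- list(); seen <- character(0)
  for (l in which(active)) {
    ord <- order(alpha[l, ], decreasing = TRUE)
    csum <- cumsum(alpha[l, ord])
    k <- which(csum >= coverage)[1]
    if (is.na(k)) k <- length(ord)
    members <- ord[seq_len(k)]
    key <- paste(sort(members), collapse = ",")
    if (key %in% seen) next
    purity <- if (length(members) == 1) 1 else {
      cm <- abs(suppressWarnings(cor(Xs[, members, drop = FALSE])))
      min(cm[upper.tri(cm)], na.rm = TRUE)
    }
    if (is.na(purity) || purity < purity_min) next
    seen <- c(seen, key)
    tb <- tibble::tibble(
      cs_id = length(out) + 1L,
      variant_id = ids[members],
      inclusion = alpha[l, members],
      purity = purity)
    tb$lead <- tb$variant_id == select_lead(tb, variant_info)
    out[[length(out) + 1]] <- tb
  }
  if (!length(out)) {
    return(tibble::tibble(cs_id = integer(0), variant_id = character(0),
                          inclusion = numeric(0), purity = numeric(0),
                          lead = logical(0)))
  }
  dplyr::bind_rows(out)
}

#' Select the lead variant of a credible set
#'
#' The member with maximal inclusion score; ties broken by higher MAF, then by
#' lower genomic position, then by variant id — fully deterministic.
#'
#' @param set Tibble with columns `variant_id`, `inclusion` (one credible set).
#' @param variant_info Optional tibble (`id`, `maf`, `pos`) for tie-breaking.
#' @return The lead variant id.
#' @export
select_lead <- function(set, variant_info = NULL) {
  if (nrow(set) == 0) abort("empty credible set")
  tb <- tibble::tibble(variant_id = set$variant_id, inclusion = set$inclusion)
  if (!is.null(variant_info)) {
    ix <- match(tb$variant_id, variant_info$id)
    tb$maf <- variant_info$maf[ix]
    tb$pos <- variant_info$pos[ix]
  } else {
    tb$maf <- 0
    tb$pos <- seq_len(nrow(tb))
  }
  tb <- dplyr::arrange(tb, dplyr::desc(.data$inclusion), dplyr::desc(.data$maf),
                       .data$pos, .data$variant_id)
  tb$variant_id[1]
}

#' Merge intron-level credible sets into gene-level credible sets
#'
#' Within a gene, credible sets sharing at least one variant are merged
#' (membership union) iteratively to a fixed point (transitive closure); the
#' result is the connected-component partition and is therefore invariant to
#' input order. A merged set's per-variant score is the maximum inclusion
#' across its source sets, and the lead variant is re-selected after merging.
#'
#' @param per_intron Tibble with columns `gene_id`, `feature_id`, `cs_id`,
#'   `variant_id`, `inclusion` (intron-level sets of a single gene).
#' @param variant_info Optional tibble (`id`, `maf`, `pos`) for lead
#'   selection.
#' @return Gene-level tibble: `gene_id`, `cs_id`, `variant_id`, `inclusion`,
#'   `source_introns` (comma-separated), `lead`.
#' @export
merge_intron_credible_sets <- function(per_intron, variant_info = NULL) {
  if (nrow(per_intron) == 0) return(per_intron)
  if (length(unique(per_intron$gene_id)) > 1) {
    abort("credible sets from different genes cannot be merged")
  }
  per_intron$node <- paste(per_intron$feature_id, per_intron$cs_id, sep = "@")
  nodes <- unique(per_intron$node)
  comp <- seq_along(nodes); names(comp) <- nodes
  # union components that share a variant
  by_var <- split(per_intron$node, per_intron$variant_id)
  repeat {
    changed <- FALSE
    for (nd in by_var) {
      cc <- comp[unique(nd)]
      if (length(unique(cc)) > 1) {
        comp[names(comp) %in% names(cc) | comp %in% cc] <- min(cc)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  per_intron$component <- comp[per_intron$node]
  merged <- per_intron |>
    dplyr::group_by(.data$component, .data$variant_id) |>
    dplyr::summarise(gene_id = dplyr::first(.data$gene_id),
                     inclusion = max(.data$inclusion),
                     source_introns = paste(sort(unique(.data$feature_id)),
                                            collapse = ","),
                     .groups = "drop") |>
    dplyr::arrange(.data$component, .data$variant_id)
  # sources span the whole merged set, not just the rows carrying a variant
  src <- per_intron |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(all_sources = paste(sort(unique(.data$feature_id)),
                                         collapse = ","), .groups = "drop")
  merged <- dplyr::left_join(merged, src, by = "component") |>
    dplyr::mutate(source_introns = .data$all_sources) |>
    dplyr::select(-"all_sources")
  # stable set numbering: by smallest member variant id
  key <- merged |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(k = min(.data$variant_id), .groups = "drop") |>
    dplyr::arrange(.data$k)
  merged$cs_id <- match(merged$component, key$component)
  merged <- dplyr::arrange(merged, .data$cs_id, .data$variant_id)
  merged$lead <- FALSE
  for (cs in unique(merged$cs_id)) {
    ix <- which(merged$cs_id == cs)
    lead <- select_lead(merged[ix, ], variant_info)
    merged$lead[ix] <- merged$variant_id[ix] == lead
  }
  merged[, c("gene_id", "cs_id", "variant_id", "inclusion",
             "source_introns", "lead")]
}

#' Fine-map one feature's cis window
#'
#' Extracts the cis genotype block around the feature anchor and runs
#' [susie_fit()] on the residualized phenotype.
#'
#' @inheritParams nominal_pass
#' @param feature_id Feature to fine-map.
#' @param L,coverage,purity_min,tol,max_iter Passed to [susie_fit()].
#' @return A `susie_fit` object (credible sets in `$sets`).
#' @export
finemap_feature <- function(genotypes, fm, feature_id, window = 1e6,
                            maf_min = 0.01, L = 10, coverage = 0.95,
                            purity_min = 0.5, tol = 1e-3, max_iter = 100) {
  i <- match(feature_id, fm$features$feature_id)
  if (is.na(i)) abort(paste("unknown feature:", feature_id))
  freq <- variant_frequencies(genotypes)
  idx <- cis_variants(genotypes, fm$features$anchor[i], fm$features$chrom[i],
                      window, freq$maf, maf_min)
  if (!length(idx)) abort(paste("no cis variants for", feature_id))
  X <- t(impute_dosage(genotypes$dosage[idx, , drop = FALSE]))
  vi <- tibble::tibble(id = genotypes$variants$id[idx],
                       maf = freq$maf[idx], pos = genotypes$variants$pos[idx])
  susie_fit(X, fm$values[i, ], L = L, coverage = coverage,
            purity_min = purity_min, tol = tol, max_iter = max_iter,
            variant_info = vi)
}

#' Fine-map a set of features and return all credible sets
#'
#' @inheritParams finemap_feature
#' @param feature_ids Features to fine-map (default: all in `fm`).
#' @return Tibble of credible sets across features: `feature_id`, `gene_id`,
#'   `cs_id`, `variant_id`, `inclusion`, `purity`, `lead`, plus a
#'   `"fits"` attribute holding the `susie_fit` objects.
#' @export
finemap_features <- function(genotypes, fm, feature_ids = fm$features$feature_id,
                             window = 1e6, maf_min = 0.01, L = 10,
                             coverage = 0.95, purity_min = 0.5, tol = 1e-3,
                             max_iter = 100) {
  fits <- list()
  out <- list()
  for (fid in feature_ids) {
    fit <- finemap_feature(genotypes, fm, fid, window, maf_min, L, coverage,
                           purity_min, tol, max_iter)
    fits[[fid]] <- fit
    if (nrow(fit$sets)) {
      gid <- fm$features$gene_id[match(fid, fm$features$feature_id)]
      out[[fid]] <- dplyr::mutate(fit$sets, feature_id = fid, gene_id = gid,
                                  .before = 1)
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "fits") <- fits
  res
}

#' @export
print.susie_fit <- function(x, ...) {
  cat(sprintf(
    "<susie_fit> %d variants, %d active effect(s), %d credible set(s); ELBO %.2f (%s in %d iter)\n",
    length(x$pip), sum(x$V > 0),
    if (nrow(x$sets)) length(unique(x$sets$cs_id)) else 0L,
    tail(x$elbo, 1), if (x$converged) "converged" else "not converged", x$niter))
  invisible(x)
}
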