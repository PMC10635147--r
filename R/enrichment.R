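#' Annotate variants by interval containment
#'
#' Membership of each variant position in each annotation's intervals
#' (internal 1-based closed coordinates; use [read_annotation_bed()] to
#' convert BED input). Unsorted intervals are sorted with a warning;
#' `chr`-prefix mismatches between variants and annotations are reconciled.
#'
#' @param variants Tibble with `chrom`, `pos`, `id`.
#' @param annotations Tibble with `name`, `chrom`, `start`, `end` (1-based
#'   closed).
#' @return Tibble: `variant_id`, one logical column per annotation name.
#' @export
annotate_variants <- function(variants, annotations) {
  if (is.unsorted(order(annotations$name, annotations$chrom, annotations$start))) {
    warn("annotation intervals unsorted; sorting")
  }
  annotations <- dplyr::arrange(annotations, .data$name, .data$chrom, .data$start)
  v_chr <- sub("^chr", "", variants$chrom)
  a_chr <- sub("^chr", "", annotations$chrom)
  out <- tibble::tibble(variant_id = variants$id)
  for (nm in unique(annotations$name)) {
    ai <- which(annotations$name == nm)
    member <- rep(FALSE, nrow(variants))
    for (ch in unique(a_chr[ai])) {
      aj <- ai[a_chr[ai] == ch]
      vi <- which(v_chr == ch)
      if (!length(vi)) next
      # intervals sorted by start; for each position find the last interval
      # starting at or before it and test containment against the running
      # maximum end (handles overlapping intervals)
      st <- annotations$start[aj]; en <- cummax(annotations$end[aj])
      k <- findInterval(variants$pos[vi], st)
      ok <- k > 0
      ok[ok] <- variants$pos[vi][ok] <= en[k[ok]]
      member[vi] <- ok
    }
    out[[nm]] <- member
  }
  out
}

#' MAF- and distance-matched background sampling
#' @noRd
match_background <- function(leads, background, ratio, seed) {
  set.seed(seed)
  maf_breaks <- quantile(c(leads$maf, background$maf), probs = seq(0, 1, 0.1),
                         na.rm = TRUE)
  maf_breaks[1] <- -Inf; maf_breaks[length(maf_breaks)] <- Inf
  bin_of <- function(maf, dist) {
    mb <- cut(maf, unique(maf_breaks), labels = FALSE)
    db <- pmin(pmax(floor(log10(pmax(abs(dist), 1))), 0), 6)
    paste(mb, db, sep = ":")
  }
  lb <- bin_of(leads$maf, leads$distance)
  bb <- bin_of(background$maf, background$distance)
  picks <- integer(0)
  for (b in unique(lb)) {
    want <- sum(lb == b) * ratio
    pool <- which(bb == b)
    if (!length(pool)) {
      warn(sprintf("no background in matching bin %s; relaxing to MAF bin", b))
      pool <- which(sub(":.*", "", bb) == sub(":.*", "", b))
      if (!length(pool)) pool <- seq_len(nrow(background))
    }
    picks <- c(picks, sample_safe(pool, min(want, length(pool))))
  }
  background[unique(picks), , drop = FALSE]
}

#' Enrichment of lead QTLs in genomic annotations
#'
#' For each annotation (and optionally each lead effect-size decile), builds
#' the 2x2 in/out count table of leads versus a background of non-lead cis
#' variants matched to the leads on MAF (deciles) and TSS distance
#' (log10-scale bins) at `ratio`:1, and tests enrichment with Fisher's exact
#' test. Fold enrichment is the ratio of hit rates; Bonferroni correction is
#' over annotations (times deciles in decile mode).
#'
#' @param leads Tibble with `id`, `chrom`, `pos`, `maf`, `distance` and
#'   (for decile mode) `abs_afc`.
#' @param background Tibble of candidate background variants, same columns,
#'   disjoint from the leads.
#' @param annotations Annotation tibble (see [annotate_variants()]).
#' @param deciles Stratify leads by `abs_afc` decile?
#' @param ratio Background:lead matching ratio (default 10).
#' @param match Match the background on MAF and distance (default `TRUE`;
#'   `FALSE` uses the whole background set).
#' @param seed Sampling seed.
#' @return Tibble: `annotation`, optional `decile`, counts, `fold`,
#'   `log2_fold`, `p`, `p_bonferroni`.
#' @export
enrichment_test <- function(leads, background, annotations, deciles = FALSE,
                            ratio = 10, match = TRUE, seed = 1) {
  if (nrow(leads) == 0 || nrow(background) == 0) {
    abort("leads and background must be nonempty")
  }
  if (length(intersect(leads$id, background$id))) {
    abort("background must be disjoint from leads")
  }
  bg <- if (match) match_background(leads, background, ratio, seed) else background
  lead_mem <- annotate_variants(leads, annotations)
  bg_mem <- annotate_variants(bg, annotations)
  ann_names <- setdiff(names(lead_mem), "variant_id")

  dec <- if (deciles) {
    if (!"abs_afc" %in% names(leads)) abort("decile mode needs an abs_afc column")
    as.integer(ceiling(rank(leads$abs_afc, ties.method = "first") * 10 / nrow(leads)))
  } else rep(1L, nrow(leads))
  dec_levels <- sort(unique(dec))
  n_tests <- length(ann_names) * length(dec_levels)

  out <- list()
  for (nm in ann_names) {
    for (dl in dec_levels) {
      li <- dec == dl
      n_in <- sum(lead_mem[[nm]][li]); n_out <- sum(li) - n_in
      b_in <- sum(bg_mem[[nm]]); b_out <- nrow(bg) - b_in
      rate_l <- n_in / sum(li)
      rate_b <- b_in / nrow(bg)
      fold <- if (rate_b > 0) rate_l / rate_b else NA_real_
      p <- fisher.test(matrix(c(n_in, n_out, b_in, b_out), 2, byrow = TRUE))$p.value
      out[[length(out) + 1]] <- tibble::tibble(
        annotation = nm,
        decile = if (deciles) dl else NA_integer_,
        n_lead_in = n_in, n_lead = sum(li),
        n_background_in = b_in, n_background = nrow(bg),
        fold = fold, log2_fold = log2(fold), p = p,
        p_bonferroni = pmin(1, p * n_tests))
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "background_used") <- bg$id
  res
}
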