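#' Pipeline configuration
#'
#' Validates a configuration for [run_pipeline()]. Unknown keys are rejected;
#' defaults are resolved here so the effective configuration can be echoed to
#' the log and saved alongside the outputs.
#'
#' @param out_dir Output directory.
#' @param seed Global seed; per-stage seeds are derived from it with a named
#'   hash so each stage is individually reproducible.
#' @param sim A [sim_config()] (or list of its arguments) for the simulate
#'   stage, or `NULL` to read inputs from `paths`.
#' @param paths Named list of input paths (`vcf`, `expression_bed`,
#'   `samples_tsv`, `annotations_bed`, `constraint_tsv`) when not simulating.
#' @param stages Character vector of stages to run, in dependency order.
#' @param window,maf_min,n_perm,fdr,L,coverage,purity_min Stage parameters.
#' @param n_geno_pcs,n_pheno_pcs Covariate counts.
#' @param n_boot aFC bootstrap resamples.
#' @param focal_group Focal group for the population-statistics stage.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1, sim = sim_config(),
                            paths = list(), stages = pipeline_stages(),
                            window = 1e6, maf_min = 0.01, n_perm = 1000,
                            fdr = 0.05, L = 10, coverage = 0.95,
                            purity_min = 0.5, n_geno_pcs = 5, n_pheno_pcs = 15,
                            n_boot = 100, focal_group = "AFR") {
  cfg <- as.list(environment())
  if (!is.null(sim) && !inherits(sim, "sim_config")) {
    cfg$sim <- do.call(sim_config, sim)
  }
  bad <- setdiff(stages, pipeline_stages())
  if (length(bad)) abort(paste("unknown stage(s):", toString(bad)))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
pipeline_stages <- function() {
  c("simulate", "normalize", "variance", "map_cis", "finemap", "afc",
    "popstats", "enrich")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) abort(paste("unknown config key(s):", toString(bad)))
  do.call(pipeline_config, raw)
}

#' Deterministic per-stage seed derived from the global seed
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order: simulate -> normalize ->
#' variance -> map_cis -> finemap -> afc -> popstats -> enrich. Each stage
#' writes its outputs under `out_dir` and appends an entry (with md5 hashes of
#' the written files) to `manifest.json`. A stage failure halts downstream
#' stages; partial outputs are retained with a failure marker in the manifest.
#' Reruns with an identical configuration and seed are bit-identical for the
#' deterministic stages.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly; outputs live in `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  state <- new.env(parent = emptyenv())
  jsonlite::write_json(
    lapply(unclass(config)[c("seed", "window", "maf_min", "n_perm", "fdr", "L",
                             "coverage", "purity_min", "focal_group")], identity),
    file.path(config$out_dir, "effective_config.json"), auto_unbox = TRUE)

  for (stage in config$stages) {
    inform(paste("pipeline stage:", stage))
    entry <- list(stage = stage, seed = stage_seed(config$seed, stage))
    result <- tryCatch({
      files <- run_stage(stage, config, state, entry$seed)
      entry$status <- "ok"
      entry$outputs <- as.list(unname(tools::md5sum(files)))
      names(entry$outputs) <- basename(files)
      entry
    }, error = function(e) {
      entry$status <- "failed"
      entry$error <- conditionMessage(e)
      entry
    })
    manifest$stages[[stage]] <- result
    if (identical(result$status, "failed")) {
      warn(sprintf("stage '%s' failed: %s; downstream stages skipped",
                   stage, result$error))
      break
    }
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @noRd
run_stage <- function(stage, config, state, seed) {
  od <- config$out_dir
  switch(stage,
    simulate = {
      if (is.null(config$sim)) {
        state$genotypes <- read_genotypes(config$paths$vcf)
        state$expression_raw <- read_phenotype_bed(config$paths$expression_bed,
                                                   kind = "raw-count")
        state$samples <- read_sample_table(config$paths$samples_tsv)
        character(0)
      } else {
        cfg <- config$sim; cfg$seed <- seed
        cohort <- simulate_cohort(cfg, splicing = FALSE)
        state$genotypes <- cohort$genotypes
        state$expression_raw <- cohort$expression
        state$samples <- cohort$samples
        state$truth <- cohort$truth
        write_fixture(file.path(od, "cohort"), cohort, overwrite = TRUE)
      }
    },
    normalize = {
      al <- align_cohort(state$genotypes, state$expression_raw, state$samples)
      state$genotypes <- al$genotypes
      state$samples <- al$samples
      filt <- filter_features(al$phenotypes)
      tr <- inverse_normal_transform(filt)
      cov <- compute_covariates(state$genotypes, tr, state$samples,
                                n_geno_pcs = min(config$n_geno_pcs,
                                                 nrow(state$samples) - 1),
                                n_pheno_pcs = min(config$n_pheno_pcs,
                                                  nrow(tr$values) - 1))
      state$expression_pos <- filt
      state$residual <- residualize(tr, cov)
      state$covariates <- cov
      # technical-only residuals (batch, sex) for the variance stage: the
      # population-label partition must not have ancestry-correlated PCs
      # removed from it
      tech <- cov[, grep("^(batch_|sex)", colnames(cov)), drop = FALSE]
      state$residual_technical <-
        residualize(tr, if (ncol(tech)) tech else NULL)
      f1 <- file.path(od, "covariates.tsv")
      write_covariates_tsv(cov, f1)
      f2 <- file.path(od, "residualized.bed")
      write_phenotype_bed(state$residual, f2)
      c(f1, f2)
    },
    variance = {
      vp <- partition_variance(state$residual_technical, state$samples,
                               "group", n_perm = 999, seed = seed)
      gv <- within_group_variance_test(state$residual_technical, state$samples)
      f1 <- file.path(od, "variance_partition.tsv")
      readr::write_tsv(tidy(vp), f1)
      f2 <- file.path(od, "variance_summary.json")
      jsonlite::write_json(
        c(as.list(glance(vp)), as.list(glance(gv))), f2,
        auto_unbox = TRUE, digits = NA)
      c(f1, f2)
    },
    map_cis = {
      nom <- nominal_pass(state$genotypes, state$residual,
                          window = config$window, maf_min = config$maf_min)
      perm <- permutation_pass(state$genotypes, state$residual,
                               window = config$window, n_perm = config$n_perm,
                               seed = seed, maf_min = config$maf_min)
      call <- call_significant(perm, fdr = config$fdr, nominal = nom)
      state$nominal <- nom
      state$call <- call
      f1 <- file.path(od, "permutation_pass.tsv")
      readr::write_tsv(tidy(call), f1)
      f2 <- file.path(od, "significant_pairs.tsv")
      readr::write_tsv(call$pairs %||%
                         tibble::tibble(feature_id = character(0)), f2)
      c(f1, f2)
    },
    finemap = {
      egenes <- state$call$features$feature_id[state$call$features$significant]
      sets <- if (length(egenes)) {
        finemap_features(state$genotypes, state$residual, egenes,
                         window = config$window, maf_min = config$maf_min,
                         L = config$L, coverage = config$coverage,
                         purity_min = config$purity_min)
      } else {
        tibble::tibble(feature_id = character(0), gene_id = character(0),
                       cs_id = integer(0), variant_id = character(0),
                       inclusion = numeric(0), purity = numeric(0),
                       lead = logical(0))
      }
      state$sets <- sets
      f1 <- file.path(od, "credible_sets.tsv")
      readr::write_tsv(sets, f1)
      f1
    },
    afc = {
      leads <- dplyr::filter(state$sets, .data$lead)
      if (nrow(leads)) {
        afc <- estimate_afc(state$expression_pos, state$genotypes,
                            dplyr::select(leads, "gene_id", "variant_id"),
                            n_boot = config$n_boot, seed = seed)
      } else {
        afc <- tibble::tibble(gene_id = character(0), variant_id = character(0),
                              log2_afc = numeric(0), se = numeric(0))
      }
      state$afc <- afc
      f1 <- file.path(od, "afc.tsv")
      readr::write_tsv(afc, f1)
      f1
    },
    popstats = {
      leads <- dplyr::filter(state$sets, .data$lead)
      files <- character(0)
      if (nrow(leads)) {
        fst <- weir_cockerham_fst(state$genotypes, state$samples,
                                  config$focal_group, leads$variant_id)
        freq <- allele_frequency_by(state$genotypes, state$samples, "group",
                                    leads$variant_id)
        cls <- classify_frequency_distribution(freq)
        de <- differential_expression_by_group(state$residual, state$samples,
                                               config$focal_group)
        inter <- interaction_scan(state$genotypes, state$residual,
                                  state$samples,
                                  dplyr::select(leads, "gene_id", "variant_id"),
                                  mode = "joint")
        f <- c(fst = file.path(od, "lead_fst.tsv"),
               cls = file.path(od, "lead_frequency_class.tsv"),
               de = file.path(od, "differential_expression.tsv"),
               inter = file.path(od, "interaction_scan.tsv"))
        readr::write_tsv(fst, f["fst"])
        readr::write_tsv(cls, f["cls"])
        readr::write_tsv(de, f["de"])
        readr::write_tsv(inter, f["inter"])
        files <- unname(f)
      }
      files
    },
    enrich = {
      leads <- dplyr::filter(state$sets, .data$lead)
      files <- character(0)
      if (nrow(leads) >= 5) {
        freq <- variant_frequencies(state$genotypes)
        vmeta <- state$genotypes$variants |>
          dplyr::mutate(maf = freq$maf) |>
          dplyr::left_join(
            dplyr::select(state$truth$variant_layout, "id", "gene_id"),
            by = "id") |>
          dplyr::left_join(
            dplyr::select(state$truth$genes, "gene_id", "tss"), by = "gene_id") |>
          dplyr::mutate(distance = .data$pos - .data$tss)
        lead_tb <- dplyr::filter(vmeta, .data$id %in% leads$variant_id)
        bg_tb <- dplyr::filter(vmeta, !(.data$id %in% leads$variant_id),
                               .data$maf >= config$maf_min)
        ann <- if (!is.null(config$paths$annotations_bed)) {
          read_annotation_bed(config$paths$annotations_bed)
        } else {
          # default diagnostic annotation: promoter-proximal windows
          tibble::tibble(name = "promoter",
                         chrom = state$truth$genes$chrom,
                         start = state$truth$genes$tss - 2000L,
                         end = state$truth$genes$tss + 2000L)
        }
        enr <- enrichment_test(lead_tb, bg_tb, ann, seed = seed)
        f1 <- file.path(od, "enrichment.tsv")
        readr::write_tsv(enr, f1)
        files <- f1
      }
      files
    },
    abort(paste("unknown stage:", stage))
  )
}
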