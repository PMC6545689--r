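#' Configuration for a pipeline run
#'
#' Collects every threshold used by the stages (detection p 0.01, failing
#' sample fraction 0.05, bead count 3, site FDR 0.01, signature delta 0.2,
#' classifier threshold 0.2, mutation window 5000 bp, 1000 GO resamples)
#' together with the synthetic-study configuration and the master seed.
#'
#' @param seed Master seed; the simulation and every stochastic stage derive
#'   their seeds from it.
#' @param sim A [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param detp_threshold,sample_fraction,min_beads Probe-filter thresholds.
#' @param fdr Site significance threshold on the q-value.
#' @param delta_threshold Signature mean-difference cutoff.
#' @param classifier_threshold Two-score decision threshold.
#' @param window Mutation association half-window (bp).
#' @param n_resamples Resamples for the gene-set test.
#' @param bmiq Logical: apply BMIQ normalization in preprocessing.
#' @param ridge Ridge fraction for the differential GLS.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, sim = NULL,
                            detp_threshold = 0.01, sample_fraction = 0.05,
                            min_beads = 3, fdr = 0.01, delta_threshold = 0.2,
                            classifier_threshold = 0.2, window = 5000,
                            n_resamples = 1000, bmiq = TRUE, ridge = 0) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  cfg <- as.list(environment())
  stopifnot(cfg$detp_threshold > 0, cfg$sample_fraction > 0,
            cfg$min_beads > 0, cfg$fdr > 0, cfg$delta_threshold > 0,
            cfg$classifier_threshold > 0, cfg$window > 0,
            cfg$n_resamples > 0)
  structure(cfg, class = "pipeline_config")
}

pipe_log <- function(...) message("[methsig] ", ...)

need_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stop("missing artifact '", basename(path), "': run stage '", stage,
         "' first", call. = FALSE)
  }
  path
}

write_run_manifest <- function(outdir, stage, config, files) {
  files <- files[file.exists(files)]
  digests <- tools::md5sum(sort(files))
  # key digests by path relative to the run directory so that identical runs
  # in different directories produce byte-identical manifests
  pre <- paste0(sub("/+$", "", outdir), "/")
  names(digests) <- ifelse(startsWith(names(digests), pre),
                           substring(names(digests), nchar(pre) + 1L),
                           names(digests))
  manifest <- list(
    stage = stage,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("methsig")),
    r_version = R.version.string,
    artifacts = as.list(digests)
  )
  jsonlite::write_json(manifest,
                       file.path(outdir, paste0("run_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

stage_simulate <- function(config, outdir) {
  pipe_log("simulate: generating synthetic study (seed ", config$seed, ")")
  study <- simulate_study(config$sim)
  dir <- file.path(outdir, "sim")
  write_study(study, dir)
  write_run_manifest(outdir, "simulate", config,
                     list.files(dir, recursive = TRUE, full.names = TRUE))
  invisible(study)
}

stage_preprocess <- function(config, outdir) {
  sim_dir <- file.path(outdir, "sim")
  need_artifact(file.path(sim_dir, "manifest.tsv"), "simulate")
  manifest <- read_tsv(file.path(sim_dir, "manifest.tsv"))
  manifest$is_negative_control <- as.logical(manifest$is_negative_control)
  manifest$is_cpg <- as.logical(manifest$is_cpg)
  manifest$is_snp <- as.logical(manifest$is_snp)
  manifest$is_multimapped <- as.logical(manifest$is_multimapped)
  M <- read_matrix_tsv(need_artifact(file.path(sim_dir, "intensity_M.tsv"),
                                     "simulate"))
  U <- read_matrix_tsv(file.path(sim_dir, "intensity_U.tsv"))
  beads <- read_matrix_tsv(file.path(sim_dir, "beads.tsv"))
  neg_M <- read_matrix_tsv(file.path(sim_dir, "neg_M.tsv"))
  neg_U <- read_matrix_tsv(file.path(sim_dir, "neg_U.tsv"))
  cgis <- read_bed(file.path(sim_dir, "cgis.bed"))
  genes <- read_tsv(file.path(sim_dir, "genes.tsv"))

  tgt <- manifest[!manifest$is_negative_control, , drop = FALSE]
  pipe_log("preprocess: detection p-values and filters on ",
           nrow(tgt), " probes x ", ncol(M), " samples")
  detp <- detection_pvalue_matrix(M, U, neg_M, neg_U)
  filt <- filter_probes(detp, beads, tgt,
                        detp_threshold = config$detp_threshold,
                        sample_fraction = config$sample_fraction,
                        min_beads = config$min_beads)
  beta <- compute_beta(M[filt$keep, , drop = FALSE],
                       U[filt$keep, , drop = FALSE])
  ann <- annotate_probes(manifest, cgis, genes,
                         chroms = c(paste0("chr", 1:4), "chrX", "chrY"))
  qc <- NULL
  if (isTRUE(config$bmiq)) {
    pipe_log("preprocess: BMIQ normalization")
    at <- ann$assay_type[match(rownames(beta), ann$probe_id)]
    bm <- bmiq_matrix(beta, at)
    beta <- bm$betas
    qc <- bm$qc
  }
  neg_beta <- compute_beta(neg_M, neg_U)

  write_tsv(ann, file.path(outdir, "manifest_annotated.tsv"))
  write_matrix_tsv(beta, file.path(outdir, "beta_norm.tsv"))
  write_matrix_tsv(neg_beta, file.path(outdir, "neg_beta.tsv"))
  write_tsv(filt$counts, file.path(outdir, "removal_report.tsv"))
  if (!is.null(qc)) write_tsv(qc, file.path(outdir, "bmiq_qc.tsv"))
  write_run_manifest(outdir, "preprocess", config, file.path(outdir, c(
    "manifest_annotated.tsv", "beta_norm.tsv", "neg_beta.tsv",
    "removal_report.tsv", "bmiq_qc.tsv")))
  invisible(list(beta = beta, neg_beta = neg_beta, manifest = ann,
                 filter = filt))
}

stage_diff <- function(config, outdir) {
  beta <- read_matrix_tsv(need_artifact(file.path(outdir, "beta_norm.tsv"),
                                        "preprocess"))
  neg_beta <- read_matrix_tsv(file.path(outdir, "neg_beta.tsv"))
  ann <- read_tsv(file.path(outdir, "manifest_annotated.tsv"))
  labels <- read_tsv(need_artifact(file.path(outdir, "sim", "labels.tsv"),
                                   "simulate"))
  pipe_log("diff: inverse-method GLS on ", nrow(beta), " probes")
  combined <- rbind(beta, neg_beta)
  dm <- diff_methylation(combined, labels$group,
                         control_idx = rownames(neg_beta),
                         ridge = config$ridge, fdr = config$fdr)
  sig <- select_signatures(dm, ann, delta_threshold = config$delta_threshold)
  shift <- category_shift_summary(dm, ann)

  res <- dm$results
  res$chrom <- ann$chrom[match(res$probe_id, ann$probe_id)]
  res$pos <- ann$pos[match(res$probe_id, ann$probe_id)]
  res$cgi_group <- ann$cgi_group[match(res$probe_id, ann$probe_id)]
  write_tsv(res, file.path(outdir, "diff_results.tsv"))
  write_tsv(data.frame(probe_id = sig$hyper_island_sites),
            file.path(outdir, "signature_hyper.tsv"))
  write_tsv(data.frame(probe_id = sig$hypo_opensea_sites),
            file.path(outdir, "signature_hypo.tsv"))
  for (nm in c("hyper", "hypo")) {
    ids <- if (nm == "hyper") sig$hyper_island_sites else sig$hypo_opensea_sites
    i <- match(ids, ann$probe_id)
    write_bed(data.frame(chrom = ann$chrom[i], start = ann$pos[i],
                         end = ann$pos[i] + 1, name = ids),
              file.path(outdir, paste0("signature_", nm, ".bed")))
  }
  write_tsv(shift, file.path(outdir, "category_shift.tsv"))
  write_run_manifest(outdir, "diff", config, file.path(outdir, c(
    "diff_results.tsv", "signature_hyper.tsv", "signature_hypo.tsv",
    "signature_hyper.bed", "signature_hypo.bed", "category_shift.tsv")))
  invisible(list(dm = dm, signatures = sig, shift = shift))
}

stage_integrate <- function(config, outdir) {
  res <- read_tsv(need_artifact(file.path(outdir, "diff_results.tsv"), "diff"))
  ann <- read_tsv(file.path(outdir, "manifest_annotated.tsv"))
  beta <- read_matrix_tsv(file.path(outdir, "beta_norm.tsv"))
  hyper <- read_tsv(file.path(outdir, "signature_hyper.tsv"))$probe_id
  hypo <- read_tsv(file.path(outdir, "signature_hypo.tsv"))$probe_id
  sim_dir <- file.path(outdir, "sim")
  mark_files <- list.files(file.path(sim_dir, "marks"), full.names = TRUE)
  fpkm <- read_matrix_tsv(need_artifact(file.path(sim_dir, "fpkm.tsv"),
                                        "simulate"))
  mutations <- read_tsv(file.path(sim_dir, "mutations.tsv"))

  marks <- do.call(rbind, lapply(mark_files, function(f) {
    b <- read_bed(f)
    nm <- strsplit(sub("\\.bed$", "", basename(f)), "_")[[1]]
    data.frame(mark = nm[1], cell = nm[2], b, stringsAsFactors = FALSE)
  }))
  locate <- function(ids) {
    i <- match(ids, ann$probe_id)
    data.frame(chrom = ann$chrom[i], pos = ann$pos[i],
               stringsAsFactors = FALSE)
  }
  insig <- res$probe_id[!res$significant]
  pipe_log("integrate: histone-mark enrichment")
  enr <- rbind(
    cbind(set = "hyper_island",
          enrichment_profile(locate(hyper), locate(insig), marks)),
    cbind(set = "hypo_opensea",
          enrichment_profile(locate(hypo), locate(insig), marks))
  )
  pipe_log("integrate: methylation-expression correlation")
  pg <- ann[!ann$is_negative_control, c("probe_id", "gene")]
  corr <- methylation_expression_correlation(beta, fpkm, pg)
  pipe_log("integrate: mutation-methylation association")
  bg_opensea <- res$probe_id[!res$significant & !is.na(res$cgi_group) &
                               res$cgi_group == "OpenSea"]
  mut <- mutation_methylation_association(
    mutations, beta, ann, site_set = hypo, background_set = bg_opensea,
    window = config$window
  )
  write_tsv(enr, file.path(outdir, "mark_enrichment.tsv"))
  write_tsv(corr, file.path(outdir, "expression_correlation.tsv"))
  write_tsv(mut$pairs, file.path(outdir, "mutation_pairs.tsv"))
  write_tsv(data.frame(statistic = mut$statistic, p_value = mut$p_value,
                       n_site = mut$n_site, n_background = mut$n_background,
                       n_dropped_zero_sd = mut$n_dropped_zero_sd),
            file.path(outdir, "mutation_ks.tsv"))
  write_run_manifest(outdir, "integrate", config, file.path(outdir, c(
    "mark_enrichment.tsv", "expression_correlation.tsv",
    "mutation_pairs.tsv", "mutation_ks.tsv")))
  invisible(list(enrichment = enr, correlation = corr, mutation = mut))
}

stage_go <- function(config, outdir) {
  ann <- read_tsv(need_artifact(file.path(outdir, "manifest_annotated.tsv"),
                                "preprocess"))
  hyper <- read_tsv(need_artifact(file.path(outdir, "signature_hyper.tsv"),
                                  "diff"))$probe_id
  sim_dir <- file.path(outdir, "sim")
  terms <- read_tsv(need_artifact(file.path(sim_dir, "terms.tsv"), "simulate"))
  term_desc <- read_tsv(file.path(sim_dir, "term_desc.tsv"))
  uni <- gene_universe(ann, terms, term_desc)
  test_genes <- unique(stats::na.omit(ann$gene[match(hyper, ann$probe_id)]))
  test_genes <- intersect(test_genes, uni$genes)
  if (length(test_genes) == 0L) stop("no genes linked to the hyper signature")
  pipe_log("go: weighted resampling over ", length(uni$genes), " genes, ",
           config$n_resamples, " resamples")
  go <- weighted_resampling_test(test_genes, uni,
                                 n_resamples = config$n_resamples,
                                 seed = config$seed + 10L)
  write_tsv(go, file.path(outdir, "go_results.tsv"))
  write_run_manifest(outdir, "go", config,
                     file.path(outdir, "go_results.tsv"))
  invisible(go)
}

stage_classify <- function(config, outdir) {
  hyper <- read_tsv(need_artifact(file.path(outdir, "signature_hyper.tsv"),
                                  "diff"))$probe_id
  hypo <- read_tsv(file.path(outdir, "signature_hypo.tsv"))$probe_id
  sig <- list(hyper_island_sites = hyper, hypo_opensea_sites = hypo)
  pipe_log("classify: simulating an independent validation cohort")
  # same genome (same genome seed), fresh samples from a shifted seed
  val_cfg <- config$sim
  val_cfg$seed <- config$sim$seed + 500L
  genome <- simulate_genome(config$sim)
  intens <- simulate_intensities(val_cfg, genome)
  beta_val <- compute_beta(intens$M, intens$U)
  if (isTRUE(config$bmiq)) {
    # score on the same normalization state as the discovery betas
    tgt <- genome$manifest[!genome$manifest$is_negative_control, ]
    at <- tgt$assay_type[match(rownames(beta_val), tgt$probe_id)]
    beta_val <- bmiq_matrix(beta_val, at)$betas
  }
  scores <- score_samples(beta_val, sig,
                          threshold = config$classifier_threshold)
  truth <- stats::setNames(intens$labels$group, intens$labels$sample_id)
  ev <- evaluate_cohort(scores, truth)
  write_tsv(scores, file.path(outdir, "validation_scores.tsv"))
  write_tsv(ev, file.path(outdir, "validation_evaluation.tsv"))
  write_run_manifest(outdir, "classify", config, file.path(outdir, c(
    "validation_scores.tsv", "validation_evaluation.tsv")))
  invisible(list(scores = scores, evaluation = ev))
}

#' Run pipeline stages
#'
#' Orchestrates the analysis stages over plain-text artifacts in `outdir`.
#' Each stage reads the artifacts of its upstream stages (erroring with the
#' name of the stage to run first when they are missing), writes its declared
#' outputs plus a JSON run manifest with package/R versions, the seed and
#' MD5 digests, and `"all"` chains simulate through classify.
#'
#' @param stage One of `"all"`, `"simulate"`, `"preprocess"`, `"diff"`,
#'   `"integrate"`, `"go"`, `"classify"`.
#' @param config A [pipeline_config()].
#' @param outdir Artifact directory (created).
#' @return The invisible return value of the last stage run.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "preprocess", "diff",
                                   "integrate", "go", "classify"),
                         config = pipeline_config(), outdir) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") {
    c("simulate", "preprocess", "diff", "integrate", "go", "classify")
  } else {
    stage
  }
  out <- NULL
  for (s in stages) {
    out <- switch(s,
      simulate = stage_simulate(config, outdir),
      preprocess = stage_preprocess(config, outdir),
      diff = stage_diff(config, outdir),
      integrate = stage_integrate(config, outdir),
      go = stage_go(config, outdir),
      classify = stage_classify(config, outdir)
    )
  }
  invisible(out)
}
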