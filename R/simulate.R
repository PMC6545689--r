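#' Configuration for the synthetic methylation study generator
#'
#' Collects every knob of the synthetic cohort in one validated list. The
#' defaults emulate the discovery design: 17 long-term (LTS) vs 12 short-term
#' (STS) survivors, 5000 probes of which 250 are planted hypermethylated
#' inside CpG islands and 250 hypomethylated in the open sea with a mean
#' group difference of 0.25 beta, a latent batch factor shared by negative
#' controls and a random subset of target probes, and a type-II chemistry
#' compression toward 0.5.
#'
#' @param seed Integer RNG seed; the same config and seed give identical
#'   output.
#' @param n_lts,n_sts Group sample sizes.
#' @param n_probes Total target probes (negative controls are extra).
#' @param frac_type2 Fraction of probes using the type-II assay.
#' @param n_neg_controls Number of negative-control probes.
#' @param n_hyper_island,n_hypo_opensea Planted differential site counts.
#' @param delta_beta Planted mean group difference in beta (LTS - STS is
#'   `+delta_beta` at hyper sites and `-delta_beta` at hypo sites).
#' @param batch_strength Scale of the latent unwanted-variation factor.
#' @param type2_shift Compression of type-II betas toward 0.5 (0 = none).
#' @param mutation_rate Average somatic mutations per sample.
#' @param mutation_beta_coupling Strength of the preference for placing
#'   mutations in samples with high beta at planted hypo sites (0 = off).
#' @param expression_coupling Strength of the negative promoter-methylation /
#'   expression coupling for genes linked to planted hyper sites.
#' @param expression_noise_sd Noise SD on log2(FPKM + 1).
#' @param beta_precision Precision of the Beta-distributed probe noise
#'   (larger = tighter around the group mean).
#' @param det_fail_rate,bead_fail_rate Per-entry rates of failed-detection
#'   intensities and low bead counts.
#' @param frac_sex,frac_noncpg,frac_snp,frac_multi Fractions of probes
#'   planted on sex chromosomes or flagged non-CpG / SNP / multi-mapped.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_lts = 17, n_sts = 12, n_probes = 5000,
                       frac_type2 = 0.7, n_neg_controls = 500,
                       n_hyper_island = 250, n_hypo_opensea = 250,
                       delta_beta = 0.25, batch_strength = 0.5,
                       type2_shift = 0.1, mutation_rate = 80,
                       mutation_beta_coupling = 2,
                       expression_coupling = 1, expression_noise_sd = 0.5,
                       beta_precision = 50,
                       det_fail_rate = 0.002, bead_fail_rate = 0.002,
                       frac_sex = 0.01, frac_noncpg = 0.01, frac_snp = 0.01,
                       frac_multi = 0.005) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_probes >= 0, cfg$n_lts >= 0, cfg$n_sts >= 0,
            cfg$delta_beta >= 0, cfg$delta_beta < 1,
            cfg$frac_type2 >= 0, cfg$frac_type2 <= 1,
            cfg$beta_precision > 0)
  n_sex <- round(cfg$frac_sex * cfg$n_probes)
  if (cfg$n_hyper_island + cfg$n_hypo_opensea + n_sex > cfg$n_probes) {
    stop("infeasible counts: planted + sex probes exceed n_probes")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate the synthetic genome, probe manifest and ground truth
#'
#' Builds chromosome sizes, non-overlapping CpG islands, gene models (TSS,
#' strand, first exon), histone-mark interval sets for the 12 canonical marks
#' across 3 synthetic cells, synthetic gene-set terms, the probe manifest and
#' the planted-truth table. H3K27ac intervals preferentially cover planted
#' hyper-island sites and H3K9me3 intervals the planted hypo-open-sea sites,
#' so mark-enrichment recovery is testable downstream.
#'
#' @param config A [sim_config()].
#' @return A list: `chrom_sizes`, `cgis`, `genes`, `marks`, `terms`,
#'   `term_desc`, `manifest`, `truth` (per-probe flags and per-gene coupling).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  marks12 <- c("H2az", "H3K27ac", "H3K27me3", "H3K36me3", "H3K4me1",
               "H3K4me2", "H3K4me3", "H3K79me2", "H3K9ac", "H3K9me1",
               "H3K9me3", "H4K20me1")
  autosomes <- paste0("chr", 1:4)
  chrom_sizes <- c(stats::setNames(rep(30e6, 4), autosomes),
                   chrX = 10e6, chrY = 10e6)

  empty <- function(...) data.frame(..., stringsAsFactors = FALSE)[0, , drop = FALSE]
  if (config$n_probes == 0L) {
    return(list(
      chrom_sizes = chrom_sizes,
      cgis = empty(chrom = character(1), start = integer(1), end = integer(1)),
      genes = empty(gene_id = character(1), chrom = character(1),
                    start = integer(1), end = integer(1), strand = character(1),
                    tss = integer(1), fe_start = integer(1), fe_end = integer(1)),
      marks = empty(mark = character(1), cell = character(1),
                    chrom = character(1), start = integer(1), end = integer(1)),
      terms = empty(term_id = character(1), gene_id = character(1)),
      term_desc = empty(term_id = character(1), description = character(1)),
      manifest = empty(probe_id = character(1), chrom = character(1),
                       pos = integer(1), assay_type = character(1),
                       is_negative_control = logical(1), is_cpg = logical(1),
                       is_snp = logical(1), is_multimapped = logical(1)),
      truth = list(probes = empty(probe_id = character(1),
                                  planted_hyper = logical(1),
                                  planted_hypo = logical(1),
                                  mutation_coupled = logical(1),
                                  sim_context = character(1)),
                   genes = empty(gene_id = character(1),
                                 source_probe = character(1),
                                 expression_coupled = logical(1)))
    ))
  }

  # --- CpG islands: widely spaced so shore/shelf bands never collide -------
  n_cgi_per <- max(8L, ceiling(config$n_probes / length(autosomes) / 12))
  cgis <- do.call(rbind, lapply(autosomes, function(ch) {
    gaps <- round(stats::runif(n_cgi_per, 14000, 40000))
    widths <- round(stats::runif(n_cgi_per, 600, 1800))
    starts <- cumsum(gaps) + cumsum(c(0, widths[-n_cgi_per]))
    data.frame(chrom = ch, start = starts, end = starts + widths,
               stringsAsFactors = FALSE)
  }))
  cgis <- cgis[cgis$end < 30e6 - 20000, ]

  pick_rows <- function(n) sample(nrow(cgis), n, replace = n > nrow(cgis))

  # --- planted probes ------------------------------------------------------
  hyper_cgi <- pick_rows(config$n_hyper_island)
  hyper <- data.frame(
    chrom = cgis$chrom[hyper_cgi],
    pos = round(stats::runif(config$n_hyper_island,
                             cgis$start[hyper_cgi] + 1,
                             cgis$end[hyper_cgi] - 2)),
    sim_context = rep("island_planted", config$n_hyper_island),
    stringsAsFactors = FALSE
  )
  opensea_pos <- function(n) {
    # mid-gap positions, > 4 kb from the flanking islands
    i <- pick_rows(n)
    off <- round(stats::runif(n, 4500, 8000))
    data.frame(chrom = cgis$chrom[i], pos = cgis$end[i] + off,
               stringsAsFactors = FALSE)
  }
  hypo <- opensea_pos(config$n_hypo_opensea)
  hypo$sim_context <- rep("opensea_planted", config$n_hypo_opensea)

  # --- background probes across all CGI contexts ---------------------------
  n_sex <- round(config$frac_sex * config$n_probes)
  n_bg <- config$n_probes - config$n_hyper_island - config$n_hypo_opensea - n_sex
  if (n_bg > 0L) {
    ctx <- sample(c("island", "shore", "shelf", "opensea"), n_bg,
                  replace = TRUE, prob = c(0.25, 0.25, 0.10, 0.40))
    i <- sample(nrow(cgis), n_bg, replace = TRUE)
    left <- stats::runif(n_bg) < 0.5
    off <- integer(n_bg)
    off[ctx == "shore"] <- sample(1:2000, sum(ctx == "shore"), replace = TRUE)
    off[ctx == "shelf"] <- sample(2001:4000, sum(ctx == "shelf"), replace = TRUE)
    off[ctx == "opensea"] <- sample(4500:8000, sum(ctx == "opensea"),
                                    replace = TRUE)
    pos <- ifelse(ctx == "island",
                  round(stats::runif(n_bg, cgis$start[i] + 1, cgis$end[i] - 2)),
                  ifelse(ctx == "opensea", cgis$end[i] + off,
                         ifelse(left, cgis$start[i] - off,
                                cgis$end[i] - 1 + off)))
    bg <- data.frame(chrom = cgis$chrom[i], pos = pos, sim_context = ctx,
                     stringsAsFactors = FALSE)
  } else {
    bg <- hyper[0, ]
  }
  sex <- data.frame(
    chrom = sample(c("chrX", "chrY"), n_sex, replace = TRUE, prob = c(0.8, 0.2)),
    pos = round(stats::runif(n_sex, 1e5, 9e6)),
    sim_context = rep("sex", n_sex), stringsAsFactors = FALSE
  )

  probes <- rbind(hyper, hypo, bg, sex)
  n_t <- nrow(probes)
  probes$probe_id <- sprintf("cg%06d", seq_len(n_t))
  planted_hyper <- seq_len(n_t) <= config$n_hyper_island
  planted_hypo <- seq_len(n_t) > config$n_hyper_island &
    seq_len(n_t) <= config$n_hyper_island + config$n_hypo_opensea

  # quality flags live on non-planted autosomal probes only
  bg_idx <- which(!planted_hyper & !planted_hypo & probes$sim_context != "sex")
  flag_subset <- function(frac) {
    n <- min(length(bg_idx), round(frac * config$n_probes))
    sample(bg_idx, n)
  }
  is_noncpg <- is_snp <- is_multi <- rep(FALSE, n_t)
  is_noncpg[flag_subset(config$frac_noncpg)] <- TRUE
  is_snp[flag_subset(config$frac_snp)] <- TRUE
  is_multi[flag_subset(config$frac_multi)] <- TRUE

  manifest <- data.frame(
    probe_id = probes$probe_id, chrom = probes$chrom, pos = probes$pos,
    assay_type = sample(c("II", "I"), n_t, replace = TRUE,
                        prob = c(config$frac_type2, 1 - config$frac_type2)),
    is_negative_control = FALSE, is_cpg = !is_noncpg, is_snp = is_snp,
    is_multimapped = is_multi, stringsAsFactors = FALSE
  )
  if (config$n_neg_controls > 0L) {
    manifest <- rbind(manifest, data.frame(
      probe_id = sprintf("neg%04d", seq_len(config$n_neg_controls)),
      chrom = NA_character_, pos = NA_integer_, assay_type = "II",
      is_negative_control = TRUE, is_cpg = TRUE, is_snp = FALSE,
      is_multimapped = FALSE, stringsAsFactors = FALSE
    ))
  }

  # --- gene models: promoters over planted hyper sites, plus background ----
  hyper_probes <- probes[planted_hyper, , drop = FALSE]
  coupled_genes <- if (nrow(hyper_probes) > 0L) data.frame(
    chrom = hyper_probes$chrom, tss = hyper_probes$pos + 100, strand = "+",
    source_probe = hyper_probes$probe_id, expression_coupled = TRUE,
    stringsAsFactors = FALSE
  ) else NULL
  n_bg_gene <- max(20L, ceiling(config$n_probes / 15))
  bg_anchor <- if (length(bg_idx)) sample(bg_idx, min(n_bg_gene, length(bg_idx)))
               else integer(0)
  bg_genes <- if (length(bg_anchor)) data.frame(
    chrom = probes$chrom[bg_anchor],
    tss = probes$pos[bg_anchor] + sample(c(-400:-100, 100:400),
                                         length(bg_anchor), replace = TRUE),
    strand = sample(c("+", "-"), length(bg_anchor), replace = TRUE),
    source_probe = probes$probe_id[bg_anchor], expression_coupled = FALSE,
    stringsAsFactors = FALSE
  ) else NULL
  genes <- rbind(coupled_genes, bg_genes)
  if (is.null(genes) || nrow(genes) == 0L) {
    genes <- data.frame(gene_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), tss = integer(0),
                        fe_start = integer(0), fe_end = integer(0),
                        stringsAsFactors = FALSE)
    gene_truth <- data.frame(gene_id = character(0), source_probe = character(0),
                             expression_coupled = logical(0),
                             stringsAsFactors = FALSE)
  } else {
    genes$gene_id <- sprintf("G%05d", seq_len(nrow(genes)))
    len <- round(stats::runif(nrow(genes), 4000, 9000))
    genes$start <- ifelse(genes$strand == "+", genes$tss, genes$tss - len)
    genes$end <- ifelse(genes$strand == "+", genes$tss + len, genes$tss + 1)
    genes$fe_start <- ifelse(genes$strand == "+", genes$tss, genes$tss - 300)
    genes$fe_end <- ifelse(genes$strand == "+", genes$tss + 300, genes$tss + 1)
    gene_truth <- genes[, c("gene_id", "source_probe", "expression_coupled")]
    genes <- genes[, c("gene_id", "chrom", "start", "end", "strand",
                       "tss", "fe_start", "fe_end")]
  }

  # --- synthetic gene-set terms (biological-process-like, flat sets) -------
  terms <- term_desc <- NULL
  if (nrow(genes) > 0L) {
    coupled_ids <- gene_truth$gene_id[gene_truth$expression_coupled]
    other_ids <- setdiff(genes$gene_id, coupled_ids)
    term_list <- list()
    if (length(coupled_ids) >= 5L) {
      term_list[["T0001"]] <- c(
        sample(coupled_ids, ceiling(0.6 * min(length(coupled_ids), 50))),
        sample(other_ids, min(10L, length(other_ids)))
      )
    }
    for (k in seq_len(29L)) {
      sz <- sample(8:60, 1L)
      term_list[[sprintf("T%04d", k + 1L)]] <-
        sample(genes$gene_id, min(sz, nrow(genes)))
    }
    terms <- do.call(rbind, lapply(names(term_list), function(id) {
      data.frame(term_id = id, gene_id = unique(term_list[[id]]),
                 stringsAsFactors = FALSE)
    }))
    term_desc <- data.frame(term_id = names(term_list),
                            description = paste("synthetic process",
                                                names(term_list)),
                            stringsAsFactors = FALSE)
  }

  # --- histone-mark intervals ---------------------------------------------
  cells <- paste0("C", 1:3)
  mark_frac <- stats::setNames(stats::runif(12, 0.10, 0.20), marks12)
  all_pos <- probes[probes$sim_context != "sex", c("chrom", "pos")]
  marks <- do.call(rbind, lapply(marks12, function(mk) {
    base <- all_pos[stats::runif(nrow(all_pos)) < mark_frac[[mk]], , drop = FALSE]
    if (mk == "H3K27ac" && nrow(hyper_probes) > 0L) {
      extra <- hyper_probes[stats::runif(nrow(hyper_probes)) < 0.7,
                            c("chrom", "pos"), drop = FALSE]
      base <- rbind(base, extra)
    }
    if (mk == "H3K9me3" && sum(planted_hypo) > 0L) {
      hp <- probes[planted_hypo, , drop = FALSE]
      extra <- hp[stats::runif(nrow(hp)) < 0.7, c("chrom", "pos"), drop = FALSE]
      base <- rbind(base, extra)
    }
    if (nrow(base) == 0L) return(NULL)
    do.call(rbind, lapply(cells, function(cl) {
      keep <- stats::runif(nrow(base)) < 0.85
      b <- base[keep, , drop = FALSE]
      data.frame(mark = mk, cell = cl, chrom = b$chrom,
                 start = pmax(b$pos - 500, 0), end = b$pos + 500,
                 stringsAsFactors = FALSE)
    }))
  }))

  truth_probes <- data.frame(
    probe_id = probes$probe_id,
    planted_hyper = planted_hyper, planted_hypo = planted_hypo,
    mutation_coupled = planted_hypo & config$mutation_beta_coupling > 0,
    sim_context = probes$sim_context, stringsAsFactors = FALSE
  )

  list(chrom_sizes = chrom_sizes, cgis = cgis, genes = genes, marks = marks,
       terms = terms, term_desc = term_desc, manifest = manifest,
       truth = list(probes = truth_probes, genes = gene_truth))
}

#' Simulate raw probe intensities, bead counts and negative controls
#'
#' Draws Beta-distributed per-probe betas around group means (planted sites
#' shifted by `delta_beta` in the planted direction), applies the type-II
#' chemistry compression, injects a latent batch factor that loads on the
#' negative controls and a random 30% of target probes, converts betas to
#' methylated/unmethylated intensities, and plants failed-detection entries
#' and low bead counts at the configured rates.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @return A list: target `M`, `U`, `beads` matrices, negative-control
#'   `neg_M`, `neg_U`, `neg_beads`, `labels` (`sample_id`, `group`), and the
#'   latent `batch` scores (diagnostic truth).
#' @export
simulate_intensities <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_lts + config$n_sts
  if (n == 0L) stop("no samples configured")
  labels <- data.frame(
    sample_id = c(sprintf("LTS%02d", seq_len(config$n_lts)),
                  sprintf("STS%02d", seq_len(config$n_sts))),
    group = rep(c("LTS", "STS"), c(config$n_lts, config$n_sts)),
    stringsAsFactors = FALSE
  )
  man <- genome$manifest
  tgt <- man[!man$is_negative_control, , drop = FALSE]
  tp <- genome$truth$probes
  n_p <- nrow(tgt)

  base_mean <- function(ctx) switch(ctx,
    island = stats::runif(1, 0.05, 0.25),
    island_planted = 0.15,
    shore = stats::runif(1, 0.20, 0.50),
    shelf = stats::runif(1, 0.40, 0.70),
    opensea = stats::runif(1, 0.55, 0.85),
    opensea_planted = 0.65,
    sex = stats::runif(1, 0.20, 0.80)
  )
  m_sts <- vapply(tp$sim_context, base_mean, numeric(1))
  m_lts <- m_sts +
    ifelse(tp$planted_hyper, config$delta_beta,
           ifelse(tp$planted_hypo, -config$delta_beta, 0))
  m_sts <- pmin(pmax(m_sts, 0.02), 0.98)
  m_lts <- pmin(pmax(m_lts, 0.02), 0.98)

  batch <- stats::rnorm(n) * config$batch_strength
  loads <- rep(0, n_p)
  loaded <- stats::runif(n_p) < 0.30
  loads[loaded] <- stats::rnorm(sum(loaded), 0.7, 0.2)

  mgrp <- ifelse(rep(labels$group, each = n_p) == "LTS", m_lts, m_sts)
  mu <- stats::plogis(stats::qlogis(mgrp) + outer(loads, batch)[seq_len(n_p * n)])
  mu <- matrix(mu, n_p, n)
  phi <- config$beta_precision
  beta_true <- matrix(stats::rbeta(n_p * n, mu * phi, (1 - mu) * phi), n_p, n)

  is2 <- tgt$assay_type == "II"
  beta_obs <- beta_true
  beta_obs[is2, ] <- 0.5 + (beta_true[is2, ] - 0.5) * (1 - config$type2_shift)

  tot <- matrix(stats::rlnorm(n_p * n, log(4000), 0.3), n_p, n)
  fail <- matrix(stats::runif(n_p * n) < config$det_fail_rate, n_p, n)
  tot[fail] <- stats::rlnorm(sum(fail), log(150), 0.3)
  M <- round(beta_obs * (tot + 100))
  M <- pmin(M, round(tot))
  U <- round(tot) - M
  beads <- matrix(4L + stats::rpois(n_p * n, 8), n_p, n)
  bfail <- matrix(stats::runif(n_p * n) < config$bead_fail_rate, n_p, n)
  beads[bfail] <- sample(0:2, sum(bfail), replace = TRUE)
  dimnames(M) <- dimnames(U) <- dimnames(beads) <-
    list(tgt$probe_id, labels$sample_id)

  n_c <- config$n_neg_controls
  if (n_c > 0L) {
    ctl_load <- stats::rnorm(n_c, 0.7, 0.2)
    tot_c <- matrix(stats::rlnorm(n_c * n, log(150), 0.3), n_c, n)
    frac_c <- stats::plogis(outer(ctl_load, batch) +
                              matrix(stats::rnorm(n_c * n, 0, 0.3), n_c, n))
    neg_M <- round(frac_c * tot_c)
    neg_U <- round(tot_c) - neg_M
    neg_beads <- matrix(4L + stats::rpois(n_c * n, 8), n_c, n)
    ctl_ids <- man$probe_id[man$is_negative_control]
    dimnames(neg_M) <- dimnames(neg_U) <- dimnames(neg_beads) <-
      list(ctl_ids, labels$sample_id)
  } else {
    neg_M <- neg_U <- neg_beads <- NULL
  }

  list(M = M, U = U, beads = beads, neg_M = neg_M, neg_U = neg_U,
       neg_beads = neg_beads, labels = labels, batch = batch)
}

#' Simulate coupled gene expression and somatic mutations
#'
#' Genes linked to planted hyper-island promoter sites get
#' `log2(FPKM + 1) = 5 - 4 * expression_coupling * beta + noise`, so their
#' expression is negatively correlated with the promoter site's methylation
#' (exactly affine, r = -1, when the noise SD is 0 and coupling is 1).
#' Mutations are placed within +/- 4 kb of probe sites: half near planted
#' hypo-open-sea sites preferentially in samples where that site's beta is
#' high (softmax over `mutation_beta_coupling` times the site z-score), the
#' rest uniformly over probes and samples.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @param betas Target-probe beta matrix (probes x samples) used to couple
#'   expression and mutation placement to realized methylation.
#' @param labels Sample table from [simulate_intensities()].
#' @return A list: `fpkm` (genes x samples) and `mutations`
#'   (`sample_id`, `chrom`, `pos`, `ref`, `alt`).
#' @export
simulate_expression_and_mutations <- function(config, genome, betas, labels) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- nrow(labels)
  gt <- genome$truth$genes
  genes <- genome$genes
  nt <- c("A", "C", "G", "T")

  fpkm <- NULL
  if (nrow(genes) > 0L) {
    x <- matrix(NA_real_, nrow(genes), n,
                dimnames = list(genes$gene_id, labels$sample_id))
    for (i in seq_len(nrow(genes))) {
      src <- gt$source_probe[match(genes$gene_id[i], gt$gene_id)]
      if (isTRUE(gt$expression_coupled[match(genes$gene_id[i], gt$gene_id)]) &&
          src %in% rownames(betas)) {
        x[i, ] <- 5 - 4 * config$expression_coupling * betas[src, ] +
          stats::rnorm(n, 0, config$expression_noise_sd)
      } else {
        x[i, ] <- stats::runif(1, 1, 6) + stats::rnorm(n, 0, 0.8)
      }
    }
    fpkm <- pmax(2^x - 1, 0)
  }

  tp <- genome$truth$probes
  man <- genome$manifest
  tgt <- man[!man$is_negative_control, , drop = FALSE]
  hypo_ids <- tp$probe_id[tp$planted_hypo]
  total <- round(config$mutation_rate * n)
  coupled_on <- config$mutation_beta_coupling > 0 && length(hypo_ids) > 0L
  n_coupled <- if (coupled_on) round(0.5 * total) else 0L
  n_unif <- total - n_coupled

  rows <- list()
  if (n_coupled > 0L) {
    z <- t(scale(t(betas[hypo_ids, , drop = FALSE])))
    z[!is.finite(z)] <- 0
    site <- sample(length(hypo_ids), n_coupled, replace = TRUE)
    smp <- vapply(site, function(s) {
      w <- exp(config$mutation_beta_coupling * z[s, ])
      sample.int(n, 1L, prob = w)
    }, integer(1))
    p <- tgt$pos[match(hypo_ids[site], tgt$probe_id)]
    rows$coupled <- data.frame(
      sample_id = labels$sample_id[smp],
      chrom = tgt$chrom[match(hypo_ids[site], tgt$probe_id)],
      pos = p + sample(-4000:4000, n_coupled, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  if (n_unif > 0L && nrow(tgt) > 0L) {
    site <- sample(nrow(tgt), n_unif, replace = TRUE)
    rows$uniform <- data.frame(
      sample_id = labels$sample_id[sample.int(n, n_unif, replace = TRUE)],
      chrom = tgt$chrom[site],
      pos = tgt$pos[site] + sample(-4000:4000, n_unif, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  mutations <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), chrom = character(0),
               pos = integer(0), stringsAsFactors = FALSE)
  rownames(mutations) <- NULL
  if (nrow(mutations) > 0L) {
    mutations$ref <- sample(nt, nrow(mutations), replace = TRUE)
    mutations$alt <- vapply(mutations$ref,
                            function(r) sample(setdiff(nt, r), 1L),
                            character(1))
  } else {
    mutations$ref <- character(0)
    mutations$alt <- character(0)
  }
  list(fpkm = fpkm, mutations = mutations)
}

#' Simulate a complete synthetic methylation study
#'
#' Chains [simulate_genome()], [simulate_intensities()] (with raw betas via
#' [compute_beta()]) and [simulate_expression_and_mutations()] from one seed.
#'
#' @param config A [sim_config()].
#' @return A list with all generator outputs plus `beta_raw` (target probes)
#'   and `neg_beta` (negative-control rows).
#' @export
simulate_study <- function(config) {
  genome <- simulate_genome(config)
  if (config$n_probes == 0L) {
    return(list(config = config, genome = genome))
  }
  intens <- simulate_intensities(config, genome)
  beta_raw <- compute_beta(intens$M, intens$U)
  neg_beta <- if (!is.null(intens$neg_M)) compute_beta(intens$neg_M, intens$neg_U)
  em <- simulate_expression_and_mutations(config, genome, beta_raw,
                                          intens$labels)
  c(list(config = config, genome = genome, beta_raw = beta_raw,
         neg_beta = neg_beta),
    intens, em)
}

#' Write a simulated study to plain-text artifacts
#'
#' Emits manifest, intensity, bead, beta, label, FPKM, mutation and truth
#' TSVs, CGI and per-mark/per-cell BED files, gene models, term tables and
#' the configuration as JSON, all with deterministic formatting.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- study$genome
  write_tsv(g$manifest, file.path(dir, "manifest.tsv"))
  write_bed(g$cgis, file.path(dir, "cgis.bed"))
  write_tsv(g$genes, file.path(dir, "genes.tsv"))
  write_tsv(g$truth$probes, file.path(dir, "truth_probes.tsv"))
  write_tsv(g$truth$genes, file.path(dir, "truth_genes.tsv"))
  if (!is.null(g$terms)) {
    write_tsv(g$terms, file.path(dir, "terms.tsv"))
    write_tsv(g$term_desc, file.path(dir, "term_desc.tsv"))
  }
  if (!is.null(g$marks)) {
    for (mk in unique(g$marks$mark)) {
      for (cl in unique(g$marks$cell)) {
        sub <- g$marks[g$marks$mark == mk & g$marks$cell == cl, ]
        write_bed(sub, file.path(dir, "marks", paste0(mk, "_", cl, ".bed")))
      }
    }
  }
  if (!is.null(study$M)) {
    write_matrix_tsv(study$M, file.path(dir, "intensity_M.tsv"))
    write_matrix_tsv(study$U, file.path(dir, "intensity_U.tsv"))
    write_matrix_tsv(study$beads, file.path(dir, "beads.tsv"))
    write_matrix_tsv(study$beta_raw, file.path(dir, "beta_raw.tsv"))
    write_tsv(study$labels, file.path(dir, "labels.tsv"))
    if (!is.null(study$neg_M)) {
      write_matrix_tsv(study$neg_M, file.path(dir, "neg_M.tsv"))
      write_matrix_tsv(study$neg_U, file.path(dir, "neg_U.tsv"))
    }
    if (!is.null(study$fpkm)) {
      write_matrix_tsv(study$fpkm, file.path(dir, "fpkm.tsv"), id_col = "gene_id")
    }
    write_tsv(study$mutations, file.path(dir, "mutations.tsv"))
  }
  cfg <- unclass(study$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
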