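#' Merge overlapping genomic intervals
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return A `data.frame` of disjoint, sorted intervals covering the same
#'   bases.
#' @export
merge_intervals <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  out <- lapply(split(intervals, intervals$chrom), function(x) {
    x <- x[order(x$start, x$end), , drop = FALSE]
    s <- x$start; e <- x$end
    keep_s <- s[1]; keep_e <- e[1]
    for (i in seq_len(nrow(x))[-1]) {
      if (s[i] <= keep_e[length(keep_e)]) {
        keep_e[length(keep_e)] <- max(keep_e[length(keep_e)], e[i])
      } else {
        keep_s <- c(keep_s, s[i]); keep_e <- c(keep_e, e[i])
      }
    }
    data.frame(chrom = x$chrom[1], start = keep_s, end = keep_e,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Test whether point positions fall inside an interval set
#'
#' @param chrom,pos Vectors of point chromosomes and positions.
#' @param intervals `data.frame` with `chrom`, `start`, `end`; overlapping
#'   intervals are merged internally.
#' @return Logical vector: `TRUE` where `pos` lies in `[start, end)` of some
#'   interval on the same chromosome.
#' @export
points_in_intervals <- function(chrom, pos, intervals) {
  iv <- merge_intervals(intervals)
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0L) next
    idx <- findInterval(pos[i], sub$start)
    out[i] <- idx >= 1L & pos[i] < sub$end[pmax(idx, 1L)]
  }
  out
}

#' Histone-mark enrichment of signature vs insignificant sites
#'
#' For each mark, the enrichment proportion of a site set is the fraction of
#' its sites overlapping at least one interval of that mark. By default a
#' site "has" a mark if any cell shows it (union across cells); per-cell
#' proportions are also reported as a min--max range. The difference
#' `proportion(sig) - proportion(insig)` lies in `[-1, 1]`, and the sig-set
#' proportion is additionally binned into quarters (`0-0.25`, `0.25-0.5`,
#' `0.5-0.75`, `0.75-1`).
#'
#' @param sig_sites,insig_sites `data.frame`s with `chrom`, `pos` for the
#'   two (non-empty) site sets.
#' @param marks `data.frame` with `mark`, `cell`, `chrom`, `start`, `end`.
#' @return A `data.frame` per mark: `mark`, `prop_sig`, `prop_insig`,
#'   `difference`, `prop_bin`, `prop_sig_min`, `prop_sig_max` (per-cell
#'   range).
#' @export
enrichment_profile <- function(sig_sites, insig_sites, marks) {
  stopifnot(nrow(sig_sites) > 0L, nrow(insig_sites) > 0L)
  bins <- c("0-0.25", "0.25-0.5", "0.5-0.75", "0.75-1")
  out <- lapply(unique(marks$mark), function(mk) {
    mv <- marks[marks$mark == mk, , drop = FALSE]
    if (nrow(mv) == 0L) {
      ps <- pi_ <- 0; rng <- c(0, 0)
    } else {
      ps <- mean(points_in_intervals(sig_sites$chrom, sig_sites$pos, mv))
      pi_ <- mean(points_in_intervals(insig_sites$chrom, insig_sites$pos, mv))
      per_cell <- vapply(unique(mv$cell), function(cl) {
        mean(points_in_intervals(sig_sites$chrom, sig_sites$pos,
                                 mv[mv$cell == cl, , drop = FALSE]))
      }, numeric(1))
      rng <- range(per_cell)
    }
    data.frame(mark = mk, prop_sig = ps, prop_insig = pi_,
               difference = ps - pi_,
               prop_bin = bins[pmin(floor(ps * 4) + 1L, 4L)],
               prop_sig_min = rng[1], prop_sig_max = rng[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-gene maximum methylation--expression correlation
#'
#' Computes the Pearson correlation between each site's beta and
#' `log2(FPKM + 1)` of its assigned gene across shared samples, after
#' dropping sites with beta SD <= `sd_min` and genes with mean FPKM <= 0.
#' When several sites map to one gene, the maximum (signed) correlation is
#' assigned to the gene.
#'
#' @param betas Probes-by-samples beta matrix.
#' @param fpkm Genes-by-samples FPKM matrix.
#' @param probe_gene `data.frame` with `probe_id`, `gene` linking sites to
#'   genes.
#' @param sd_min Minimum beta SD for a site to be considered (default 0.1,
#'   strict: SD must exceed it).
#' @return A `data.frame` with `gene`, `r` (max over the gene's surviving
#'   sites), `n_sites`.
#' @export
methylation_expression_correlation <- function(betas, fpkm, probe_gene,
                                               sd_min = 0.1) {
  shared <- intersect(colnames(betas), colnames(fpkm))
  if (length(shared) < 3L) stop("fewer than 3 shared samples")
  b <- betas[, shared, drop = FALSE]
  ex <- log2(fpkm[, shared, drop = FALSE] + 1)

  pg <- probe_gene[!is.na(probe_gene$gene) &
                     probe_gene$probe_id %in% rownames(b) &
                     probe_gene$gene %in% rownames(fpkm), , drop = FALSE]
  sds <- apply(b, 1L, stats::sd)
  pg <- pg[sds[pg$probe_id] > sd_min, , drop = FALSE]
  gene_mean <- rowMeans(fpkm[, shared, drop = FALSE])
  pg <- pg[gene_mean[pg$gene] > 0, , drop = FALSE]
  if (nrow(pg) == 0L) {
    return(data.frame(gene = character(0), r = numeric(0),
                      n_sites = integer(0), stringsAsFactors = FALSE))
  }
  r <- vapply(seq_len(nrow(pg)), function(i) {
    stats::cor(b[pg$probe_id[i], ], ex[pg$gene[i], ])
  }, numeric(1))
  agg <- tapply(r, pg$gene, max, na.rm = TRUE)
  cnt <- tapply(r, pg$gene, length)
  data.frame(gene = names(agg), r = as.numeric(agg),
             n_sites = as.integer(cnt), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Mutation-proximal methylation z-scores and KS comparison
#'
#' For every (site, sample) pair where the sample carries a somatic mutation
#' within `window` bp of the site (inclusive at exactly `window`), records
#' the sample's beta at that site and its z-score (sample beta minus the
#' across-sample mean, over the across-sample SD at that site; each pair
#' counted once regardless of how many nearby mutations the sample has).
#' The z-score distributions of `site_set` and `background_set` are compared
#' by a two-sample Kolmogorov--Smirnov test.
#'
#' @param mutations `data.frame` with `sample_id`, `chrom`, `pos`.
#' @param betas Probes-by-samples beta matrix.
#' @param manifest `data.frame` with `probe_id`, `chrom`, `pos` for the
#'   probes in `betas`.
#' @param site_set,background_set Probe-id character vectors.
#' @param window Association half-window in bp (default 5000).
#' @return A list: `pairs` (`probe_id`, `sample_id`, `set`, `beta`, `z`),
#'   `ks` (`htest` from [stats::ks.test()]), `statistic`, `p_value`,
#'   `n_site`, `n_background`, `n_dropped_zero_sd`.
#' @export
mutation_methylation_association <- function(mutations, betas, manifest,
                                             site_set, background_set,
                                             window = 5000) {
  collect_pairs <- function(ids, set_name) {
    m <- manifest[match(ids, manifest$probe_id), , drop = FALSE]
    keep <- !is.na(m$chrom) & m$probe_id %in% rownames(betas)
    m <- m[keep, , drop = FALSE]
    if (nrow(m) == 0L || nrow(mutations) == 0L) {
      return(data.frame(probe_id = character(0), sample_id = character(0),
                        set = character(0), stringsAsFactors = FALSE))
    }
    res <- lapply(unique(m$chrom), function(ch) {
      mm <- m[m$chrom == ch, , drop = FALSE]
      mu <- mutations[mutations$chrom == ch, , drop = FALSE]
      if (nrow(mu) == 0L) return(NULL)
      # all (site, mutation) pairs within the window, one row per pair
      hits <- lapply(seq_len(nrow(mm)), function(i) {
        near <- abs(mu$pos - mm$pos[i]) <= window
        if (!any(near)) return(NULL)
        data.frame(probe_id = mm$probe_id[i],
                   sample_id = unique(mu$sample_id[near]),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, hits)
    })
    res <- do.call(rbind, res)
    if (is.null(res) || nrow(res) == 0L) {
      return(data.frame(probe_id = character(0), sample_id = character(0),
                        set = character(0), stringsAsFactors = FALSE))
    }
    res$set <- set_name
    res
  }
  pairs <- rbind(collect_pairs(site_set, "site"),
                 collect_pairs(background_set, "background"))
  if (nrow(pairs) == 0L) stop("no mutation-proximal (site, sample) pairs")
  pairs <- pairs[pairs$sample_id %in% colnames(betas), , drop = FALSE]

  mu <- rowMeans(betas)
  sds <- apply(betas, 1L, stats::sd)
  zero_sd <- sds[pairs$probe_id] == 0
  n_drop <- sum(zero_sd)
  pairs <- pairs[!zero_sd, , drop = FALSE]
  pairs$beta <- betas[cbind(pairs$probe_id, pairs$sample_id)]
  pairs$z <- (pairs$beta - mu[pairs$probe_id]) / sds[pairs$probe_id]

  z_site <- pairs$z[pairs$set == "site"]
  z_bg <- pairs$z[pairs$set == "background"]
  if (length(z_site) == 0L || length(z_bg) == 0L) {
    stop("one of the two sets has no mutation-proximal pairs")
  }
  ks <- suppressWarnings(stats::ks.test(z_site, z_bg))
  list(pairs = pairs, ks = ks,
       statistic = unname(ks$statistic), p_value = ks$p.value,
       n_site = length(z_site), n_background = length(z_bg),
       n_dropped_zero_sd = n_drop)
}

#' Ordinary-least-squares summary of methylation on a ChIP signal
#'
#' Convenience fit of per-site beta on a per-site signal value, reporting the
#' slope, intercept, p-value of the slope and n.
#'
#' @param beta Numeric vector of per-site methylation values.
#' @param signal Numeric vector of per-site ChIP signal values.
#' @return A one-row `data.frame`: `slope`, `intercept`, `p`, `n`.
#' @export
beta_signal_regression <- function(beta, signal) {
  stopifnot(length(beta) == length(signal))
  fit <- stats::lm(beta ~ signal)
  s <- summary(fit)$coefficients
  data.frame(slope = s["signal", "Estimate"],
             intercept = s["(Intercept)", "Estimate"],
             p = s["signal", "Pr(>|t|)"], n = length(beta),
             stringsAsFactors = FALSE)
}
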