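# Shared fixtures: small synthetic studies built in code, cached per seed so
# several test files can reuse them without re-simulating.

small_config <- function(seed = 1, n_probes = 800, n_hyper_island = 40,
                         n_hypo_opensea = 40, n_neg_controls = 100, ...) {
  sim_config(seed = seed, n_probes = n_probes,
             n_hyper_island = n_hyper_island,
             n_hypo_opensea = n_hypo_opensea,
             n_neg_controls = n_neg_controls, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cache_key <- function(prefix, seed, ...) {
  args <- list(...)
  paste(prefix, seed,
        paste(names(args), unlist(args), sep = "=", collapse = "_"),
        sep = "_")
}

cached_study <- function(seed = 1, ...) {
  key <- cache_key("small", seed, ...)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_study(small_config(seed, ...))
  }
  .fixture_cache[[key]]
}

# discovery run (filters + BMIQ + differential test) on the default-size
# study, reused by the acceptance checks for recovery / signatures / scoring
discovery_run <- function(seed = 1) {
  key <- paste0("disc_", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  st <- simulate_study(sim_config(seed = seed))
  tgt <- st$genome$manifest[!st$genome$manifest$is_negative_control, ]
  detp <- detection_pvalue_matrix(st$M, st$U, st$neg_M, st$neg_U)
  filt <- filter_probes(detp, st$beads, tgt)
  beta <- compute_beta(st$M[filt$keep, , drop = FALSE],
                       st$U[filt$keep, , drop = FALSE])
  at <- tgt$assay_type[match(filt$keep, tgt$probe_id)]
  beta <- bmiq_matrix(beta, at)$betas
  comb <- rbind(beta, compute_beta(st$neg_M, st$neg_U))
  dm <- diff_methylation(comb, st$labels$group,
                         control_idx = rownames(st$neg_M))
  ann <- annotate_probes(st$genome$manifest, st$genome$cgis, st$genome$genes,
                         chroms = c(paste0("chr", 1:4), "chrX", "chrY"))
  sig <- select_signatures(dm, ann)
  out <- list(study = st, beta = beta, dm = dm, ann = ann, sig = sig,
              filt = filt)
  .fixture_cache[[key]] <- out
  out
}

# default-size study (5000 probes, 17+12 samples), cached per seed/overrides
cached_study_default <- function(seed = 1, ...) {
  key <- cache_key("def", seed, ...)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_study(sim_config(seed = seed, ...))
  }
  .fixture_cache[[key]]
}

# KS comparison of mutation-proximal z-scores: planted hypo sites vs the
# non-planted open-sea background, using the generator's own truth table
mutation_ks_for <- function(st) {
  tp <- st$genome$truth$probes
  hypo <- tp$probe_id[tp$planted_hypo]
  bg <- tp$probe_id[!tp$planted_hyper & !tp$planted_hypo &
                      tp$sim_context == "opensea"]
  mutation_methylation_association(st$mutations, st$beta_raw,
                                   st$genome$manifest, hypo, bg)
}

# independent two-group OLS oracle: per-probe t-test of beta on the group
# indicator, written from the closed form rather than via the package path
ols_oracle_p <- function(betas, labels) {
  x <- as.numeric(labels == "LTS")
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  yc <- betas - rowMeans(betas)
  bhat <- as.numeric(yc %*% xc) / sxx
  rss <- rowSums((yc - outer(bhat, xc))^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tt <- bhat / se
  2 * stats::pt(-abs(tt), df = n - 2)
}
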