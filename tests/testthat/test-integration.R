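test_that("interval membership agrees with a brute-force overlap scan", {
  set.seed(31)
  for (rep in 1:20) {
    n_iv <- sample(1:200, 1); n_pt <- sample(1:200, 1)
    iv <- data.frame(
      chrom = sample(c("chr1", "chr2"), n_iv, replace = TRUE),
      start = sample(1:5000, n_iv, replace = TRUE)
    )
    iv$end <- iv$start + sample(1:400, n_iv, replace = TRUE)
    ch <- sample(c("chr1", "chr2", "chr3"), n_pt, replace = TRUE)
    pos <- sample(1:6000, n_pt, replace = TRUE)
    got <- points_in_intervals(ch, pos, iv)
    brute <- vapply(seq_len(n_pt), function(i) {
      any(iv$chrom == ch[i] & pos[i] >= iv$start & pos[i] < iv$end)
    }, logical(1))
    expect_equal(got, brute)
  }
})

test_that("merged intervals are disjoint and cover the same points", {
  iv <- data.frame(chrom = "chr1",
                   start = c(10, 15, 40, 100), end = c(20, 30, 50, 110))
  m <- merge_intervals(iv)
  expect_equal(nrow(m), 3L)
  expect_true(all(m$start[-1] > m$end[-nrow(m)]))
  pts <- 1:120
  expect_equal(points_in_intervals(rep("chr1", 120), pts, iv),
               points_in_intervals(rep("chr1", 120), pts, m))
})

test_that("enrichment differences hit the documented extremes", {
  marks <- data.frame(mark = "H3K27ac", cell = "C1", chrom = "chr1",
                      start = c(100, 500), end = c(200, 600))
  sig <- data.frame(chrom = "chr1", pos = c(150, 550))
  insig <- data.frame(chrom = "chr1", pos = c(1000, 2000))
  prof <- enrichment_profile(sig, insig, marks)
  expect_equal(prof$difference, 1.0)
  expect_equal(prof$prop_bin, "0.75-1")
  # identical sets: difference exactly zero
  prof0 <- enrichment_profile(sig, sig, marks)
  expect_equal(prof0$difference, 0.0)
  # enrichment differences always within [-1, 1]
  expect_true(all(prof$difference >= -1 & prof$difference <= 1))
})

test_that("planted mark co-location is recovered from the generator", {
  st <- cached_study(seed = 1)
  tp <- st$genome$truth$probes
  man <- st$genome$manifest
  locate <- function(ids) {
    i <- match(ids, man$probe_id)
    data.frame(chrom = man$chrom[i], pos = man$pos[i],
               stringsAsFactors = FALSE)
  }
  bg <- tp$probe_id[!tp$planted_hyper & !tp$planted_hypo &
                      tp$sim_context != "sex"]
  prof_hyper <- enrichment_profile(locate(tp$probe_id[tp$planted_hyper]),
                                   locate(bg), st$genome$marks)
  prof_hypo <- enrichment_profile(locate(tp$probe_id[tp$planted_hypo]),
                                  locate(bg), st$genome$marks)
  expect_gt(prof_hyper$difference[prof_hyper$mark == "H3K27ac"], 0.2)
  expect_gt(prof_hypo$difference[prof_hypo$mark == "H3K9me3"], 0.2)
  # per-cell ranges bracket the union proportion from below
  expect_true(all(prof_hyper$prop_sig_min <= prof_hyper$prop_sig + 1e-12))
})

test_that("per-gene correlation takes the maximum over surviving sites", {
  sam <- paste0("s", 1:10)
  beta <- rbind(
    siteA = seq(0.1, 0.9, length.out = 10),   # strongly anticorrelated
    siteB = c(0.2, 0.8, 0.3, 0.7, 0.4, 0.6, 0.5, 0.2, 0.8, 0.3),
    siteC = rep(0.4, 10)                      # zero SD: filtered out
  )
  colnames(beta) <- sam
  ex <- 2^(5 - 4 * beta["siteA", ]) - 1
  fpkm <- rbind(G1 = ex)
  colnames(fpkm) <- sam
  pg <- data.frame(probe_id = c("siteA", "siteB", "siteC"),
                   gene = "G1", stringsAsFactors = FALSE)
  out <- methylation_expression_correlation(beta, fpkm, pg)
  rB <- cor(beta["siteB", ], log2(ex + 1))
  expect_equal(out$r, max(-1, rB))
  expect_equal(out$n_sites, 2L)  # siteC dropped by the SD filter

  # a perfect affine decreasing relation gives r = -1
  out1 <- methylation_expression_correlation(
    beta["siteA", , drop = FALSE], fpkm,
    data.frame(probe_id = "siteA", gene = "G1"))
  expect_equal(out1$r, -1, tolerance = 1e-12)

  expect_error(
    methylation_expression_correlation(beta[, 1:2], fpkm[, 1:2, drop = FALSE],
                                       pg),
    "3 shared samples")
})

test_that("mutation association respects the inclusive 5 kb window", {
  sam <- c("a", "b", "c", "d")
  beta <- matrix(c(0.1, 0.5, 0.9, 0.5,
                   0.2, 0.4, 0.6, 0.8), 2, 4, byrow = TRUE,
                 dimnames = list(c("p1", "p2"), sam))
  man <- data.frame(probe_id = c("p1", "p2"), chrom = "chr1",
                    pos = c(15000, 40000), stringsAsFactors = FALSE)
  muts <- data.frame(sample_id = c("a", "b", "c"), chrom = "chr1",
                     pos = c(10000, 9999, 41000), stringsAsFactors = FALSE)
  out <- mutation_methylation_association(muts, beta, man,
                                          site_set = "p1",
                                          background_set = "p2")
  # distance 5000 is associated, 5001 is not
  expect_setequal(out$pairs$sample_id[out$pairs$set == "site"], "a")
  expect_equal(out$n_site, 1L)
  expect_equal(out$n_background, 1L)
  # z-score of a beta equal to the site mean is 0
  # setting a = mean(b, c, d) makes a equal the across-sample mean exactly
  beta2 <- beta; beta2["p1", "a"] <- mean(beta["p1", c("b", "c", "d")])
  out2 <- mutation_methylation_association(muts, beta2, man, "p1", "p2")
  z_a <- out2$pairs$z[out2$pairs$set == "site"]
  expect_equal(z_a, 0, tolerance = 1e-12)
})

test_that("zero-SD sites are dropped from z-scores with a count", {
  sam <- c("a", "b", "c")
  beta <- matrix(c(0.4, 0.4, 0.4,
                   0.1, 0.5, 0.9,
                   0.2, 0.5, 0.8), 3, 3, byrow = TRUE,
                 dimnames = list(c("flat", "ok", "bg"), sam))
  man <- data.frame(probe_id = c("flat", "ok", "bg"), chrom = "chr1",
                    pos = c(1000, 20000, 40000), stringsAsFactors = FALSE)
  muts <- data.frame(sample_id = c("a", "b", "c"), chrom = "chr1",
                     pos = c(1200, 20200, 40100), stringsAsFactors = FALSE)
  out <- mutation_methylation_association(muts, beta, man,
                                          site_set = c("flat", "ok"),
                                          background_set = "bg")
  expect_equal(out$n_dropped_zero_sd, 1L)  # sample a's pair at 'flat'
  expect_equal(out$n_site, 1L)             # only the 'ok' pair survives
  expect_equal(out$n_background, 1L)
})

test_that("KS statistic vanishes on identical z-score sets", {
  st <- cached_study(seed = 1)
  tp <- st$genome$truth$probes
  hypo <- tp$probe_id[tp$planted_hypo]
  man <- st$genome$manifest
  out <- mutation_methylation_association(st$mutations, st$beta_raw, man,
                                          hypo, hypo)
  expect_equal(out$statistic, 0)
})

test_that("z-scores of a standardized site have mean 0 and sd 1", {
  st <- cached_study(seed = 1)
  b <- st$beta_raw[1, ]
  z <- (b - mean(b)) / sd(b)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("methylation-on-signal regression returns the fitted slope", {
  set.seed(5)
  x <- runif(50)
  y <- 0.2 + 0.3 * x + rnorm(50, 0, 0.01)
  fit <- beta_signal_regression(y, x)
  expect_lt(abs(fit$slope - 0.3), 0.02)
  expect_equal(fit$n, 50L)
})
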