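test_that("BH adjustment matches the hand-worked examples", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.3, 5)), rep(0.3, 5))
  expect_equal(fdr_adjust(0.07), 0.07)
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjustment equals a brute-force step-up oracle", {
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    out <- numeric(n)
    out[o] <- pmin(q, 1)
    out
  }
  set.seed(13)
  for (rep in 1:100) {
    p <- runif(sample(1:200, 1))
    expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("the GLS test recovers planted effects with the right sign", {
  st <- cached_study(seed = 1)
  comb <- rbind(st$beta_raw, st$neg_beta)
  dm <- diff_methylation(comb, st$labels$group,
                         control_idx = rownames(st$neg_beta))
  r <- dm$results
  tp <- st$genome$truth$probes
  hyper <- r[r$probe_id %in% tp$probe_id[tp$planted_hyper], ]
  hypo <- r[r$probe_id %in% tp$probe_id[tp$planted_hypo], ]
  # positive coefficient = hypermethylation in LTS
  expect_gt(mean(hyper$coef > 0), 0.95)
  expect_gt(mean(hypo$coef < 0), 0.95)
  expect_gt(mean(hyper$significant), 0.8)
  expect_gt(mean(hypo$significant), 0.8)
  # q >= p and the significance flag is consistent
  expect_true(all(r$q >= r$p - 1e-12))
  expect_identical(r$significant, r$q < dm$fdr)
  expect_true(all(abs(r$delta) <= 1))
})

test_that("structureless controls reduce the test to ordinary least squares", {
  st <- cached_study(seed = 2, batch_strength = 0)
  comb <- rbind(st$beta_raw, st$neg_beta)
  res <- ruv_inverse_test(comb, st$labels$group, rownames(st$neg_beta))
  p_ols <- ols_oracle_p(st$beta_raw, st$labels$group)
  expect_gt(cor(res$p, p_ols, method = "spearman"), 0.99)
})

test_that("permuted null labels give calibrated p-values", {
  st <- cached_study(seed = 6, delta_beta = 0, n_hyper_island = 0,
                     n_hypo_opensea = 0)
  set.seed(61)
  perm <- sample(st$labels$group)
  comb <- rbind(st$beta_raw, st$neg_beta)
  res <- ruv_inverse_test(comb, perm, rownames(st$neg_beta))
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.025)
})

test_that("degenerate and invalid designs are handled", {
  st <- cached_study(seed = 1)
  comb <- rbind(st$beta_raw, st$neg_beta)
  ctl <- rownames(st$neg_beta)
  # constant probe reports p = 1
  comb2 <- comb
  comb2[1, ] <- 0.5
  res <- ruv_inverse_test(comb2, st$labels$group, ctl)
  expect_equal(res$p[res$probe_id == rownames(comb2)[1]], 1)
  expect_equal(res$stat[res$probe_id == rownames(comb2)[1]], 0)

  expect_error(ruv_inverse_test(comb, st$labels$group, ctl[1:5]),
               "at least 10")
  expect_error(ruv_inverse_test(comb, rep("LTS", ncol(comb)), ctl),
               "3 samples")
  tiny <- comb[, 1:6]
  expect_error(ruv_inverse_test(tiny, c("LTS", "LTS", rep("STS", 4)), ctl),
               "3 samples")
  expect_error(ruv_inverse_test(comb, st$labels$group, ctl,
                                k = length(ctl) + 1), "fewer controls")
})

test_that("signature selection applies strict delta cutoffs by region", {
  res <- data.frame(
    probe_id = c("a", "b", "c", "d", "e", "f"),
    delta = c(0.25, 0.2, -0.3, -0.2, 0.5, 0.3),
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  man <- data.frame(
    probe_id = c("a", "b", "c", "d", "e", "f"),
    cgi_group = c("Island", "Island", "OpenSea", "OpenSea", "Island",
                  "OpenSea"),
    stringsAsFactors = FALSE
  )
  sig <- select_signatures(res, man)
  expect_equal(sig$hyper_island_sites, "a")   # b at exactly 0.2 excluded
  expect_equal(sig$hypo_opensea_sites, "c")   # d at exactly -0.2 excluded
  # e insignificant, f positive in open sea: neither qualifies
  expect_equal(length(intersect(c("e", "f"),
                                unlist(sig[c("hyper_island_sites",
                                             "hypo_opensea_sites")]))), 0L)
})

test_that("category shift summaries recover the planted directions", {
  run <- discovery_run(seed = 1)
  shift <- category_shift_summary(run$dm, run$ann)
  sig_island <- shift[shift$axis == "cgi" & shift$category == "Island" &
                        shift$group == "significant", ]
  sig_open <- shift[shift$axis == "cgi" & shift$category == "OpenSea" &
                      shift$group == "significant", ]
  expect_gt(sig_island$median, 0)
  expect_lt(sig_open$median, 0)
  other <- shift[shift$group == "other" & shift$axis == "cgi", ]
  expect_true(all(abs(other$median) < 0.05))
})
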