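test_that("detection p-values follow the Gaussian background model", {
  # controls constructed to have mean 100 and sd exactly 10
  z <- rep(c(-1, 1), 50)
  neg <- 100 + 10 * z / stats::sd(z)
  expect_equal(detection_pvalue(100, neg), 0.5)
  expect_equal(detection_pvalue(120, neg),
               stats::pnorm(2, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(detection_pvalue(1e9, neg), 1e-12)

  expect_error(detection_pvalue(100, rep(5, 20)), "degenerate")
  expect_error(detection_pvalue(100, rnorm(5, 100, 10)), "at least 10")

  # empirical alternative is the exceedance rank
  expect_equal(detection_pvalue(101, neg, method = "empirical"),
               mean(neg >= 101))
})

test_that("beta values reproduce the offset formula and its monotonicity", {
  expect_equal(compute_beta(0, 0), 0)
  expect_equal(compute_beta(300, 100), 0.6)
  expect_equal(compute_beta(100, 0), 0.5)
  expect_error(compute_beta(-1, 5), "non-negative")

  set.seed(1)
  M <- runif(500, 0, 1e4); U <- runif(500, 0, 1e4)
  b <- compute_beta(M, U)
  expect_true(all(b >= 0 & b <= 1))
  expect_equal(b, M / (M + U + 100))
  # strictly increasing in M, decreasing in U
  expect_true(all(compute_beta(M + 1, U) > b))
  expect_true(all(compute_beta(M, U + 1) < b))
})

test_that("probe filters match a brute-force per-rule oracle", {
  set.seed(11)
  for (rep in 1:30) {
    np <- sample(20:100, 1); ns <- sample(5:30, 1)
    detp <- matrix(runif(np * ns), np, ns)
    beads <- matrix(sample(0:15, np * ns, replace = TRUE), np, ns)
    man <- data.frame(
      probe_id = sprintf("p%03d", seq_len(np)),
      chrom = sample(c("chr1", "chr2", "chrX", "chrY"), np, replace = TRUE,
                     prob = c(0.45, 0.45, 0.05, 0.05)),
      is_cpg = runif(np) > 0.05,
      is_snp = runif(np) < 0.05,
      is_multimapped = runif(np) < 0.05,
      stringsAsFactors = FALSE
    )
    got <- filter_probes(detp, beads, man)

    keep_oracle <- character(0)
    rule_oracle <- c(i = 0L, ii = 0L, iii = 0L, iv = 0L, v = 0L, vi = 0L)
    for (p in seq_len(np)) {
      fired <- c(
        i = sum(detp[p, ] > 0.01) / ns > 0.05,
        ii = sum(beads[p, ] < 3) / ns > 0.05,
        iii = !man$is_cpg[p],
        iv = man$is_snp[p],
        v = man$is_multimapped[p],
        vi = man$chrom[p] %in% c("chrX", "chrY")
      )
      if (!any(fired)) {
        keep_oracle <- c(keep_oracle, man$probe_id[p])
      } else {
        first <- names(fired)[which(fired)[1]]
        rule_oracle[first] <- rule_oracle[first] + 1L
      }
    }
    expect_equal(got$keep, keep_oracle)
    expect_equal(setNames(got$counts$count, got$counts$rule), rule_oracle)
  }
})

test_that("filter inequalities are strict at the printed boundaries", {
  # 20 samples: 1 failing sample is exactly 5% (kept), 2 is 10% (removed)
  man <- data.frame(probe_id = c("a", "b"), chrom = "chr1", is_cpg = TRUE,
                    is_snp = FALSE, is_multimapped = FALSE,
                    stringsAsFactors = FALSE)
  detp <- rbind(c(rep(0.001, 19), 0.5), c(rep(0.001, 18), 0.5, 0.5))
  beads <- matrix(10, 2, 20)
  got <- filter_probes(detp, beads, man)
  expect_equal(got$keep, "a")
  expect_equal(got$removed$rule, "i")
})

test_that("BMIQ reduces the type-II/type-I distribution gap monotonically", {
  st <- cached_study(seed = 1)
  tgt <- st$genome$manifest[!st$genome$manifest$is_negative_control, ]
  at <- tgt$assay_type[match(rownames(st$beta_raw), tgt$probe_id)]
  b <- st$beta_raw[, 1]
  ks <- function(x) suppressWarnings(
    stats::ks.test(x[at == "II"], x[at == "I"])$statistic)
  out <- bmiq_normalize(b, at)
  expect_true(all(out$beta >= 0 & out$beta <= 1))
  # type I untouched
  expect_identical(out$beta[at == "I"], b[at == "I"])
  # monotone map: type-II order is preserved (up to exact ties)
  b2 <- b[at == "II"]; m2 <- out$beta[at == "II"]
  expect_true(all(diff(m2[order(b2)]) >= 0))
  # distribution gap shrinks by at least half
  expect_lt(ks(out$beta), 0.5 * ks(b))
})

test_that("BMIQ is near the identity when the two assay distributions match", {
  set.seed(21)
  pool <- c(rbeta(1500, 2, 10), rbeta(600, 8, 8), rbeta(1400, 10, 2.5))
  at <- rep(c("I", "II"), length.out = length(pool))
  out <- bmiq_normalize(pool, at)
  expect_lt(max(abs(out$beta - pool)), 0.02)
})

test_that("BMIQ is idempotent within tolerance", {
  st <- cached_study(seed = 1)
  tgt <- st$genome$manifest[!st$genome$manifest$is_negative_control, ]
  at <- tgt$assay_type[match(rownames(st$beta_raw), tgt$probe_id)]
  once <- bmiq_normalize(st$beta_raw[, 2], at)$beta
  twice <- bmiq_normalize(once, at)$beta
  expect_lt(max(abs(twice - once)), 0.01)
})

test_that("BMIQ requires both probe types", {
  expect_error(bmiq_normalize(runif(100), rep("II", 100)), "both probe types")
})
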