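test_that("CGI categorization handles inside, shore, shelf and open sea", {
  cgi <- data.frame(start = 1000, end = 2000)
  expect_equal(categorize_cgi(1500, cgi), "Island")
  expect_equal(categorize_cgi(2500, cgi), "S_Shore")   # d = 501
  expect_equal(categorize_cgi(7000, cgi), "OpenSea")   # d = 5001
  # empty CGI set: everything is open sea
  expect_equal(categorize_cgi(c(10, 1e6), cgi[0, ]), c("OpenSea", "OpenSea"))
})

test_that("CGI distance bands are exact at 2000/2001 and 4000/4001", {
  cgi <- data.frame(start = 100000, end = 101000)
  last <- 100999  # last base of the island
  expect_equal(categorize_cgi(last + 2000, cgi), "S_Shore")
  expect_equal(categorize_cgi(last + 2001, cgi), "S_Shelf")
  expect_equal(categorize_cgi(last + 4000, cgi), "S_Shelf")
  expect_equal(categorize_cgi(last + 4001, cgi), "OpenSea")
  expect_equal(categorize_cgi(100000 - 2000, cgi), "N_Shore")
  expect_equal(categorize_cgi(100000 - 2001, cgi), "N_Shelf")
  expect_equal(categorize_cgi(100000 - 4000, cgi), "N_Shelf")
  expect_equal(categorize_cgi(100000 - 4001, cgi), "OpenSea")
})

test_that("the flipped N_/S_ convention swaps only the prefixes", {
  cgi <- data.frame(start = 100000, end = 101000)
  pos <- c(98500, 102500)
  expect_equal(categorize_cgi(pos, cgi), c("N_Shore", "S_Shore"))
  expect_equal(categorize_cgi(pos, cgi, ns_convention = "flipped"),
               c("S_Shore", "N_Shore"))
})

test_that("CGI categorization agrees with a brute-force scan", {
  set.seed(42)
  for (rep in 1:40) {
    n_cgi <- sample(2:10, 1)
    starts <- sort(sample(seq(5000, 5e5, by = 100), n_cgi))
    widths <- sample(200:1500, n_cgi, replace = TRUE)
    # enforce non-overlap
    ends <- starts + widths
    keep <- c(TRUE, starts[-1] > ends[-n_cgi])
    cgi <- data.frame(start = starts[keep], end = ends[keep])
    pos <- sample(seq(1, 6e5), 25)

    brute <- vapply(pos, function(p) {
      inside <- any(p >= cgi$start & p < cgi$end)
      if (inside) return("Island")
      d_each <- pmax(cgi$start - p, p - (cgi$end - 1))
      i <- which.min(d_each)
      # resolve equidistance toward the higher-coordinate island
      cand <- which(d_each == d_each[i])
      i <- cand[length(cand)]
      d <- d_each[i]
      pre <- if (cgi$start[i] > p) "N_" else "S_"
      if (d <= 2000) paste0(pre, "Shore")
      else if (d <= 4000) paste0(pre, "Shelf")
      else "OpenSea"
    }, character(1))
    expect_equal(categorize_cgi(pos, cgi), brute)
  }
})

test_that("TSS categories follow the strand-aware windows and priority", {
  tx_plus <- data.frame(tss = 10000, strand = "+",
                        fe_start = 10000, fe_end = 10300)
  # 100 bp upstream of a + strand TSS
  expect_equal(categorize_tss(9900, tx_plus), "TSS200")
  expect_equal(categorize_tss(9800, tx_plus), "TSS200")   # 200 exactly
  expect_equal(categorize_tss(9799, tx_plus), "TSS1500")  # 201
  expect_equal(categorize_tss(8500, tx_plus), "TSS1500")  # 1500 exactly
  expect_equal(categorize_tss(8499, tx_plus), "Far")      # 1501
  expect_equal(categorize_tss(10100, tx_plus), "FirstExon")
  # far from everything
  expect_equal(categorize_tss(1e6, tx_plus), "Far")
  # empty transcript set
  expect_equal(categorize_tss(10, tx_plus[0, ]), "Far")

  # minus strand: upstream means higher coordinates
  tx_minus <- data.frame(tss = 20000, strand = "-",
                         fe_start = 19700, fe_end = 20001)
  expect_equal(categorize_tss(20100, tx_minus), "TSS200")
  expect_equal(categorize_tss(21000, tx_minus), "TSS1500")
  expect_equal(categorize_tss(19900, tx_minus), "FirstExon")

  # priority: first exon of gene B beats TSS1500 of gene A
  both <- rbind(data.frame(tss = 10000, strand = "+",
                           fe_start = 50000, fe_end = 50300),
                data.frame(tss = 8000, strand = "+",
                           fe_start = 8000, fe_end = 9500))
  expect_equal(categorize_tss(9100, both), "FirstExon")
})

test_that("gene assignment uses promoter windows with documented tie-breaks", {
  genes <- data.frame(gene_id = c("GB", "GA"),
                      start = c(10000, 30000), end = c(20000, 40000),
                      strand = c("+", "+"), stringsAsFactors = FALSE)
  expect_equal(assign_gene(15000, genes), "GB")           # inside body
  expect_equal(assign_gene(9000, genes), "GB")            # promoter window
  expect_true(is.na(assign_gene(25000, genes)))           # between windows
  expect_equal(assign_gene(500, genes[0, ]), NA_character_)

  # equidistant overlap: lexicographically smaller id wins
  twin <- data.frame(gene_id = c("GZ", "GA"),
                     start = c(1000, 1000), end = c(5000, 5000),
                     strand = c("+", "+"), stringsAsFactors = FALSE)
  expect_equal(assign_gene(3000, twin), "GA")
})

test_that("annotate_probes gives controls no context and rejects unknown chromosomes", {
  man <- data.frame(
    probe_id = c("cg1", "cg2", "neg1"),
    chrom = c("chr1", "chr1", NA), pos = c(1500, 9000, NA),
    is_negative_control = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  cgis <- data.frame(chrom = "chr1", start = 1000, end = 2000)
  genes <- data.frame(gene_id = "G1", chrom = "chr1", start = 1200,
                      end = 6000, strand = "+", tss = 1200,
                      fe_start = 1200, fe_end = 1500)
  ann <- annotate_probes(man, cgis, genes)
  expect_equal(ann$cgi_category, c("Island", "OpenSea", NA))
  expect_equal(ann$cgi_group, c("Island", "OpenSea", NA))
  expect_equal(ann$gene[1], "G1")
  expect_true(is.na(ann$tss_category[3]))

  bad <- man
  bad$chrom[1] <- "chr99"
  expect_error(annotate_probes(bad, cgis, genes), "unknown chromosome")
})
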