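#' Build a gene universe with probe-count weights and term memberships
#'
#' The selection weight of a gene is the number of probes assigned to it in
#' the manifest, so resampling reproduces the probe-density bias of the
#' array. Terms are flat gene sets restricted to genes present on the array.
#'
#' @param manifest Annotated manifest with a `gene` column (`NA` for
#'   unassigned probes).
#' @param terms `data.frame` with `term_id`, `gene_id`.
#' @param term_desc Optional `data.frame` with `term_id`, `description`.
#' @return A list of class `gene_universe`: `genes`, `weights` (probe
#'   counts), `terms` (named list of gene-id vectors with `n_total >= 1`),
#'   `descriptions`.
#' @export
gene_universe <- function(manifest, terms, term_desc = NULL) {
  g <- manifest$gene[!is.na(manifest$gene)]
  counts <- table(g)
  genes <- names(counts)
  weights <- as.numeric(counts)
  term_list <- lapply(split(terms$gene_id, terms$term_id),
                      function(x) intersect(unique(x), genes))
  term_list <- term_list[vapply(term_list, length, integer(1)) >= 1L]
  desc <- if (!is.null(term_desc)) {
    stats::setNames(term_desc$description, term_desc$term_id)
  } else {
    stats::setNames(names(term_list), names(term_list))
  }
  structure(list(genes = genes, weights = weights, terms = term_list,
                 descriptions = desc),
            class = "gene_universe")
}

#' Probe-bias-corrected gene-set enrichment by weighted resampling
#'
#' Draws `n_resamples` random gene sets of the same size as the test set,
#' without replacement, with per-gene selection probability proportional to
#' its probe count, and compares each term's observed gene count against the
#' resampled counts: `p = #(resample count >= observed) / n_resamples`
#' (no pseudocount by default, so a term never reached by any resample can
#' report p = 0; `pseudocount = TRUE` adds one to numerator and denominator).
#' q-values are Benjamini-Hochberg over all tested terms; terms are flagged
#' significant at `q < 0.05`.
#'
#' @param test_genes Character vector of gene ids, a subset of the universe.
#' @param universe A [gene_universe()].
#' @param n_resamples Number of random sets (default 1000).
#' @param seed Integer seed for the resampling RNG.
#' @param pseudocount Logical; add-one correction for conservative p-values.
#' @return A `data.frame` with `term_id`, `description`, `n_total`,
#'   `n_intersect`, `p`, `q`, `significant`, sorted by `p`.
#' @export
weighted_resampling_test <- function(test_genes, universe, n_resamples = 1000,
                                     seed = 1, pseudocount = FALSE) {
  stopifnot(inherits(universe, "gene_universe"), length(test_genes) >= 1L)
  if (!all(test_genes %in% universe$genes)) {
    stop("test_genes must be a subset of the universe")
  }
  m <- length(unique(test_genes))
  if (m > length(universe$genes)) stop("test set larger than the universe")
  test_genes <- unique(test_genes)

  term_ids <- names(universe$terms)
  term_idx <- lapply(universe$terms,
                     function(g) match(g, universe$genes))
  observed <- vapply(universe$terms,
                     function(g) length(intersect(g, test_genes)), integer(1))

  set.seed(seed)
  n_genes <- length(universe$genes)
  exceed <- integer(length(term_ids))
  member <- logical(n_genes)
  for (r in seq_len(n_resamples)) {
    draw <- sample.int(n_genes, m, replace = FALSE, prob = universe$weights)
    member[] <- FALSE
    member[draw] <- TRUE
    cnt <- vapply(term_idx, function(ix) sum(member[ix]), integer(1))
    exceed <- exceed + (cnt >= observed)
  }
  p <- if (pseudocount) (exceed + 1) / (n_resamples + 1) else
    exceed / n_resamples
  q <- fdr_adjust(p)
  out <- data.frame(
    term_id = term_ids,
    description = unname(universe$descriptions[term_ids]),
    n_total = vapply(universe$terms, length, integer(1)),
    n_intersect = observed,
    p = p, q = q, significant = q < 0.05,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(out$p, out$term_id), ]
}
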