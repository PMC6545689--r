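#' Categorize probe positions by CpG-island context
#'
#' Assigns each probe position on one chromosome to a CpG-island (CGI)
#' relation category based on its distance to the nearest CGI: `Island` if the
#' position falls inside a CGI, `Shore` if the distance to the nearest CGI
#' boundary base is at most 2000 bp, `Shelf` if it lies in (2000, 4000] bp,
#' and `OpenSea` beyond 4000 bp. Shores and shelves carry an `N_`/`S_` prefix
#' marking which flank of the nearest CGI the probe sits on.
#'
#' @details
#' Distances are measured from the probe position to the nearest boundary base
#' of the nearest CGI, with CGIs given as 0-based half-open intervals
#' `[start, end)` (boundary bases `start` and `end - 1`). Both band edges are
#' closed: d = 2000 is still Shore and d = 4000 still Shelf.
#'
#' Under the default `"genomic"` convention, `N_` means the nearest CGI lies
#' at higher coordinates (the probe is on the lower-coordinate flank) and `S_`
#' that it lies at lower coordinates. `ns_convention = "flipped"` swaps the
#' two labels; the underlying distance bands are unaffected. A probe exactly
#' equidistant between two CGIs is labelled from the higher-coordinate CGI.
#'
#' @param pos Integer vector of probe positions (0-based) on one chromosome.
#' @param cgis A `data.frame` with columns `start`, `end`: non-overlapping,
#'   sorted CGI intervals on the same chromosome (0-based half-open).
#' @param ns_convention `"genomic"` (default) or `"flipped"`; see Details.
#' @return Character vector: one of `Island`, `N_Shore`, `S_Shore`,
#'   `N_Shelf`, `S_Shelf`, `OpenSea` per position. An empty CGI set yields
#'   `OpenSea` everywhere.
#' @export
categorize_cgi <- function(pos, cgis, ns_convention = c("genomic", "flipped")) {
  ns_convention <- match.arg(ns_convention)
  if (length(pos) == 0L) return(character(0))
  if (is.null(cgis) || nrow(cgis) == 0L) return(rep("OpenSea", length(pos)))
  starts <- as.numeric(cgis$start)
  ends <- as.numeric(cgis$end)
  if (any(starts >= ends)) stop("invalid CGI intervals: start >= end")
  if (is.unsorted(starts)) stop("CGI intervals must be sorted by start")
  if (any(starts[-1] < ends[-length(ends)])) {
    stop("CGI intervals must be non-overlapping")
  }

  idx <- findInterval(pos, starts)           # last CGI with start <= pos
  inside <- idx >= 1L & pos < ends[pmax(idx, 1L)]

  # distance to the previous CGI's last base and the next CGI's first base
  d_prev <- ifelse(idx >= 1L, pos - (ends[pmax(idx, 1L)] - 1), Inf)
  d_next <- ifelse(idx < length(starts), starts[pmin(idx + 1L, length(starts))] - pos, Inf)
  nearest_is_next <- d_next <= d_prev       # tie goes to the higher-coordinate CGI
  d <- pmin(d_prev, d_next)

  prefix_next <- if (ns_convention == "genomic") "N_" else "S_"
  prefix_prev <- if (ns_convention == "genomic") "S_" else "N_"
  prefix <- ifelse(nearest_is_next, prefix_next, prefix_prev)

  out <- rep("OpenSea", length(pos))
  out[d <= 4000] <- paste0(prefix[d <= 4000], "Shelf")
  out[d <= 2000] <- paste0(prefix[d <= 2000], "Shore")
  out[inside] <- "Island"
  out
}

#' Collapse N_/S_ CGI categories to their four-level grouping
#'
#' @param cgi_category Character vector of categories from [categorize_cgi()].
#' @return Character vector over `Island`, `Shore`, `Shelf`, `OpenSea`.
#' @export
collapse_cgi_category <- function(cgi_category) {
  sub("^[NS]_", "", cgi_category)
}

#' Categorize probe positions relative to transcription start sites
#'
#' Per transcript, a probe is `FirstExon` if it falls inside the transcript's
#' first exon, `TSS200` if it lies 0--200 bases upstream of the TSS in
#' transcript orientation, `TSS1500` if 200--1500 bases upstream (exclusive at
#' 200, inclusive at 1500), and `Far` otherwise. When several transcripts give
#' different categories the single reported category follows the priority
#' FirstExon > TSS200 > TSS1500 > Far.
#'
#' @param pos Integer vector of probe positions.
#' @param transcripts A `data.frame` with columns `tss` (TSS position),
#'   `strand` (`"+"`/`"-"`), `fe_start`, `fe_end` (first-exon interval,
#'   0-based half-open). May have zero rows.
#' @return Character vector over `FirstExon`, `TSS200`, `TSS1500`, `Far`.
#' @export
categorize_tss <- function(pos, transcripts) {
  if (length(pos) == 0L) return(character(0))
  if (is.null(transcripts) || nrow(transcripts) == 0L) {
    return(rep("Far", length(pos)))
  }
  tss <- as.numeric(transcripts$tss)
  minus <- transcripts$strand == "-"
  fe_s <- as.numeric(transcripts$fe_start)
  fe_e <- as.numeric(transcripts$fe_end)

  # rank: 3 = FirstExon, 2 = TSS200, 1 = TSS1500, 0 = Far
  best <- vapply(pos, function(p) {
    up <- ifelse(minus, p - tss, tss - p)   # upstream distance in tx orientation
    in_fe <- p >= fe_s & p < fe_e
    r <- integer(length(tss))
    r[up > 200 & up <= 1500] <- 1L
    r[up >= 0 & up <= 200] <- 2L
    r[in_fe] <- 3L
    max(r, 0L)
  }, integer(1))
  c("Far", "TSS1500", "TSS200", "FirstExon")[best + 1L]
}

#' Assign probes to genes by overlap with promoter-extended gene windows
#'
#' Each gene's extent is extended 1500 bp upstream (strand-aware) to form its
#' body-or-promoter window. A probe is assigned to the gene whose window
#' contains it; when several windows contain the probe, the gene whose body
#' edge is closest wins, with remaining ties broken by the lexicographically
#' smaller gene id. Probes contained in no window get `NA`.
#'
#' @param pos Integer vector of probe positions on one chromosome.
#' @param genes A `data.frame` with columns `gene_id`, `start`, `end`,
#'   `strand` for genes on the same chromosome (0-based half-open extents).
#' @param upstream Promoter extension in bp (default 1500).
#' @return Character vector of gene ids (`NA` where unassigned).
#' @export
assign_gene <- function(pos, genes, upstream = 1500) {
  if (length(pos) == 0L) return(character(0))
  if (is.null(genes) || nrow(genes) == 0L) return(rep(NA_character_, length(pos)))
  win_s <- ifelse(genes$strand == "-", genes$start, genes$start - upstream)
  win_e <- ifelse(genes$strand == "-", genes$end + upstream, genes$end)
  vapply(pos, function(p) {
    hit <- which(p >= win_s & p < win_e)
    if (length(hit) == 0L) return(NA_character_)
    if (length(hit) > 1L) {
      # distance to the gene body (0 if inside)
      d <- pmax(genes$start[hit] - p, p - (genes$end[hit] - 1), 0)
      hit <- hit[d == min(d)]
      if (length(hit) > 1L) hit <- hit[order(genes$gene_id[hit])][1L]
    }
    genes$gene_id[hit]
  }, character(1))
}

#' Annotate a probe manifest with CGI, TSS and gene context
#'
#' Runs [categorize_cgi()], [categorize_tss()] and [assign_gene()] per
#' chromosome and attaches the results to the manifest. Negative-control
#' probes have no genomic context and receive `NA` in every context column.
#'
#' @param manifest A `data.frame` with at least `probe_id`, `chrom`, `pos`,
#'   `is_negative_control`.
#' @param cgis CGI intervals (`chrom`, `start`, `end`).
#' @param genes Gene models (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`, `fe_start`, `fe_end`).
#' @param ns_convention Passed to [categorize_cgi()].
#' @param chroms Optional character vector of valid chromosome names; defaults
#'   to the chromosomes seen in `cgis` and `genes`. Probes on chromosomes
#'   outside this set raise an error.
#' @return The manifest with columns `cgi_category`, `cgi_group`,
#'   `tss_category`, `gene` added.
#' @export
annotate_probes <- function(manifest, cgis, genes,
                            ns_convention = c("genomic", "flipped"),
                            chroms = NULL) {
  ns_convention <- match.arg(ns_convention)
  n <- nrow(manifest)
  cgi_cat <- rep(NA_character_, n)
  tss_cat <- rep(NA_character_, n)
  gene <- rep(NA_character_, n)

  target <- !manifest$is_negative_control
  known <- if (is.null(chroms)) unique(c(cgis$chrom, genes$chrom)) else chroms
  bad <- target & !(manifest$chrom %in% known)
  if (any(bad)) {
    # chromosomes absent from both annotation sources are unknown territory
    stop("probes on unknown chromosome(s): ",
         paste(unique(manifest$chrom[bad]), collapse = ", "))
  }

  for (ch in unique(manifest$chrom[target])) {
    i <- which(target & manifest$chrom == ch)
    p <- manifest$pos[i]
    cg <- cgis[cgis$chrom == ch, , drop = FALSE]
    cg <- cg[order(cg$start), , drop = FALSE]
    cgi_cat[i] <- categorize_cgi(p, cg, ns_convention)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    tss_cat[i] <- categorize_tss(p, g)
    gene[i] <- assign_gene(p, g)
  }
  manifest$cgi_category <- cgi_cat
  manifest$cgi_group <- ifelse(is.na(cgi_cat), NA_character_,
                               collapse_cgi_category(cgi_cat))
  manifest$tss_category <- tss_cat
  manifest$gene <- gene
  manifest
}
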