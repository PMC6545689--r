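#' Inverse-method generalized-least-squares differential test
#'
#' Tests each probe's betas for a group difference after controlling
#' unwanted variation estimated from negative-control probes. The working
#' sample-by-sample covariance is built from the intercept-removed
#' negative-control rows; its eigencomponents exceeding the
#' Marchenko-Pastur upper edge (the unwanted-variation factors the controls
#' actually evidence) are retained and the remainder replaced by spherical
#' noise, so that with structureless controls the fit reduces exactly to
#' ordinary least squares. Each target probe is then fitted by generalized
#' least squares on the group indicator; two-sided p-values come from
#' t-statistics with n - 2 degrees of freedom.
#'
#' @param betas Numeric matrix, probes x samples, containing both target and
#'   negative-control rows.
#' @param labels Character or factor vector per sample; `"LTS"` is coded 1
#'   and any other value 0, so a positive coefficient means hypermethylation
#'   in LTS.
#' @param control_idx Row indices (or rownames) of the negative-control
#'   probes within `betas`; at least 10 are required.
#' @param k Optional number of unwanted-variation components: when given,
#'   the control covariance is truncated to its top `k` eigencomponents plus
#'   a scaled identity; the default (`NULL`) selects k automatically by the
#'   Marchenko-Pastur edge criterion.
#' @param ridge Ridge added to the eigenvalues as a fraction of their mean
#'   (numerical stabiliser; 0 disables it).
#' @return A `data.frame` with `probe_id`, `coef`, `stat`, `p` for every
#'   non-control row. Zero-variance probes get `stat = 0`, `p = 1`.
#' @export
ruv_inverse_test <- function(betas, labels, control_idx, k = NULL,
                             ridge = 0) {
  if (is.character(control_idx)) {
    control_idx <- match(control_idx, rownames(betas))
  }
  if (length(control_idx) < 10L) {
    stop("at least 10 negative-control probes are required")
  }
  x <- as.numeric(labels == "LTS")
  n <- length(x)
  if (ncol(betas) != n) stop("labels do not match the sample columns")
  if (sum(x == 1) < 3L || sum(x == 0) < 3L) {
    stop("both groups need at least 3 samples")
  }
  if (stats::var(x) == 0) stop("rank-deficient design: one group only")

  Yc <- betas[control_idx, , drop = FALSE]
  Yc0 <- Yc - rowMeans(Yc)                   # remove the intercept direction
  pc <- nrow(Yc0)
  Sigma <- crossprod(Yc0) / pc               # n x n across-sample covariance
  e <- eigen(Sigma, symmetric = TRUE)
  lam <- e$values
  if (is.null(k)) {
    # keep the eigencomponents a spherical-noise model cannot explain:
    # sequential comparison against the Marchenko-Pastur upper edge. The 25%
    # margin absorbs finite-sample fluctuation of the top eigenvalue (and
    # heterogeneous control variances, which fatten the null edge); measured
    # null ratios stay near 1 while genuine batch factors sit severalfold
    # above the edge, so the margin costs no sensitivity
    k <- 0L
    while (k < n - 1L) {
      noise <- mean(lam[(k + 1L):n])
      if (lam[k + 1L] > 1.25 * noise * (1 + sqrt(n / pc))^2) {
        k <- k + 1L
      } else {
        break
      }
    }
  } else {
    if (k >= length(control_idx)) {
      stop("fewer controls than requested components")
    }
    k <- min(k, n - 1L)
  }
  noise <- mean(lam[(k + 1L):n])
  lam_shrunk <- c(lam[seq_len(k)], rep(noise, n - k))
  lam_shrunk <- lam_shrunk + ridge * mean(lam)
  W <- e$vectors %*% (t(e$vectors) / sqrt(lam_shrunk))   # Sigma^(-1/2)

  Yt <- betas[-control_idx, , drop = FALSE]
  D <- cbind(intercept = 1, group = x)
  Dw <- W %*% D
  XtXi <- solve(crossprod(Dw))
  coefs <- XtXi %*% crossprod(Dw, tcrossprod(W, Yt))   # 2 x p
  resid <- tcrossprod(W, Yt) - Dw %*% coefs            # n x p whitened resid
  df <- n - 2L
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * XtXi["group", "group"])
  beta_hat <- coefs["group", ]
  # constant probes carry no information: report stat 0, p 1
  degenerate <- rowSums((Yt - rowMeans(Yt))^2) == 0 | se < 1e-12
  stat <- ifelse(degenerate, 0, beta_hat / se)
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(stat), df = df))
  data.frame(probe_id = rownames(Yt), coef = beta_hat, stat = stat, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length (empty in, empty out).
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential methylation between survival groups
#'
#' Runs [ruv_inverse_test()] on the target rows of a beta matrix, attaches
#' group means and the LTS - STS mean difference (delta), adjusts p-values
#' by Benjamini-Hochberg and flags significance at `fdr < 0.01`.
#'
#' @inheritParams ruv_inverse_test
#' @param fdr Significance threshold on the q-value (default 0.01).
#' @return An object of class `ruvdm`: a list with `results` (per-probe
#'   `data.frame`: `probe_id`, `mean_beta_lts`, `mean_beta_sts`, `delta`,
#'   `coef`, `stat`, `p`, `q`, `significant`), `fdr`, `n_lts`, `n_sts`.
#' @export
diff_methylation <- function(betas, labels, control_idx, k = NULL,
                             ridge = 0, fdr = 0.01) {
  res <- ruv_inverse_test(betas, labels, control_idx, k = k, ridge = ridge)
  if (is.character(control_idx)) {
    control_idx <- match(control_idx, rownames(betas))
  }
  Yt <- betas[-control_idx, , drop = FALSE]
  is_lts <- labels == "LTS"
  res$mean_beta_lts <- rowMeans(Yt[, is_lts, drop = FALSE])
  res$mean_beta_sts <- rowMeans(Yt[, !is_lts, drop = FALSE])
  res$delta <- res$mean_beta_lts - res$mean_beta_sts
  res$q <- fdr_adjust(res$p)
  res$significant <- res$q < fdr
  res <- res[, c("probe_id", "mean_beta_lts", "mean_beta_sts", "delta",
                 "coef", "stat", "p", "q", "significant")]
  structure(list(results = res, fdr = fdr,
                 n_lts = sum(is_lts), n_sts = sum(!is_lts)),
            class = "ruvdm")
}

#' @export
print.ruvdm <- function(x, ...) {
  cat("Differential methylation (inverse-method GLS with negative controls)\n")
  cat(sprintf("  samples: %d LTS vs %d STS; probes tested: %d\n",
              x$n_lts, x$n_sts, nrow(x$results)))
  cat(sprintf("  significant at FDR < %g: %d\n", x$fdr,
              sum(x$results$significant)))
  invisible(x)
}

#' @export
summary.ruvdm <- function(object, ...) {
  r <- object$results
  out <- list(
    n_probes = nrow(r),
    n_significant = sum(r$significant),
    delta_quartiles = stats::quantile(r$delta, c(0.25, 0.5, 0.75)),
    min_q = min(r$q)
  )
  class(out) <- "summary.ruvdm"
  out
}

#' @export
print.summary.ruvdm <- function(x, ...) {
  cat(sprintf("probes: %d, significant: %d, min q: %.3g\n",
              x$n_probes, x$n_significant, x$min_q))
  cat("delta quartiles:\n")
  print(x$delta_quartiles)
  invisible(x)
}

#' Select the hyper-island and hypo-open-sea signature sets
#'
#' The hyper signature holds significant Island probes with
#' `delta > delta_threshold`; the hypo signature holds significant OpenSea
#' probes with `delta < -delta_threshold`. Both comparisons are strict, so a
#' probe at exactly the threshold is excluded.
#'
#' @param dm A `ruvdm` object (or its `results` `data.frame`).
#' @param manifest Annotated manifest with `probe_id` and `cgi_group`.
#' @param delta_threshold Mean-difference cutoff (default 0.2).
#' @return A list of class `signature_set` with `hyper_island_sites` and
#'   `hypo_opensea_sites` (probe-id character vectors).
#' @export
select_signatures <- function(dm, manifest, delta_threshold = 0.2) {
  res <- if (inherits(dm, "ruvdm")) dm$results else dm
  grp <- manifest$cgi_group[match(res$probe_id, manifest$probe_id)]
  hyper <- res$probe_id[res$significant & !is.na(grp) & grp == "Island" &
                          res$delta > delta_threshold]
  hypo <- res$probe_id[res$significant & !is.na(grp) & grp == "OpenSea" &
                         res$delta < -delta_threshold]
  structure(list(hyper_island_sites = hyper, hypo_opensea_sites = hypo),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature set: %d hyper-island, %d hypo-open-sea sites\n",
              length(x$hyper_island_sites), length(x$hypo_opensea_sites)))
  invisible(x)
}

#' Per-category distribution of the LTS - STS difference
#'
#' Summarises delta (median and quartiles) separately for significant and
#' insignificant probes within each CGI category and each TSS category,
#' mirroring the violin-style views of shift direction by genomic context.
#'
#' @param dm A `ruvdm` object (or its `results` `data.frame`).
#' @param manifest Annotated manifest with `probe_id`, `cgi_category`,
#'   `tss_category`.
#' @return A `data.frame` with `axis` (`cgi`/`tss`), `category`, `group`
#'   (`significant`/`other`), `n`, `q25`, `median`, `q75`.
#' @export
category_shift_summary <- function(dm, manifest) {
  res <- if (inherits(dm, "ruvdm")) dm$results else dm
  m <- manifest[match(res$probe_id, manifest$probe_id), ]
  one_axis <- function(axis, cats) {
    out <- lapply(unique(stats::na.omit(cats)), function(ct) {
      lapply(c(TRUE, FALSE), function(sig) {
        d <- res$delta[!is.na(cats) & cats == ct & res$significant == sig]
        if (length(d) == 0L) return(NULL)
        q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
        data.frame(axis = axis, category = ct,
                   group = if (sig) "significant" else "other",
                   n = length(d), q25 = q[1], median = q[2], q75 = q[3],
                   stringsAsFactors = FALSE)
      })
    })
    do.call(rbind, unlist(out, recursive = FALSE))
  }
  rbind(one_axis("cgi", m$cgi_category), one_axis("tss", m$tss_category))
}
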