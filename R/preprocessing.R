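#' Detection p-value against negative-control background
#'
#' A probe's total intensity (methylated + unmethylated) is compared to the
#' distribution of negative-control total intensities in the same sample
#' under a Gaussian background model:
#' `p = 1 - pnorm((total - mu_neg) / sd_neg)`.
#'
#' @param total Numeric vector of target-probe total intensities (M + U).
#' @param neg_totals Numeric vector of negative-control total intensities for
#'   the same sample; at least 10 are required.
#' @param method `"gaussian"` (default) or `"empirical"`; the empirical
#'   alternative reports the rank-based exceedance fraction
#'   `mean(neg_totals >= total)`.
#' @return Numeric vector of detection p-values in `[0, 1]`.
#' @export
detection_pvalue <- function(total, neg_totals,
                             method = c("gaussian", "empirical")) {
  method <- match.arg(method)
  if (length(neg_totals) < 10L) {
    stop("at least 10 negative-control intensities are required")
  }
  if (method == "empirical") {
    return(vapply(total, function(t) mean(neg_totals >= t), numeric(1)))
  }
  mu <- mean(neg_totals)
  sigma <- stats::sd(neg_totals)
  if (!is.finite(sigma) || sigma == 0) {
    stop("degenerate negative controls: zero standard deviation")
  }
  stats::pnorm((total - mu) / sigma, lower.tail = FALSE)
}

#' Detection p-value matrix for an intensity table
#'
#' Applies [detection_pvalue()] column-by-column (per sample), comparing each
#' target probe's M + U against that sample's negative-control totals.
#'
#' @param M,U Probes-by-samples matrices of methylated / unmethylated
#'   intensities (target probes only).
#' @param neg_M,neg_U Negative-control intensity matrices (controls x
#'   samples), same sample columns.
#' @inheritParams detection_pvalue
#' @return A probes-by-samples matrix of detection p-values.
#' @export
detection_pvalue_matrix <- function(M, U, neg_M, neg_U,
                                    method = c("gaussian", "empirical")) {
  method <- match.arg(method)
  stopifnot(identical(dim(M), dim(U)), identical(dim(neg_M), dim(neg_U)),
            ncol(M) == ncol(neg_M))
  total <- M + U
  neg_total <- neg_M + neg_U
  out <- matrix(NA_real_, nrow(M), ncol(M), dimnames = dimnames(M))
  for (j in seq_len(ncol(M))) {
    out[, j] <- detection_pvalue(total[, j], neg_total[, j], method = method)
  }
  out
}

#' Beta value from methylated and unmethylated intensities
#'
#' `beta = M / (M + U + offset)` with the standard offset of 100, keeping the
#' ratio defined and shrunk toward 0 when both channels are dim.
#'
#' @param M,U Non-negative intensities (vectors or matrices of equal shape).
#' @param offset Stabilizing offset added to the denominator (default 100).
#' @return Beta values in `[0, 1]`, same shape as the inputs.
#' @export
compute_beta <- function(M, U, offset = 100) {
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative")
  }
  M / (M + U + offset)
}

#' Apply the six probe-exclusion rules
#'
#' A probe is removed iff any rule fires:
#' \enumerate{
#'   \item detection p-value > `detp_threshold` in more than
#'     `sample_fraction` of samples;
#'   \item bead count < `min_beads` in more than `sample_fraction` of samples;
#'   \item non-CpG probe;
#'   \item probe overlapping a SNP;
#'   \item probe aligning to multiple genomic locations;
#'   \item probe on a sex chromosome.
#' }
#' All three numeric inequalities are strict. Each removed probe is
#' attributed to the first rule (in the order above) that fires; attribution
#' affects only the per-rule counts, never membership of the retained set.
#'
#' @param detp Probes-by-samples matrix of detection p-values.
#' @param beads Probes-by-samples matrix of bead counts.
#' @param manifest Probe manifest with `probe_id`, `chrom`, `is_cpg`,
#'   `is_snp`, `is_multimapped` for the same probe rows.
#' @param detp_threshold,sample_fraction,min_beads Rule thresholds
#'   (defaults 0.01, 0.05, 3).
#' @param sex_chroms Chromosome names treated as sex chromosomes.
#' @return A list with `keep` (retained probe ids), `removed` (a `data.frame`
#'   of `probe_id`, `rule`), and `counts` (a `data.frame` of per-rule removal
#'   counts, rules i--vi).
#' @export
filter_probes <- function(detp, beads, manifest,
                          detp_threshold = 0.01, sample_fraction = 0.05,
                          min_beads = 3, sex_chroms = c("chrX", "chrY")) {
  n_samples <- ncol(detp)
  if (is.null(n_samples) || n_samples == 0L) stop("no samples in the table")
  stopifnot(nrow(detp) == nrow(manifest), nrow(beads) == nrow(manifest))

  fails <- cbind(
    i   = rowMeans(detp > detp_threshold) > sample_fraction,
    ii  = rowMeans(beads < min_beads) > sample_fraction,
    iii = !manifest$is_cpg,
    iv  = manifest$is_snp,
    v   = manifest$is_multimapped,
    vi  = manifest$chrom %in% sex_chroms
  )
  removed <- rowSums(fails) > 0L
  first_rule <- apply(fails, 1L, function(f) {
    w <- which(f)
    if (length(w)) colnames(fails)[w[1L]] else NA_character_
  })
  rules <- colnames(fails)
  counts <- data.frame(
    rule = rules,
    count = vapply(rules, function(r) sum(first_rule == r, na.rm = TRUE),
                   integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(
    keep = manifest$probe_id[!removed],
    removed = data.frame(probe_id = manifest$probe_id[removed],
                         rule = first_rule[removed],
                         stringsAsFactors = FALSE),
    counts = counts
  )
}

# Three-state beta-mixture fit by EM with weighted moment-matching updates.
# Convergence is judged on the state means (max absolute change < tol), which
# stabilise long before the log-likelihood plateau on overlapping components.
# Large inputs are quantile-thinned to at most 2000 points for the fit; the
# resulting mixture is a distribution estimate, so thinning does not bias it.
fit_beta_mixture3 <- function(b, max_iter = 3000, tol = 1e-4) {
  eps <- 1e-4
  b <- pmin(pmax(b, eps), 1 - eps)
  if (length(b) < 30L) stop("too few beta values to fit a 3-state mixture")
  if (length(b) > 2000L) {
    b <- stats::quantile(sort(b), seq(0, 1, length.out = 2000L), names = FALSE)
  }
  n <- length(b)

  # deterministic initialization from fixed cutpoints
  state <- cut(b, c(-Inf, 0.25, 0.75, Inf), labels = FALSE)
  r <- matrix(0, n, 3L)
  r[cbind(seq_len(n), state)] <- 1
  r <- r + 0.05  # soften so no state starts empty
  r <- r / rowSums(r)

  shapes <- matrix(NA_real_, 3L, 2L)
  pi_k <- rep(1 / 3, 3L)
  mu_old <- rep(-1, 3L)
  ll <- NA_real_
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # M-step: weighted moments -> beta shapes
    w <- colSums(r)
    if (any(w < 1e-8)) stop("a mixture state became empty during EM")
    pi_k <- w / n
    mu <- colSums(r * b) / w
    v <- colSums(r * (b - rep(mu, each = n))^2) / w
    v <- pmax(v, 1e-6)
    phi <- pmax(mu * (1 - mu) / v - 1, 0.1)
    shapes[, 1L] <- mu * phi
    shapes[, 2L] <- (1 - mu) * phi

    # E-step
    d <- vapply(1:3, function(k) {
      pi_k[k] * stats::dbeta(b, shapes[k, 1L], shapes[k, 2L])
    }, numeric(n))
    rs <- rowSums(d)
    rs[rs < 1e-300] <- 1e-300
    r <- d / rs
    ll <- sum(log(rs))
    if (max(abs(mu - mu_old)) < tol) break
    if (iter >= max_iter) {
      stop("beta-mixture EM did not converge in ", max_iter,
           " iterations (last state-mean change ",
           format(max(abs(mu - mu_old)), digits = 3), ")")
    }
    mu_old <- mu
  }
  ord <- order(shapes[, 1L] / rowSums(shapes))
  list(pi = pi_k[ord], shape1 = shapes[ord, 1L], shape2 = shapes[ord, 2L],
       iterations = iter, loglik = ll)
}

mixture_cdf <- function(x, fit) {
  out <- 0
  for (k in 1:3) {
    out <- out + fit$pi[k] * stats::pbeta(x, fit$shape1[k], fit$shape2[k])
  }
  out
}

#' BMIQ-style normalization of type-II betas onto the type-I scale
#'
#' Fits a three-state (unmethylated / hemimethylated / methylated)
#' beta-mixture by EM separately to the type-I and type-II betas of one
#' sample, then maps each type-II beta through the fitted mixture
#' distribution functions, `b' = F1^{-1}(F2(b))`. Because both fitted CDFs
#' are strictly increasing, the map is monotone and preserves the rank order
#' of the type-II betas; type-I betas are returned unchanged.
#'
#' @param beta Numeric vector of one sample's betas in `[0, 1]`.
#' @param assay_type Character vector (`"I"`/`"II"`) aligned with `beta`.
#' @param max_iter,tol EM iteration cap and convergence tolerance on the
#'   maximum absolute change of the three state means.
#' @return A list with `beta` (normalized vector, type-I entries unchanged)
#'   and `qc` (a one-row `data.frame` with state means, mixture weights and
#'   EM iteration counts for both fits).
#' @export
bmiq_normalize <- function(beta, assay_type, max_iter = 3000, tol = 1e-4) {
  stopifnot(length(beta) == length(assay_type))
  is2 <- assay_type == "II"
  if (!any(is2) || !any(!is2)) {
    stop("both probe types must be present for BMIQ")
  }
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) stop("betas must lie in [0, 1]")
  fit1 <- fit_beta_mixture3(beta[!is2], max_iter = max_iter, tol = tol)
  fit2 <- fit_beta_mixture3(beta[is2], max_iter = max_iter, tol = tol)

  # invert the type-I mixture CDF on a fine grid
  grid <- seq(1e-4, 1 - 1e-4, length.out = 2000L)
  f1 <- mixture_cdf(grid, fit1)
  keep <- !duplicated(f1)   # CDF saturates in the far tails
  u <- mixture_cdf(pmin(pmax(beta[is2], 1e-4), 1 - 1e-4), fit2)
  mapped <- stats::approx(f1[keep], grid[keep], xout = u, rule = 2)$y

  out <- beta
  out[is2] <- pmin(pmax(mapped, 0), 1)
  state_means <- function(f) f$shape1 / (f$shape1 + f$shape2)
  qc <- data.frame(
    t(c(typeI_mean = state_means(fit1), typeII_mean = state_means(fit2))),
    typeI_iter = fit1$iterations, typeII_iter = fit2$iterations,
    check.names = FALSE
  )
  list(beta = out, qc = qc)
}

#' BMIQ normalization across all samples of a beta matrix
#'
#' @param betas Probes-by-samples beta matrix.
#' @param assay_type Character vector (`"I"`/`"II"`) per probe row.
#' @inheritParams bmiq_normalize
#' @return A list with `betas` (normalized matrix) and `qc` (per-sample QC
#'   rows from [bmiq_normalize()]).
#' @export
bmiq_matrix <- function(betas, assay_type, max_iter = 3000, tol = 1e-4) {
  stopifnot(nrow(betas) == length(assay_type))
  out <- betas
  qc <- vector("list", ncol(betas))
  for (j in seq_len(ncol(betas))) {
    r <- bmiq_normalize(betas[, j], assay_type, max_iter = max_iter, tol = tol)
    out[, j] <- r$beta
    qc[[j]] <- cbind(sample = colnames(betas)[j] %||% as.character(j), r$qc)
  }
  list(betas = out, qc = do.call(rbind, qc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
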