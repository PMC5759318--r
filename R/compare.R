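#' Wilcoxon rank-sum screen between two flux sample sets
#'
#' For every reaction, the two sampled flux distributions (e.g. low versus
#' high salinity) are compared with a two-sided Wilcoxon rank-sum test in
#' its tie-corrected normal approximation. The Z statistic is oriented so
#' that positive values mean the second sample (conventionally the
#' high-salinity condition) tends to larger fluxes. A reaction is flagged
#' significant when |Z| exceeds `z_min` and the p-value falls below
#' `p_max`; the extreme default `z_min = 50` is a deliberate screen that no
#' null fluctuation at 20,000 points per condition can reach, so no further
#' multiple-testing correction is applied by default. Benjamini-Hochberg
#' q-values are emitted as an extra column for users who want one.
#'
#' @param sample_a,sample_b `flux_sample_set`s over identical reaction
#'   sets; `sample_b` minus `sample_a` is the reported direction.
#' @param z_min,p_max significance thresholds (defaults 50 and 0.01).
#' @return a `flux_comparison` data.frame with columns `reaction`, `Z`,
#'   `p`, `q`, `significant`.
#' @export
wilcoxon_compare <- function(sample_a, sample_b, z_min = 50,
                             p_max = 0.01) {
  A <- sample_a$samples
  B <- sample_b$samples
  if (!identical(sort(colnames(A)), sort(colnames(B)))) {
    only_a <- setdiff(colnames(A), colnames(B))
    only_b <- setdiff(colnames(B), colnames(A))
    stop("reaction sets differ; only in first: ",
         paste(only_a, collapse = ", "), "; only in second: ",
         paste(only_b, collapse = ", "), call. = FALSE)
  }
  B <- B[, colnames(A), drop = FALSE]
  n1 <- nrow(A); n2 <- nrow(B); N <- n1 + n2
  stats_z <- vapply(colnames(A), function(id) {
    r <- rank(c(A[, id], B[, id]))
    w <- sum(r[(n1 + 1):N])
    mu <- n2 * (N + 1) / 2
    ties <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(0)
    (w - mu) / sqrt(sigma2)
  }, numeric(1))
  p <- 2 * stats::pnorm(-abs(stats_z))
  out <- data.frame(reaction = colnames(A), Z = unname(stats_z),
                    p = unname(p),
                    q = stats::p.adjust(unname(p), method = "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- abs(out$Z) > z_min & out$p < p_max
  attr(out, "thresholds") <- c(z_min = z_min, p_max = p_max)
  class(out) <- c("flux_comparison", class(out))
  out
}

#' Mean paired-subtraction effect size between two sample sets
#'
#' Draws `k` points without replacement from each condition's flux vector
#' of every reaction (independently per condition — the marginals are
#' independent samples, so the pairing is arbitrary and the estimator
#' targets the difference of marginal means), subtracts them pairwise, and
#' averages: the reported value estimates the second-minus-first shift of
#' each reaction's flux distribution.
#'
#' @param sample_a,sample_b `flux_sample_set`s over identical reactions,
#'   each with at least `k` rows.
#' @param k number of points drawn per condition (default 2000).
#' @param seed integer seed making the draws reproducible.
#' @return named numeric vector of per-reaction mean differences
#'   (`sample_b` minus `sample_a`).
#' @export
mean_paired_difference <- function(sample_a, sample_b, k = 2000,
                                   seed = 1L) {
  A <- sample_a$samples
  B <- sample_b$samples
  if (!identical(sort(colnames(A)), sort(colnames(B)))) {
    stop("reaction sets differ between samples", call. = FALSE)
  }
  B <- B[, colnames(A), drop = FALSE]
  if (k > nrow(A) || k > nrow(B)) {
    stop("k = ", k, " exceeds sample size (", nrow(A), ", ", nrow(B), ")",
         call. = FALSE)
  }
  set.seed(seed)
  ia <- sample.int(nrow(A), k)
  ib <- sample.int(nrow(B), k)
  colMeans(B[ib, , drop = FALSE] - A[ia, , drop = FALSE])
}
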