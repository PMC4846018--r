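#' Attained genotypic value of a selected set
#'
#' The maximum of the true genotypic values among the selected plants — the
#' headline response metric of a selection cycle, under the assumption that
#' the breeder can identify the best plant among the selected ones in field
#' trials before release.
#'
#' @param selected a nonempty [gs_pop()] of selected plants.
#' @param arch a `trait_arch`.
#' @return The maximum true genotypic value.
#' @export
attained_genotypic_value <- function(selected, arch) {
  if (n_ind(selected) == 0) stop("selected set is empty")
  max(genotypic_value(selected, arch))
}

#' Best-line standard of an initial family
#'
#' The maximum true genotypic value among a family's recombinant inbred
#' lines: the standard against which recurrent-selection gains are compared
#' (the attainable ceiling of pure inbred-line selection).
#'
#' @param family a nonempty [gs_pop()] of inbred lines.
#' @param arch a `trait_arch`.
#' @return The maximum true genotypic value in the family.
#' @export
baseline_best_line <- function(family, arch) {
  if (n_ind(family) == 0) stop("family is empty")
  max(genotypic_value(family, arch))
}

#' Prediction accuracy
#'
#' Pearson's correlation between predicted values and true genotypic values.
#' Returns `NA` with a warning when either vector has zero variance.
#'
#' @param predicted,true_values numeric vectors of equal length >= 3.
#' @return Correlation in [-1, 1], or `NA`.
#' @export
prediction_accuracy <- function(predicted, true_values) {
  stopifnot(length(predicted) == length(true_values),
            length(predicted) >= 3)
  if (stats::var(predicted) == 0 || stats::var(true_values) == 0) {
    warning("zero variance: prediction accuracy undefined")
    return(NA_real_)
  }
  stats::cor(predicted, true_values)
}

#' Heterozygosity and locus fixation of a population
#'
#' The heterozygous proportion is the mean over individuals and markers of
#' the heterozygote indicator (a population-level proportion that is near
#' zero for inbred lines and jumps after crossing).  The fixed-locus
#' proportion is the fraction of markers at which every individual carries
#' the same homozygous genotype.
#'
#' @param pop a nonempty [gs_pop()].
#' @return List with `het` and `fixed`.
#' @export
heterozygosity_and_fixation <- function(pop) {
  if (n_ind(pop) == 0) stop("population is empty")
  het <- mean(pop$hap1 != pop$hap2)
  same_allele <- pop$hap1 == pop$hap2
  first1 <- pop$hap1[1, ]; first2 <- pop$hap2[1, ]
  fixed_col <- colSums(same_allele) == nrow(same_allele) &
    colSums(pop$hap1 == matrix(first1, nrow(pop$hap1), ncol(pop$hap1),
                               byrow = TRUE)) == nrow(pop$hap1)
  fixed <- mean(fixed_col & first1 == first2)
  list(het = het, fixed = fixed)
}

#' Chi-square test of family selection bias
#'
#' Goodness-of-fit test of the per-family selected counts against equal
#' expected proportions (df = number of families - 1).
#'
#' @param counts integer vector of selected counts per family (length >= 2,
#'   positive total).
#' @return List with `statistic`, `df` and `p`.
#' @export
family_bias_chisq <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) >= 2, sum(counts) > 0)
  tst <- suppressWarnings(stats::chisq.test(counts))
  list(statistic = unname(tst$statistic), df = unname(tst$parameter),
       p = tst$p.value)
}

#' Matched-pairs Wilcoxon signed-rank test
#'
#' Paired test on per-replicate differences between two breeding schemes
#' started from identical initial populations.  Zero differences are
#' dropped; the exact distribution is used for up to 25 informative pairs
#' (absent ties), otherwise the normal approximation with tie correction.
#' If every pair is tied the p-value is reported as 1 with a warning.
#'
#' @param a,b numeric vectors of paired per-replicate values.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List with `statistic` (V) and `p`.
#' @export
wilcoxon_matched_pairs <- function(a, b, alternative = "two.sided") {
  stopifnot(length(a) == length(b))
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  d <- (a - b)[a != b]
  n <- length(d)
  if (n == 0) {
    warning("all pairs tied; p-value reported as 1")
    return(list(statistic = 0, p = 1))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25) {
    # exact null distribution of the signed-rank sum by convolution
    # (doubled ranks keep tied average ranks integral)
    R <- as.integer(round(2 * r))
    tot <- sum(R)
    f <- numeric(tot + 1)
    f[1] <- 1
    for (Ri in R) {
      shifted <- c(rep(0, Ri), f[seq_len(tot + 1 - Ri)])
      f <- f + shifted
    }
    f <- f / 2^n
    v2 <- as.integer(round(2 * v))
    pge <- sum(f[(v2 + 1):(tot + 1)])
    ple <- sum(f[seq_len(v2 + 1)])
    p <- switch(alternative, greater = pge, less = ple,
                two.sided = min(1, 2 * min(pge, ple)))
  } else {
    tst <- suppressWarnings(stats::wilcox.test(
      d, alternative = alternative, exact = FALSE, correct = TRUE))
    p <- tst$p.value
  }
  list(statistic = v, p = p)
}

#' Principal components of a population's genotypes
#'
#' Scores of the first `k` principal components of the centered genotype
#' code matrix, via singular value decomposition.  Component signs are fixed
#' by making the largest-magnitude entry of each loading vector positive, so
#' results are reproducible across platforms.
#'
#' @param pop a [gs_pop()] with >= 3 individuals.
#' @param k number of components (default 2).
#' @return Matrix of scores (individuals x k).
#' @export
pca_genotypes <- function(pop, k = 2) {
  if (n_ind(pop) < 3) stop("need at least 3 individuals")
  g <- genotypes(pop)
  gc <- sweep(g, 2, colMeans(g))
  sv <- svd(gc, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k) %*% diag(flip, k, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- pop$id
  scores
}
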