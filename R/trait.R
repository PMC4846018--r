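#' Geometric-series QTL heritability weights with a target effective number
#'
#' Per-QTL heritability weights follow a truncated geometric series
#' w_k proportional to (1-a)^(k-1), k = 1..n_qtl, the declining-effects
#' architecture of Lande and Thompson.  The decay parameter a is solved
#' numerically so that the effective number of QTL of the truncated series,
#' (sum w)^2 / sum(w^2), equals `effective_n`; the weights are then scaled to
#' sum exactly to `total_h2`.
#'
#' @param n_qtl number of QTL.
#' @param effective_n target effective number, in (1, n_qtl].
#' @param total_h2 total heritability the weights sum to.
#' @return Numeric vector of length `n_qtl`, strictly positive and
#'   nonincreasing, summing to `total_h2`.
#' @examples
#' w <- lande_thompson_weights(100, 40, 0.6)
#' sum(w)                      # 0.6
#' sum(w)^2 / sum(w^2)         # 40
#' @export
lande_thompson_weights <- function(n_qtl = 100, effective_n = 40,
                                   total_h2 = 0.6) {
  if (effective_n > n_qtl)
    stop("effective_n exceeds n_qtl: unattainable")
  if (effective_n < 1) stop("effective_n must be >= 1")
  eff_n <- function(a) {
    r <- (1 - a)^(seq_len(n_qtl) - 1)
    sum(r)^2 / sum(r^2)
  }
  if (abs(effective_n - n_qtl) < 1e-12) {
    w <- rep(1, n_qtl)
  } else {
    a <- stats::uniroot(function(a) eff_n(a) - effective_n,
                        interval = c(1e-12, 1 - 1e-12), tol = 1e-14)$root
    w <- (1 - a)^(seq_len(n_qtl) - 1)
  }
  w * (total_h2 / sum(w))
}

#' Build an additive QTL architecture on a founder panel
#'
#' Samples `n_qtl` founder-polymorphic markers uniformly without replacement
#' as QTL, assigns the [lande_thompson_weights()] to them in random order
#' with i.i.d. random effect signs, and calibrates allele-substitution
#' effects so that each QTL's marginal genotypic-variance contribution in
#' the founder panel is its weight: |effect_k| = sqrt(w_k / Var(code_k)).
#' Because linked QTL covary, the sum of marginal contributions differs from
#' the variance of the sum, so the whole effect vector is rescaled once so
#' the realized founder genetic variance (including LD covariances) equals
#' `total_h2` exactly; the environmental variance is set to `1 - total_h2`,
#' making founder phenotypic variance exactly 1.  Uses the current RNG.
#'
#' @param panel a `founder_panel`.
#' @param n_qtl number of QTL markers.
#' @param effective_n target effective QTL number.
#' @param total_h2 total heritability (founder phenotypic variance is
#'   standardized to 1, so this is also the founder genetic variance).
#' @return An object of class `trait_arch`: list with `qtl` (marker indices),
#'   `effects` (signed substitution effects, parallel to `qtl`), `weights`,
#'   `h2`, `sigma2_e`, and `non_qtl` (all remaining marker indices).
#' @export
build_architecture <- function(panel, n_qtl = 100, effective_n = 40,
                               total_h2 = 0.6) {
  g <- genotypes(panel$pop)
  v <- apply(g, 2, stats::var)
  poly <- which(v > 0)
  if (length(poly) < n_qtl)
    stop("panel has only ", length(poly), " polymorphic markers; need ",
         n_qtl)
  qtl <- sort(sample(poly, n_qtl))
  w <- lande_thompson_weights(n_qtl, effective_n, total_h2)
  w <- w[sample.int(n_qtl)]                      # random rank assignment
  sgn <- sample(c(-1, 1), n_qtl, replace = TRUE)
  eff <- sgn * sqrt(w / v[qtl])
  if (total_h2 > 0) {
    gv <- drop(g[, qtl, drop = FALSE] %*% eff)
    eff <- eff * sqrt(total_h2 / stats::var(gv))
  } else {
    eff <- rep(0, n_qtl)
  }
  structure(list(qtl = qtl, effects = eff, weights = w, h2 = total_h2,
                 sigma2_e = 1 - total_h2,
                 non_qtl = setdiff(seq_len(ncol(g)), qtl)),
            class = "trait_arch")
}

#' @export
print.trait_arch <- function(x, ...) {
  cat(sprintf(
    "Additive trait architecture: %d QTL, h2 = %.3g, sigma2_e = %.3g\n",
    length(x$qtl), x$h2, x$sigma2_e))
  invisible(x)
}

#' True genotypic values under an additive architecture
#'
#' Purely additive: sum over QTL of effect times the -1/0/1 genotype code.
#' No dominance or epistasis.
#'
#' @param pop a [gs_pop()].
#' @param arch a `trait_arch`.
#' @return Numeric vector of genotypic values, one per individual.
#' @export
genotypic_value <- function(pop, arch) {
  g <- pop$hap1[, arch$qtl, drop = FALSE] +
    pop$hap2[, arch$qtl, drop = FALSE] - 1L
  drop(g %*% arch$effects)
}

#' Simulate phenotypes
#'
#' Genotypic value plus independent Normal(0, sigma2_e) environmental
#' deviations.  Uses the current RNG.
#'
#' @param pop a [gs_pop()].
#' @param arch a `trait_arch`.
#' @return Numeric vector of phenotypes.
#' @export
phenotype <- function(pop, arch) {
  genotypic_value(pop, arch) +
    stats::rnorm(n_ind(pop), 0, sqrt(arch$sigma2_e))
}

#' Export a trait architecture as a data frame
#'
#' @param arch a `trait_arch`.
#' @param map the [genetic_map()] the architecture refers to.
#' @return Data frame with marker_id, chrom, cM, effect and weight per QTL.
#' @export
architecture_table <- function(arch, map) {
  data.frame(marker_id = map$marker[arch$qtl],
             chrom = map$chrom[arch$qtl],
             cM = map$pos_cM[arch$qtl],
             effect = arch$effects,
             weight = arch$weights)
}
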