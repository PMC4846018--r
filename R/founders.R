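#' Generate a synthetic founder panel of fully inbred lines
#'
#' Emulates a diversity panel of inbred cultivars (default 112 lines over a
#' 3,102-marker map) by a mosaic-of-ancestors construction: `n_ancestors`
#' ancestral haplotypes are drawn marker-wise from a U-shaped allele-frequency
#' spectrum (Beta(1/2, 1/2) truncated at `maf_floor`), and every founder is a
#' doubled haplotype built by copying ancestral segments whose cM lengths are
#' exponential with mean `segment_length_cM`.  Each founder is biased towards
#' one "home" ancestor (probability `cluster_bias` per segment), which yields
#' the ancestry-driven cluster structure typical of cultivar panels, while
#' the segment mosaic yields linkage disequilibrium decaying with cM
#' distance.  All founders are exactly homozygous.  Uses the current RNG.
#'
#' @param n_founders number of inbred lines.
#' @param map a [genetic_map()].
#' @param n_ancestors number of ancestral haplotypes (>= 2).
#' @param segment_length_cM mean ancestral segment length in cM.
#' @param maf_floor lower truncation of ancestral minor-allele frequency.
#' @param cluster_bias probability that a segment is copied from the
#'   founder's home ancestor rather than a uniformly random one.
#' @return An object of class `founder_panel`: list with elements `pop`
#'   (a [gs_pop()]), `map`, and `cluster` (home-ancestor label per founder).
#' @export
generate_founders <- function(n_founders = 112, map = synthetic_map(),
                              n_ancestors = 8, segment_length_cM = 20,
                              maf_floor = 0.05, cluster_bias = 0.7) {
  if (n_ancestors < 2)
    stop("n_ancestors must be >= 2: a single ancestor gives no polymorphism")
  m <- nrow(map)
  p <- stats::rbeta(m, 0.5, 0.5)
  p <- pmin(pmax(p, maf_floor), 1 - maf_floor)
  anc <- matrix(stats::rbinom(n_ancestors * m, 1L, rep(p, each = n_ancestors)),
                n_ancestors, m)
  ms <- map_split(map)
  home <- rep_len(seq_len(n_ancestors), n_founders)
  home <- home[sample.int(n_founders)]
  hap <- matrix(0L, n_founders, m)
  for (f in seq_len(n_founders)) {
    for (k in seq_along(ms$pos)) {
      pos <- ms$pos[[k]]; cols <- ms$idx[[k]]
      L <- pos[length(pos)] - pos[1]
      # segment breakpoints along the chromosome
      br <- numeric(0); at <- pos[1]
      repeat {
        at <- at + stats::rexp(1, 1 / segment_length_cM)
        if (at >= pos[1] + L) break
        br <- c(br, at)
      }
      seg <- findInterval(pos, br) + 1L
      n_seg <- max(seg)
      donor <- ifelse(stats::runif(n_seg) < cluster_bias, home[f],
                      sample.int(n_ancestors, n_seg, replace = TRUE))
      hap[f, cols] <- anc[cbind(donor[seg], cols)]
    }
  }
  pop <- gs_pop(hap, hap, id = sprintf("founder%03d", seq_len(n_founders)))
  structure(list(pop = pop, map = map, cluster = home),
            class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  g <- genotypes(x$pop)
  poly <- mean(apply(g, 2, function(v) length(unique(v)) > 1))
  cat(sprintf(
    "Founder panel: %d inbred lines x %d markers, %.1f%% polymorphic markers\n",
    n_ind(x$pop), ncol(g), 100 * poly))
  invisible(x)
}

#' Fraction of panel-polymorphic markers
#' @param panel a `founder_panel`.
#' @return Proportion of markers segregating among the founders.
#' @export
polymorphic_fraction <- function(panel) {
  g <- genotypes(panel$pop)
  mean(apply(g, 2, function(v) any(v != v[1])))
}

#' Euclidean distance matrix between founders
#'
#' Pairwise Euclidean distance over marker codes with the two homozygous
#' genotypes recoded to 0 and 1 (the diversity-analysis coding, distinct
#' from the -1/0/1 genomic-prediction coding).  Heterozygous founders are
#' rejected: the panel invariant is full homozygosity.
#'
#' @param panel a `founder_panel`.
#' @return Symmetric matrix with zero diagonal; two lines differing at
#'   exactly k markers are at distance sqrt(k).
#' @export
founder_distance <- function(panel) {
  if (n_ind(panel$pop) < 2) stop("need at least two founders")
  if (any(panel$pop$hap1 != panel$pop$hap2))
    stop("founder panel contains heterozygous individuals")
  d <- as.matrix(stats::dist(panel$pop$hap1, method = "euclidean"))
  dimnames(d) <- list(panel$pop$id, panel$pop$id)
  d
}

#' Hierarchical clustering of founders by Ward's method
#'
#' Agglomerates under Ward's minimum-variance criterion (`stats::hclust`,
#' method `"ward.D2"`, appropriate for Euclidean distances).
#'
#' @param distances symmetric distance matrix (e.g. [founder_distance()]).
#' @param k optional number of flat clusters to cut.
#' @return List with `tree` (an `hclust`) and, if `k` is given, `labels`
#'   (integer cluster memberships).
#' @export
ward_cluster <- function(distances, k = NULL) {
  distances <- as.matrix(distances)
  if (!isSymmetric(unname(distances), tol = 1e-8))
    stop("distance matrix must be symmetric")
  tree <- stats::hclust(stats::as.dist(distances), method = "ward.D2")
  out <- list(tree = tree)
  if (!is.null(k)) out$labels <- stats::cutree(tree, k = k)
  out
}

#' Choose crossing parents representing the panel's diversity
#'
#' The common parent is the panel medoid (minimum summed Euclidean distance
#' to all other lines, standing in for a predominant variety); the remaining
#' parents are chosen by greedy maximin distance: each next parent maximizes
#' its minimum distance to the already-selected set.  Ties are broken with
#' the current RNG.
#'
#' @param panel a `founder_panel`.
#' @param n_parents total parents to select (common parent included).
#' @return List with `common` (index of the common parent) and `others`
#'   (indices of the remaining `n_parents - 1`).
#' @export
choose_diverse_parents <- function(panel, n_parents = 7) {
  d <- founder_distance(panel)
  n <- nrow(d)
  if (n_parents > n) stop("n_parents exceeds panel size")
  pick_min <- function(v) {   # argmax with random tie-break
    w <- which(v >= max(v) - 1e-12)
    if (length(w) > 1) w <- w[sample.int(length(w), 1)]
    w
  }
  common <- {
    s <- rowSums(d)
    w <- which(s <= min(s) + 1e-12)
    if (length(w) > 1) w <- w[sample.int(length(w), 1)]
    w
  }
  sel <- common
  while (length(sel) < n_parents) {
    cand <- setdiff(seq_len(n), sel)
    mind <- apply(d[cand, sel, drop = FALSE], 1, min)
    sel <- c(sel, cand[pick_min(mind)])
  }
  list(common = common, others = sel[-1])
}
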