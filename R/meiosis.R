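#' @title Meiosis, crossing and single-seed descent
#' @name meiosis
#' @description Gametes are simulated under a no-interference crossover model:
#'   the number of crossovers on a chromosome of genetic length L cM is
#'   Poisson(L/100), crossover positions are uniform on the cM scale, and the
#'   starting parental haplotype is chosen with probability 1/2.  Chromosomes
#'   assort independently.  This is the Haldane model, so the recombination
#'   fraction between two markers d cM apart is (1 - exp(-2d/100))/2.
NULL

# Recombination patterns for n gametes: integer matrix (n x total markers),
# entry 0 = copy haplotype 1, 1 = copy haplotype 2.  Uses the current RNG.
recomb_patterns <- function(map, n) {
  ms <- map_split(map)
  m <- nrow(map)
  C <- matrix(0L, n, m)
  for (k in seq_along(ms$pos)) {
    pos <- ms$pos[[k]]
    cols <- ms$idx[[k]]
    L <- pos[length(pos)] - pos[1]
    nxo <- stats::rpois(n, L / 100)
    start <- sample.int(2L, n, replace = TRUE) - 1L
    for (i in seq_len(n)) {
      if (nxo[i] == 0L) {
        if (start[i] == 1L) C[i, cols] <- 1L
      } else {
        xo <- sort(stats::runif(nxo[i], pos[1], pos[1] + L))
        C[i, cols] <- (start[i] + findInterval(pos, xo)) %% 2L
      }
    }
  }
  C
}

# n gametes, one from each parent row given in parent_idx (recycled against n)
make_gametes <- function(pop, parent_idx, map) {
  n <- length(parent_idx)
  C <- recomb_patterns(map, n)
  H1 <- pop$hap1[parent_idx, , drop = FALSE]
  H2 <- pop$hap2[parent_idx, , drop = FALSE]
  g <- H1
  sw <- C == 1L
  g[sw] <- H2[sw]
  g
}

#' Simulate one gamete from an individual
#'
#' @param pop a [gs_pop()].
#' @param i row index of the parent individual.
#' @param map the [genetic_map()] the population conforms to.
#' @return Integer vector of 0/1 alleles, one per marker.
#' @export
simulate_gamete <- function(pop, i, map) {
  if (ncol(pop$hap1) != nrow(map))
    stop("population marker count does not match the map")
  drop(make_gametes(pop[i], 1L, map))
}

#' Cross pairs of parents
#'
#' Each of `n_progeny` offspring per cross receives one independent gamete
#' from each parent; pedigree (mother and father id) is recorded.  `mothers`
#' and `fathers` are parallel vectors of row indices defining the crosses.
#' A progeny keeps its parents' family label when both parents share one.
#'
#' @param pop a [gs_pop()] containing the parents.
#' @param mothers,fathers row indices of the parents of each cross.
#' @param map the [genetic_map()].
#' @param n_progeny offspring per cross (>= 1).
#' @param id_prefix prefix for generated progeny ids.
#' @return A [gs_pop()] of `length(mothers) * n_progeny` progeny, ordered by
#'   cross then progeny.
#' @export
cross <- function(pop, mothers, fathers, map, n_progeny = 10,
                  id_prefix = "x") {
  stopifnot(length(mothers) == length(fathers), n_progeny >= 1)
  if (ncol(pop$hap1) != nrow(map))
    stop("population marker count does not match the map")
  mi <- rep(mothers, each = n_progeny)
  fi <- rep(fathers, each = n_progeny)
  g1 <- make_gametes(pop, mi, map)
  g2 <- make_gametes(pop, fi, map)
  fam <- ifelse(!is.na(pop$family[mi]) & !is.na(pop$family[fi]) &
                  pop$family[mi] == pop$family[fi],
                pop$family[mi], NA_character_)
  gs_pop(g1, g2,
         id = sprintf("%s%03d_%02d", id_prefix,
                      rep(seq_along(mothers), each = n_progeny),
                      rep(seq_len(n_progeny), length(mothers))),
         mother = pop$id[mi], father = pop$id[fi], family = fam)
}

#' Advance lines by single-seed descent
#'
#' Each line is self-fertilized for `generations` generations, keeping a
#' single progeny per line per generation (the SSD procedure used to derive
#' recombinant inbred lines).  Heterozygosity halves per generation in
#' expectation, so an F1 advanced 5 generations is an F6 line with expected
#' residual heterozygosity (1/2)^5 ~ 3.1% at initially heterozygous loci.
#'
#' @param pop a [gs_pop()]; every line is advanced.
#' @param map the [genetic_map()].
#' @param generations number of selfing generations (>= 1).
#' @return A [gs_pop()] of the terminal individuals, ids suffixed with the
#'   generation, family labels preserved.
#' @export
ssd_advance <- function(pop, map, generations = 5) {
  stopifnot(generations >= 1)
  cur <- pop
  n <- n_ind(pop)
  for (g in seq_len(generations)) {
    h1 <- make_gametes(cur, seq_len(n), map)
    h2 <- make_gametes(cur, seq_len(n), map)
    cur <- gs_pop(h1, h2, id = sprintf("%s_s%d", pop$id, g),
                  mother = cur$id, father = cur$id, family = pop$family)
  }
  cur
}
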