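#' Populations of identified diploid individuals
#'
#' A `gs_pop` stores a set of individuals as two haplotype matrices (`hap1`,
#' `hap2`, individuals in rows, markers in columns, alleles coded 0/1)
#' together with ids, pedigree references and a family label.  Founders and
#' fully inbred lines have identical rows in the two matrices.  The marker
#' genotype code used throughout genomic prediction is
#' `hap1 + hap2 - 1`, i.e. 1 / 0 / -1 for two / one / zero copies of the
#' reference allele.
#'
#' @param hap1,hap2 integer matrices of 0/1 alleles, equal dimensions.
#' @param id character vector of individual ids (default auto-generated).
#' @param mother,father parent ids (`NA` for founders).
#' @param family family label per individual (`NA` if not applicable).
#' @return An object of class `gs_pop`.
#' @export
gs_pop <- function(hap1, hap2, id = NULL, mother = NA_character_,
                   father = NA_character_, family = NA_character_) {
  hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
  storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
  if (!identical(dim(hap1), dim(hap2)))
    stop("hap1 and hap2 must have identical dimensions")
  if (any(hap1 != 0L & hap1 != 1L) || any(hap2 != 0L & hap2 != 1L))
    stop("haplotype alleles must be coded 0/1")
  n <- nrow(hap1)
  if (is.null(id)) id <- sprintf("ind%06d", seq_len(n))
  structure(list(hap1 = hap1, hap2 = hap2,
                 id = as.character(id),
                 mother = rep_len(as.character(mother), n),
                 father = rep_len(as.character(father), n),
                 family = rep_len(as.character(family), n)),
            class = "gs_pop")
}

#' @export
print.gs_pop <- function(x, ...) {
  cat(sprintf("Population of %d individuals x %d markers (%d families)\n",
              n_ind(x), ncol(x$hap1),
              length(unique(x$family[!is.na(x$family)]))))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a [gs_pop()].
#' @return integer count.
#' @export
n_ind <- function(pop) nrow(pop$hap1)

#' Subset a population by individual index
#' @param x a [gs_pop()].
#' @param i individual (row) index.
#' @param ... ignored.
#' @return A [gs_pop()] with the selected individuals.
#' @export
`[.gs_pop` <- function(x, i, ...) {
  gs_pop(x$hap1[i, , drop = FALSE], x$hap2[i, , drop = FALSE],
         id = x$id[i], mother = x$mother[i], father = x$father[i],
         family = x$family[i])
}

#' Concatenate populations over the same marker panel
#' @param ... [gs_pop()] objects.
#' @return A single [gs_pop()].
#' @export
pop_bind <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && is.list(ps[[1]]) && !inherits(ps[[1]], "gs_pop"))
    ps <- ps[[1]]
  m <- unique(vapply(ps, function(p) ncol(p$hap1), integer(1)))
  if (length(m) != 1L) stop("populations have different marker counts")
  gs_pop(do.call(rbind, lapply(ps, `[[`, "hap1")),
         do.call(rbind, lapply(ps, `[[`, "hap2")),
         id = unlist(lapply(ps, `[[`, "id")),
         mother = unlist(lapply(ps, `[[`, "mother")),
         father = unlist(lapply(ps, `[[`, "father")),
         family = unlist(lapply(ps, `[[`, "family")))
}

#' Marker genotype codes of a population
#'
#' @param pop a [gs_pop()].
#' @return Integer matrix (individuals x markers) with codes 1, 0, -1 for
#'   two, one and zero copies of the reference allele.
#' @export
genotypes <- function(pop) {
  g <- pop$hap1 + pop$hap2 - 1L
  rownames(g) <- pop$id
  g
}

#' Per-individual heterozygosity
#'
#' @param pop a [gs_pop()].
#' @return Numeric vector: for each individual, the proportion of markers at
#'   which its two haplotypes differ.
#' @export
heterozygosity <- function(pop) {
  rowMeans(pop$hap1 != pop$hap2)
}
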