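# Small in-code fixtures shared across test files.

# compact map: 4 chromosomes, irregular spacing
mini_map <- function(n_markers = 240, n_chrom = 4, seed = 424) {
  set.seed(seed)
  synthetic_map(n_markers, n_chrom, chrom_length = seq(120, 60,
                                                       length.out = n_chrom))
}

mini_panel <- function(n_founders = 30, map = mini_map(), seed = 425) {
  set.seed(seed)
  generate_founders(n_founders, map)
}

# a replicate setup at desk scale: 6 families of 30 lines, 20 QTL
mini_setup <- function(seed = 426, panel = mini_panel(), n_lines = 30,
                       subpop_size = 5, n_qtl = 20, effective_n = 8) {
  replicate_setup(panel, seed, n_lines = n_lines, subpop_size = subpop_size,
                  n_qtl = n_qtl, effective_n = effective_n)
}

# fully homozygous two-line toy population over a map
inbred_pair <- function(map, seed = 427) {
  set.seed(seed)
  m <- nrow(map)
  h1 <- matrix(rbinom(m, 1, 0.5), 1)
  h2 <- matrix(rbinom(m, 1, 0.5), 1)
  gs_pop(rbind(h1, h2), rbind(h1, h2), id = c("A", "B"))
}
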