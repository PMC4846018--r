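#' Export a founder panel as a genotype CSV
#'
#' Lines as rows (ids in the first column), markers as columns, homozygous
#' genotype codes -1/1 (the panel invariant is full homozygosity, so 0 never
#' occurs).
#'
#' @param panel a `founder_panel`.
#' @param path output file.
#' @export
export_founders_csv <- function(panel, path) {
  g <- genotypes(panel$pop)
  colnames(g) <- panel$map$marker
  df <- data.frame(id = panel$pop$id, g, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a founder panel as a plain-text VCF
#'
#' Writes a minimal VCF 4.2 with one homozygous GT call (`0/0` or `1/1`)
#' per founder; positions come from the map's `pos_bp` (or are derived from
#' cM at 250 kb/cM when absent).
#'
#' @param panel a `founder_panel`.
#' @param path output file (uncompressed `.vcf`).
#' @export
export_founders_vcf <- function(panel, path) {
  map <- panel$map
  bp <- if (!is.null(map$pos_bp)) map$pos_bp else round(map$pos_cM * 250000) + 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=islandGS",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$pop$id), collapse = "\t")),
             con)
  gt <- ifelse(panel$pop$hap1 == 1L, "1/1", "0/0")
  for (j in seq_len(nrow(map))) {
    writeLines(paste(c(map$chrom[j], bp[j], map$marker[j], "A", "T", ".",
                       "PASS", ".", "GT", gt[, j]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Import a founder panel from CSV or VCF
#'
#' CSV: lines as rows (first column ids), markers as columns, codes -1/0/1;
#' any heterozygous (0) code is rejected.  VCF (parsed with `vcfR`): only
#' biallelic SNPs with homozygous calls are accepted; heterozygous or
#' multiallelic records are rejected with their identities (first 10
#' listed).  For CSV a genetic map covering the marker columns is required;
#' for VCF the map defaults to chromosome/position from the file with cM
#' derived at 250 kb/cM.
#'
#' @param path input file.
#' @param format `"csv"` or `"vcf"`.
#' @param map optional [genetic_map()]; required for CSV.
#' @return A `founder_panel`.
#' @export
import_founders <- function(path, format = c("csv", "vcf"), map = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    if (is.null(map)) stop("CSV import requires a genetic map")
    df <- utils::read.csv(path, check.names = FALSE)
    ids <- as.character(df[[1]])
    g <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(g) <- "integer"
    if (ncol(g) != nrow(map))
      stop("genotype columns (", ncol(g), ") do not match map markers (",
           nrow(map), ")")
    bad <- which(g == 0L, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      show <- utils::head(sprintf("line %s at marker %s", ids[bad[, 1]],
                                  colnames(g)[bad[, 2]]), 10)
      stop("heterozygous genotypes are not allowed in a founder panel:\n  ",
           paste(show, collapse = "\n  "))
    }
    if (any(g != 1L & g != -1L)) stop("genotype codes must be in {-1, 0, 1}")
    hap <- (g + 1L) %/% 2L
    pop <- gs_pop(hap, hap, id = ids)
    return(structure(list(pop = pop, map = map, cluster = NULL),
                     class = "founder_panel"))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- which(nchar(fix[, "ALT"]) != 1 | grepl(",", fix[, "ALT"]))
  if (length(multi) > 0)
    stop("multiallelic records rejected:\n  ",
         paste(utils::head(fix[multi, "ID"], 10), collapse = "\n  "))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  het <- which(is.na(gt) | !(gt == "0/0" | gt == "1/1"), arr.ind = TRUE)
  if (nrow(het) > 0) {
    show <- utils::head(sprintf("record %s sample %s",
                                rownames(gt)[het[, 1]],
                                colnames(gt)[het[, 2]]), 10)
    stop("heterozygous or missing founder calls rejected:\n  ",
         paste(show, collapse = "\n  "))
  }
  hap <- t(ifelse(gt == "1/1", 1L, 0L))
  if (is.null(map)) {
    bp <- as.numeric(fix[, "POS"])
    map <- genetic_map(fix[, "ID"], fix[, "CHROM"],
                       pos_cM = stats::ave(bp, fix[, "CHROM"],
                                           FUN = function(x) (x - min(x)) / 250000),
                       pos_bp = bp)
  }
  if (ncol(hap) != nrow(map)) stop("VCF records do not match map markers")
  # reorder columns to map order
  hap <- hap[, match(map$marker, fix[, "ID"]), drop = FALSE]
  pop <- gs_pop(hap, hap, id = rownames(hap))
  structure(list(pop = pop, map = map, cluster = NULL),
            class = "founder_panel")
}
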