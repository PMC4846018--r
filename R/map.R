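#' Genetic map of a marker panel
#'
#' A genetic map holds, for every marker of the panel, its chromosome and its
#' genetic position in centimorgans (cM), optionally with a physical position
#' in base pairs.  The map drives recombination in [simulate_gamete()] and all
#' downstream crossing operations: crossovers are placed on the cM scale, so
#' marker spacing in cM determines recombination fractions.
#'
#' @param marker character vector of unique marker ids.
#' @param chrom chromosome id per marker (coerced to character).
#' @param pos_cM genetic position per marker, nonnegative, nondecreasing
#'   within each chromosome.
#' @param pos_bp optional physical position per marker (1-based).
#' @return An object of class `genetic_map`: a data frame with columns
#'   `marker`, `chrom`, `pos_cM` and optionally `pos_bp`, ordered by
#'   chromosome then position, with row order defining the marker index used
#'   by every haplotype in the package.
#' @seealso [read_genetic_map()], [synthetic_map()]
#' @export
genetic_map <- function(marker, chrom, pos_cM, pos_bp = NULL) {
  marker <- as.character(marker)
  chrom <- as.character(chrom)
  pos_cM <- as.numeric(pos_cM)
  n <- length(marker)
  if (length(chrom) != n || length(pos_cM) != n)
    stop("marker, chrom and pos_cM must have equal length")
  if (anyDuplicated(marker))
    stop("marker ids must be unique")
  if (any(!is.finite(pos_cM)) || any(pos_cM < 0))
    stop("genetic positions must be finite and nonnegative")
  df <- data.frame(marker = marker, chrom = chrom, pos_cM = pos_cM,
                   stringsAsFactors = FALSE)
  if (!is.null(pos_bp)) {
    if (length(pos_bp) != n) stop("pos_bp must match marker length")
    df$pos_bp <- as.numeric(pos_bp)
  }
  # preserve first-appearance chromosome order, sort by position within
  df$chrom <- factor(df$chrom, levels = unique(df$chrom))
  ord <- order(as.integer(df$chrom), df$pos_cM)
  df <- df[ord, , drop = FALSE]
  df$chrom <- as.character(df$chrom)
  rownames(df) <- NULL
  for (cc in unique(df$chrom)) {
    p <- df$pos_cM[df$chrom == cc]
    if (is.unsorted(p)) stop("positions not sortable within chromosome ", cc)
  }
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("Genetic map: %d markers on %d chromosomes, %.1f cM total\n",
              nrow(x), length(unique(x$chrom)), sum(map_lengths(x))))
  invisible(x)
}

n_markers <- function(map) nrow(map)

#' Chromosome lengths of a genetic map
#'
#' @param map a [genetic_map()].
#' @return Named numeric vector: per-chromosome marker span in cM.
#' @export
map_lengths <- function(map) {
  vapply(split(map$pos_cM, factor(map$chrom, levels = unique(map$chrom))),
         function(p) max(p) - min(p), numeric(1))
}

# per-chromosome marker index and position list, cached shape used by meiosis
map_split <- function(map) {
  chr <- factor(map$chrom, levels = unique(map$chrom))
  idx <- split(seq_len(nrow(map)), chr)
  pos <- split(map$pos_cM, chr)
  list(idx = idx, pos = pos)
}

#' Read a genetic map from a tab-delimited file
#'
#' Expects a header row and columns `marker_id`, `chrom`, `cM` and optionally
#' `bp`.
#'
#' @param path file path.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "cM")
  if (!all(need %in% names(df)))
    stop("map file must have columns marker_id, chrom, cM (and optional bp)")
  genetic_map(df$marker_id, df$chrom, df$cM,
              pos_bp = if ("bp" %in% names(df)) df$bp else NULL)
}

#' Write a genetic map to a tab-delimited file
#'
#' @param map a [genetic_map()].
#' @param path file path.
#' @export
write_genetic_map <- function(map, path) {
  out <- data.frame(marker_id = map$marker, chrom = map$chrom, cM = map$pos_cM)
  if (!is.null(map$pos_bp)) out$bp <- map$pos_bp
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic genetic map
#'
#' Builds a map emulating a rice-like genome: by default 3,102 markers spread
#' over 12 chromosomes totalling about 1,550 cM.  Marker counts are split
#' proportionally to chromosome length and positions are drawn uniformly
#' within each chromosome (sorted), giving realistic irregular spacing.
#' Uses the current RNG state.
#'
#' @param n_markers total number of markers.
#' @param n_chrom number of chromosomes.
#' @param chrom_length numeric vector of chromosome lengths in cM (recycled to
#'   `n_chrom`); default lengths decline from ~180 to ~80 cM as in compact
#'   cereal genomes.
#' @return A [genetic_map()] with `pos_bp` filled at ~250 kb/cM.
#' @export
synthetic_map <- function(n_markers = 3102, n_chrom = 12, chrom_length = NULL) {
  if (is.null(chrom_length))
    chrom_length <- seq(180, 80, length.out = n_chrom)
  chrom_length <- rep_len(chrom_length, n_chrom)
  n_per <- floor(n_markers * chrom_length / sum(chrom_length))
  rem <- n_markers - sum(n_per)
  if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1L
  marker <- character(0); chrom <- character(0); pos <- numeric(0)
  for (i in seq_len(n_chrom)) {
    p <- sort(stats::runif(n_per[i], 0, chrom_length[i]))
    p <- p - p[1]  # 0-based at the first marker
    chrom <- c(chrom, rep(sprintf("chr%02d", i), n_per[i]))
    pos <- c(pos, p)
    marker <- c(marker, sprintf("m%02d_%04d", i, seq_len(n_per[i])))
  }
  genetic_map(marker, chrom, pos, pos_bp = round(pos * 250000) + 1)
}

#' Estimate genetic positions from physical positions by polynomial regression
#'
#' Fits, independently per chromosome, a polynomial regression of known
#' linkage-map positions (cM) on physical positions (bp) and evaluates it at
#' query physical positions.  Because a raw polynomial fit need not be
#' monotone, fitted positions are monotonized by a running maximum after
#' sorting queries by bp; negative fitted positions are shifted to 0 with a
#' warning.
#'
#' @param anchors data frame with columns `chrom`, `bp`, `cM`: markers with
#'   known positions on both maps.
#' @param query data frame with columns `chrom`, `bp`: positions to estimate.
#' @param degree polynomial degree (small positive integer).
#' @return Numeric vector of estimated cM positions, parallel to `query` rows.
#' @examples
#' anchors <- data.frame(chrom = "1", bp = c(0, 250e3, 1e6),
#'                       cM = c(0, 1, 4))
#' estimate_genetic_positions(anchors,
#'   data.frame(chrom = "1", bp = 500e3), degree = 1)
#' @export
estimate_genetic_positions <- function(anchors, query, degree = 3) {
  stopifnot(is.data.frame(anchors), is.data.frame(query),
            degree >= 1, degree == round(degree))
  out <- rep(NA_real_, nrow(query))
  for (cc in unique(as.character(query$chrom))) {
    a <- anchors[as.character(anchors$chrom) == cc, , drop = FALSE]
    if (nrow(a) < degree + 1)
      stop("too few anchors on chromosome ", cc,
           " (need at least ", degree + 1, ")")
    if (anyDuplicated(a$bp)) stop("anchor bp positions must be distinct on ",
                                  "chromosome ", cc)
    fit <- stats::lm(cM ~ stats::poly(bp, degree = degree, raw = TRUE),
                     data = a)
    qi <- which(as.character(query$chrom) == cc)
    pred <- stats::predict(fit, newdata = data.frame(bp = query$bp[qi]))
    # monotonize along physical order
    ord <- order(query$bp[qi])
    pred[ord] <- cummax(pred[ord])
    if (any(pred < 0)) {
      warning("negative fitted genetic positions on chromosome ", cc,
              " shifted to 0")
      pred[pred < 0] <- 0
    }
    out[qi] <- pred
  }
  out
}
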