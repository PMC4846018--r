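#' Realized additive relationship matrix
#'
#' VanRaden-style centered cross-product: columns monomorphic within the
#' reference rows are dropped, the remaining -1/0/1 codes are centered on the
#' reference-row column means, and K = W W' / c with
#' c = sum_j 2 p_j (1 - p_j), p_j the reference-row allele frequency.  A
#' jitter of 1e-6 is added to the diagonal for numerical positive
#' definiteness.
#'
#' @param geno matrix of -1/0/1 genotype codes (individuals x markers),
#'   already restricted to the marker set the model may use (e.g. non-QTL
#'   markers).
#' @param reference row indices used for monomorphy screening, centering and
#'   scaling (default: all rows).
#' @return The relationship matrix, with attributes `cols` (retained column
#'   indices into `geno`), `centers` (training column means) and `scale_c`
#'   (the denominator c).
#' @export
additive_relationship <- function(geno, reference = seq_len(nrow(geno))) {
  geno <- as.matrix(geno)
  if (length(reference) == 0) stop("reference row set is empty")
  ref <- geno[reference, , drop = FALSE]
  keep <- which(col_var(ref) > 0)
  if (length(keep) == 0) stop("all markers are monomorphic in the reference rows")
  centers <- colMeans(ref[, keep, drop = FALSE])
  p <- (centers + 1) / 2
  cc <- sum(2 * p * (1 - p))
  W <- sweep(geno[, keep, drop = FALSE], 2, centers)
  K <- tcrossprod(W) / cc
  diag(K) <- diag(K) + 1e-6
  rownames(K) <- colnames(K) <- rownames(geno)
  attr(K, "cols") <- keep
  attr(K, "centers") <- centers
  attr(K, "scale_c") <- cc
  K
}

col_var <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  cm <- colMeans(x)
  (colSums(x^2) - n * cm^2) / (n - 1)
}

#' Fit a G-BLUP genomic prediction model
#'
#' Fits the mixed model y = 1 beta + u + e with Var(u) = K sigma_u^2 and
#' identity residual covariance Var(e) = I sigma_e^2, by REML profiled over
#' the variance ratio lambda = sigma_u^2 / sigma_e^2 via the spectral
#' decomposition of the projected relationship matrix.  The fit is
#' deterministic given its input.
#'
#' Either supply a precomputed relationship matrix `K`, or supply the
#' training genotype matrix `genotypes` (codes -1/0/1 over the full marker
#' panel) plus `exclude` (marker columns to withhold, e.g. QTL positions);
#' in the latter case K is built with [additive_relationship()] after
#' monomorphy screening on the training rows, and the model can later score
#' candidates directly from their genotype codes.
#'
#' @param y numeric vector of training phenotypes.
#' @param genotypes optional training genotype matrix (rows = lines).
#' @param exclude optional marker column indices excluded from K (QTL).
#' @param K optional precomputed relationship matrix.
#' @return An object of class `gblup` with components `beta`, `u` (training
#'   BLUPs), `sigma2_u`, `sigma2_e`, `lambda`, `alpha` (K^-1 u, the
#'   prediction weights), and marker bookkeeping when fitted from genotypes.
#' @seealso [predict.gblup()], [update.gblup()]
#' @export
gblup <- function(y, genotypes = NULL, exclude = NULL, K = NULL) {
  cl <- match.call()
  y <- as.numeric(y)
  n <- length(y)
  if (stats::var(y) == 0) stop("zero phenotypic variance")
  marker_cols <- NULL
  if (is.null(K)) {
    if (is.null(genotypes)) stop("supply either K or genotypes")
    genotypes <- as.matrix(genotypes)
    if (nrow(genotypes) != n) stop("genotypes rows must match length(y)")
    marker_cols <- setdiff(seq_len(ncol(genotypes)), exclude)
    K <- additive_relationship(genotypes[, marker_cols, drop = FALSE])
  } else {
    if (nrow(K) != n || ncol(K) != n) stop("K must be n x n")
  }

  # REML via eigen-decomposition of the double-centered K (X = intercept)
  rk <- rowMeans(K)
  SKS <- K - outer(rk, rep(1, n)) - outer(rep(1, n), rk) + mean(K)
  eg <- eigen(SKS, symmetric = TRUE)
  theta <- eg$values[seq_len(n - 1)]
  theta[theta < 0] <- 0
  U <- eg$vectors[, seq_len(n - 1), drop = FALSE]
  eta2 <- drop(crossprod(U, y))^2
  crit <- function(t) {
    lam <- exp(t)
    d <- lam * theta + 1
    (n - 1) * log(sum(eta2 / d)) + sum(log(d))
  }
  opt <- stats::optimize(crit, interval = log(c(1e-9, 1e9)), tol = 1e-9)
  lambda <- exp(opt$minimum)
  d <- lambda * theta + 1
  sigma2_e <- sum(eta2 / d) / (n - 1)
  sigma2_u <- lambda * sigma2_e

  H <- lambda * K
  diag(H) <- diag(H) + 1
  ch <- tryCatch(chol(H), error = function(e)
    stop("relationship matrix is not positive semidefinite after jitter"))
  Hi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Hi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  beta <- sum(Hi_y) / sum(Hi_1)
  alpha <- lambda * (Hi_y - beta * Hi_1)
  u <- drop(K %*% alpha)

  fit <- structure(list(
    call = cl, y = y, n = n, beta = beta, u = u, alpha = alpha,
    sigma2_u = sigma2_u, sigma2_e = sigma2_e, lambda = lambda,
    reml_criterion = opt$objective, K = K,
    train_ids = rownames(K)), class = "gblup")
  if (!is.null(marker_cols)) {
    keep <- attr(K, "cols")
    fit$marker_cols <- marker_cols            # columns available to the model
    fit$retained <- marker_cols[keep]         # after monomorphy screening
    fit$centers <- attr(K, "centers")
    fit$scale_c <- attr(K, "scale_c")
    fit$exclude <- exclude
    fit$train_geno <- genotypes
    W <- sweep(genotypes[, fit$retained, drop = FALSE], 2, fit$centers)
    fit$marker_effects <- drop(crossprod(W, alpha)) / fit$scale_c
  }
  fit
}

#' @export
print.gblup <- function(x, ...) {
  cat("G-BLUP model\n")
  cat(sprintf("  n = %d training lines%s\n", x$n,
              if (!is.null(x$retained))
                sprintf(", %d markers retained", length(x$retained)) else ""))
  cat(sprintf("  sigma2_u = %.4g, sigma2_e = %.4g (lambda = %.4g)\n",
              x$sigma2_u, x$sigma2_e, x$lambda))
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  out <- list(
    n = object$n,
    sigma2_u = object$sigma2_u,
    sigma2_e = object$sigma2_e,
    lambda = object$lambda,
    beta = object$beta,
    genomic_h2 = object$sigma2_u * mean(diag(object$K)) /
      (object$sigma2_u * mean(diag(object$K)) + object$sigma2_e),
    n_retained = if (!is.null(object$retained)) length(object$retained)
                 else NA_integer_,
    reml_criterion = object$reml_criterion)
  class(out) <- "summary.gblup"
  out
}

#' @export
print.summary.gblup <- function(x, ...) {
  cat("G-BLUP model summary\n")
  cat(sprintf("  training lines:     %d\n", x$n))
  if (!is.na(x$n_retained))
    cat(sprintf("  retained markers:   %d\n", x$n_retained))
  cat(sprintf("  intercept:          %.4f\n", x$beta))
  cat(sprintf("  sigma2_u:           %.4f\n", x$sigma2_u))
  cat(sprintf("  sigma2_e:           %.4f\n", x$sigma2_e))
  cat(sprintf("  variance ratio:     %.4f\n", x$lambda))
  cat(sprintf("  genomic h2 (appx):  %.4f\n", x$genomic_h2))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) c(intercept = object$beta)

#' @export
fitted.gblup <- function(object, ...) object$beta + object$u

#' @export
residuals.gblup <- function(object, ...) object$y - fitted(object)

#' Random-effect (breeding value) solutions of a G-BLUP fit
#' @param object a fitted [gblup()] model.
#' @param ... ignored.
#' @return Numeric vector of training-line BLUPs.
#' @export
ranef_gblup <- function(object, ...) object$u

#' Predict genomic estimated breeding values for candidates
#'
#' Candidate GEBVs are the conditional expectation
#' K_cross K_train^-1 u = K_cross alpha, equivalent to carrying the
#' candidates as unobserved levels in the joint mixed model.  When the model
#' was fitted from genotypes, `newdata` is a candidate genotype matrix over
#' the same full marker panel and K_cross is formed internally with the
#' training marker set, training centering and training scaling (this equals
#' scoring candidates with ridge marker effects).  Alternatively pass a
#' precomputed `K_cross` (candidates x training).
#'
#' @param object a fitted [gblup()] model.
#' @param newdata candidate genotype matrix (codes -1/0/1, full panel width).
#' @param K_cross candidate-by-training relationship block.
#' @param ... ignored.
#' @return Numeric vector of predicted values (intercept + GEBV).
#' @export
predict.gblup <- function(object, newdata = NULL, K_cross = NULL, ...) {
  if (is.null(newdata) && is.null(K_cross)) return(fitted(object))
  if (!is.null(K_cross)) {
    if (ncol(K_cross) != object$n) stop("K_cross must have n training columns")
    return(object$beta + drop(K_cross %*% object$alpha))
  }
  if (is.null(object$retained))
    stop("model was fitted from K only; supply K_cross")
  newdata <- as.matrix(newdata)
  if (max(object$retained) > ncol(newdata))
    stop("candidate genotype matrix does not cover the training marker set")
  W <- sweep(newdata[, object$retained, drop = FALSE], 2, object$centers)
  object$beta + drop(W %*% object$marker_effects)
}

#' Update a G-BLUP model with newly phenotyped lines
#'
#' Refits on the concatenation of the original training set and the new
#' lines; monomorphy screening, centering and scaling are redone on the
#' combined set.
#'
#' @param object a [gblup()] model fitted from genotypes.
#' @param y_new phenotypes of the new lines.
#' @param genotypes_new genotype matrix of the new lines (full panel width),
#'   rownames used as line ids.
#' @param ... ignored.
#' @return A refitted `gblup` model.
#' @export
update.gblup <- function(object, y_new = numeric(0), genotypes_new = NULL,
                         ...) {
  if (is.null(object$train_geno))
    stop("model was fitted from K only; cannot update")
  if (length(y_new) == 0)
    return(gblup(object$y, genotypes = object$train_geno,
                 exclude = object$exclude))
  genotypes_new <- as.matrix(genotypes_new)
  if (nrow(genotypes_new) != length(y_new))
    stop("genotypes_new rows must match length(y_new)")
  ids <- c(rownames(object$train_geno), rownames(genotypes_new))
  if (!is.null(ids) && anyDuplicated(stats::na.omit(ids)))
    stop("duplicate line ids between training sets")
  gblup(c(object$y, y_new),
        genotypes = rbind(object$train_geno, genotypes_new),
        exclude = object$exclude)
}
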