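# simulate a training set of inbred-like lines with a genomic trait
sim_training <- function(n, m, h2 = 0.6, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  g <- matrix(2L * rbinom(n * m, 1, rep(p, each = n)) - 1L, n, m)
  rownames(g) <- sprintf("L%04d", seq_len(n))
  eff <- rnorm(m, 0, sqrt(h2 / (m * mean(2 * p * (1 - p)))))
  gv <- drop(g %*% eff)
  gv <- gv * sqrt(h2) / sd(gv)
  y <- gv + rnorm(n, 0, sqrt(1 - h2))
  list(g = g, y = y, gv = gv)
}

test_that("relationship matrix matches a brute-force double loop", {
  set.seed(31)
  g <- matrix(sample(c(-1L, 0L, 1L), 100, replace = TRUE), 5, 20)
  K <- additive_relationship(g)
  keep <- attr(K, "cols")
  p <- colMeans((g[, keep] + 1) / 2)
  cc <- sum(2 * p * (1 - p))
  Kbf <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    s <- 0
    for (k in seq_along(keep)) {
      ck <- keep[k]
      s <- s + (g[i, ck] - (2 * p[k] - 1)) * (g[j, ck] - (2 * p[k] - 1))
    }
    Kbf[i, j] <- s / cc
  }
  expect_equal(matrix(K, 5, 5) - diag(1e-6, 5), Kbf, tolerance = 1e-12)
})

test_that("relationship matrix screens monomorphic markers and handles duplicates", {
  set.seed(32)
  g <- matrix(sample(c(-1L, 1L), 80, replace = TRUE), 4, 20)
  g[, 1:3] <- 1L                       # monomorphic columns
  g[4, ] <- g[3, ]                     # duplicated line
  K <- additive_relationship(g)
  expect_equal(attr(K, "cols"), which(apply(g, 2, var) > 0))
  expect_false(any(1:3 %in% attr(K, "cols")))
  expect_equal(K[3, 4], K[3, 3] - 1e-6, tolerance = 1e-12)
  expect_equal(K[3, 4], K[4, 4] - 1e-6, tolerance = 1e-12)
  expect_error(additive_relationship(matrix(1L, 3, 5)), "monomorphic")
})

test_that("G-BLUP equals ridge regression on the marker effects", {
  for (s in 1:5) {
    d <- sim_training(60, 150, seed = 40 + s)
    fit <- gblup(d$y, genotypes = d$g)
    # independent primal-ridge oracle on the centered marker matrix
    W <- sweep(d$g[, fit$retained], 2, fit$centers)
    lam_r <- fit$sigma2_e / fit$sigma2_u * fit$scale_c
    r <- d$y - fit$beta
    m_hat <- solve(crossprod(W) + diag(lam_r, ncol(W)), crossprod(W, r))
    u_ridge <- drop(W %*% m_hat)
    # jitter on K perturbs at the 1e-6 level
    expect_equal(fit$u, u_ridge, tolerance = 1e-4)
    expect_equal(fit$marker_effects, drop(m_hat), tolerance = 1e-4)
  }
})

test_that("REML shrinks towards the intercept for pure-noise phenotypes", {
  ratios <- vapply(1:5, function(s) {
    set.seed(50 + s)
    g <- matrix(2L * rbinom(100 * 400, 1, 0.5) - 1L, 100, 400)
    y <- rnorm(100)
    fit <- gblup(y, genotypes = g)
    fit$sigma2_u / fit$sigma2_e
  }, numeric(1))
  expect_lt(median(ratios), 0.3)
})

test_that("candidate prediction interpolates training lines and matches both routes", {
  d <- sim_training(80, 200, seed = 61)
  fit <- gblup(d$y, genotypes = d$g)
  # a candidate genotypically identical to a training line gets its BLUP
  cand <- d$g[c(7, 33), , drop = FALSE]
  pred <- predict(fit, newdata = cand)
  expect_equal(unname(pred - fit$beta), unname(fit$u[c(7, 33)]),
               tolerance = 1e-3)
  # marker-effect route equals the K_cross conditional-expectation route
  W_c <- sweep(cand[, fit$retained], 2, fit$centers)
  W_t <- sweep(d$g[, fit$retained], 2, fit$centers)
  K_cross <- tcrossprod(W_c, W_t) / fit$scale_c
  expect_equal(unname(pred), unname(predict(fit, K_cross = K_cross)),
               tolerance = 1e-10)
  expect_error(predict(fit, newdata = cand[, 1:10]), "marker set")
})

test_that("REML fit validates its inputs", {
  expect_error(gblup(rep(1, 10), K = diag(10)), "zero phenotypic variance")
  d <- sim_training(20, 50, seed = 62)
  expect_error(gblup(d$y[1:20], K = diag(5)), "n x n")
  expect_error(gblup(d$y, genotypes = d$g[1:10, ]), "rows must match")
})

test_that("model methods are coherent", {
  d <- sim_training(50, 120, seed = 63)
  fit <- gblup(d$y, genotypes = d$g)
  expect_equal(fitted(fit), fit$beta + fit$u)
  expect_equal(residuals(fit), d$y - fitted(fit))
  expect_equal(unname(coef(fit)), fit$beta)
  expect_output(print(fit), "G-BLUP")
  s <- summary(fit)
  expect_s3_class(s, "summary.gblup")
  expect_equal(s$n, 50)
})

test_that("updating with new lines refits on the concatenated training set", {
  d <- sim_training(60, 150, seed = 64)
  fit <- gblup(d$y, genotypes = d$g)
  same <- update(fit, y_new = numeric(0))
  expect_equal(same$u, fit$u, tolerance = 1e-10)
  expect_equal(same$sigma2_u, fit$sigma2_u, tolerance = 1e-10)

  d2 <- sim_training(20, 150, seed = 65)
  rownames(d2$g) <- sprintf("N%04d", 1:20)
  fit2 <- update(fit, y_new = d2$y, genotypes_new = d2$g)
  expect_equal(fit2$n, 80)
  # duplicate ids are rejected
  dup <- d2$g; rownames(dup) <- rownames(d$g)[1:20]
  expect_error(update(fit, y_new = d2$y, genotypes_new = dup), "duplicate")
})

test_that("updating with lines from a drifted generation does not hurt accuracy there", {
  deltas <- vapply(1:10, function(s) {
    set.seed(70 + s)
    map <- synthetic_map(300, 3)
    panel <- generate_founders(16, map)
    setup <- replicate_setup(panel, 700 + s, n_parents = 4, n_lines = 30,
                             subpop_size = 10, n_qtl = 20, effective_n = 8)
    # advance the training lines several cycles of random mating to drift
    pop <- pop_bind(setup$families)
    set.seed(7000 + s)
    for (i in 1:3) {
      idx <- sample(n_ind(pop), 30)
      pop <- cross(pop, idx[1:15], idx[16:30], map, n_progeny = 8)
    }
    newly <- pop[1:60]
    holdout <- pop[61:120]
    y_new <- phenotype(newly, setup$arch)
    gv_h <- genotypic_value(holdout, setup$arch)
    acc_old <- cor(predict(setup$model, newdata = genotypes(holdout)), gv_h)
    upd <- update(setup$model, y_new = y_new,
                  genotypes_new = genotypes(newly))
    acc_new <- cor(predict(upd, newdata = genotypes(holdout)), gv_h)
    acc_new - acc_old
  }, numeric(1))
  expect_gte(median(deltas), 0)
})
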