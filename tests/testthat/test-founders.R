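test_that("generated founder panels have the configured shape and are fully inbred", {
  set.seed(7)
  map <- synthetic_map(500, 12)
  panel <- generate_founders(112, map)
  expect_equal(n_ind(panel$pop), 112)
  expect_equal(ncol(panel$pop$hap1), 500)
  expect_equal(length(unique(map$chrom)), 12)
  expect_true(all(heterozygosity(panel$pop) == 0))
  expect_error(generate_founders(10, map, n_ancestors = 1), "n_ancestors")
})

test_that("single-ancestry founders are identical (no polymorphism without admixture)", {
  map <- mini_map()
  # cluster_bias = 1 pins every segment to the home ancestor, so founders
  # sharing a home ancestor are copies of that ancestral haplotype
  set.seed(9)
  p2 <- generate_founders(6, map, n_ancestors = 2, cluster_bias = 1)
  for (cl in unique(p2$cluster)) {
    rows <- which(p2$cluster == cl)
    if (length(rows) > 1) {
      ref <- p2$pop$hap1[rows[1], ]
      for (r in rows[-1])
        expect_identical(unname(p2$pop$hap1[r, ]), unname(ref))
    }
  }
})

test_that("linkage disequilibrium decays with genetic distance", {
  map <- mini_map(300, 2)
  near <- numeric(0); far <- numeric(0)
  for (s in 1:20) {
    set.seed(500 + s)
    panel <- generate_founders(40, map)
    g <- genotypes(panel$pop)
    v <- apply(g, 2, var)
    poly <- which(v > 0)
    pos <- map$pos_cM[poly]; chr <- map$chrom[poly]
    cors <- abs(cor(g[, poly]))
    pairs <- which(upper.tri(cors), arr.ind = TRUE)
    same <- chr[pairs[, 1]] == chr[pairs[, 2]]
    d <- abs(pos[pairs[, 1]] - pos[pairs[, 2]])
    near <- c(near, mean(cors[pairs[same & d < 2, , drop = FALSE]]))
    far <- c(far, mean(cors[pairs[same & d > 50, , drop = FALSE]]))
  }
  expect_gt(mean(near), mean(far))
})

test_that("founder Euclidean distances use the 0/1 recoding", {
  map <- mini_map()
  m <- nrow(map)
  h <- matrix(0L, 3, m)
  h[2, 1:9] <- 1L           # differs from line 1 at exactly 9 markers
  h[3, ] <- 1L
  panel <- structure(list(pop = gs_pop(h, h), map = map, cluster = NULL),
                     class = "founder_panel")
  d <- founder_distance(panel)
  expect_equal(unname(d[1, 2]), sqrt(9))
  expect_equal(unname(d[1, 3]), sqrt(m))
  expect_identical(unname(d), unname(t(d)))
  expect_true(all(diag(d) == 0))
  # heterozygous founders violate the panel invariant
  hh <- h; hh2 <- h; hh2[1, 1] <- 1L
  bad <- structure(list(pop = gs_pop(hh, hh2), map = map, cluster = NULL),
                   class = "founder_panel")
  expect_error(founder_distance(bad), "heterozygous")
})

test_that("Ward clustering recovers planted structure and handles edge cases", {
  set.seed(10)
  blob1 <- matrix(rnorm(40, 0), 20, 2)
  blob2 <- matrix(rnorm(40, 8), 20, 2)
  d <- as.matrix(dist(rbind(blob1, blob2)))
  cl <- ward_cluster(d, k = 2)
  expect_equal(length(unique(cl$labels[1:20])), 1)
  expect_equal(length(unique(cl$labels[21:40])), 1)
  expect_true(cl$labels[1] != cl$labels[40])
  # n = 2: a single merge at their distance
  d2 <- as.matrix(dist(rbind(c(0, 0), c(3, 4))))
  cl2 <- ward_cluster(d2)
  expect_equal(nrow(cl2$tree$merge), 1)
  expect_equal(cl2$tree$height, 5)
  # duplicate points merge first (zero height)
  d3 <- as.matrix(dist(rbind(c(0, 0), c(0, 0), c(9, 9))))
  cl3 <- ward_cluster(d3)
  expect_equal(cl3$tree$height[1], 0)
  expect_error(ward_cluster(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("diverse-parent choice picks the medoid plus a maximin set", {
  panel <- mini_panel()
  set.seed(11)
  sel <- choose_diverse_parents(panel, n_parents = 7)
  expect_length(sel$others, 6)
  expect_false(sel$common %in% sel$others)
  d <- founder_distance(panel)
  expect_equal(unname(sel$common),
               unname(which.min(rowSums(d))))
  # selecting as many parents as founders returns everyone
  small <- mini_panel(7, seed = 430)
  set.seed(12)
  all7 <- choose_diverse_parents(small, n_parents = 7)
  expect_setequal(c(all7$common, all7$others), 1:7)

  # maximin beats random sets of the same size
  wins <- 0
  for (s in 1:5) {
    set.seed(600 + s)
    sel <- choose_diverse_parents(panel, n_parents = 7)
    chosen <- c(sel$common, sel$others)
    mind <- min(d[chosen, chosen][upper.tri(diag(7))])
    rnd <- replicate(200, {
      r <- sample(n_ind(panel$pop), 7)
      min(d[r, r][upper.tri(diag(7))])
    })
    if (mind >= max(rnd)) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("polymorphic-marker fraction is reported", {
  panel <- mini_panel()
  pf <- polymorphic_fraction(panel)
  expect_true(pf > 0 && pf <= 1)
  g <- genotypes(panel$pop)
  expect_equal(pf, mean(apply(g, 2, function(v) length(unique(v)) > 1)))
})
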