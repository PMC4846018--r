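test_that("initial populations are six families of inbred bi-parental descent", {
  panel <- mini_panel()
  set.seed(81)
  parents <- choose_diverse_parents(panel, n_parents = 7)
  set.seed(82)
  fams <- make_initial_populations(panel, parents, n_lines = 40,
                                   ssd_generations = 5)
  expect_length(fams, 6)
  expect_true(all(vapply(fams, n_ind, integer(1)) == 40))
  common <- panel$pop$hap1[parents$common, ]
  het_rates <- numeric(0)
  for (i in seq_along(fams)) {
    other <- panel$pop$hap1[parents$others[i], ]
    f <- fams[[i]]
    # every allele traces to one of the two parents
    for (h in list(f$hap1, f$hap2)) {
      ok <- h == matrix(common, nrow(h), ncol(h), byrow = TRUE) |
        h == matrix(other, nrow(h), ncol(h), byrow = TRUE)
      expect_true(all(ok))
    }
    seg <- common != other
    if (any(seg))
      het_rates <- c(het_rates,
                     rowMeans((f$hap1 != f$hap2)[, seg, drop = FALSE]))
  }
  # F6 residual heterozygosity at parent-polymorphic loci ~ (1/2)^5; lines
  # are the independent unit (loci within a line are linked)
  se <- sd(het_rates) / sqrt(length(het_rates))
  expect_lt(abs(mean(het_rates) - 0.03125), 4 * se)
})

test_that("truncation selection takes the top fraction with valid tie handling", {
  set.seed(83)
  pred <- rnorm(180)
  sel <- select_top(pred, 0.10)
  expect_length(sel, 18)
  expect_setequal(sel, order(pred, decreasing = TRUE)[1:18])
  expect_length(select_top(rnorm(30), 0.10), 3)
  expect_error(select_top(rnorm(7), 0.10), "positive integer")
  # all-tied predictions: any valid subset of the right size
  tied <- select_top(rep(1, 50), 0.10)
  expect_length(tied, 5)
  expect_true(all(tied %in% 1:50))
})

test_that("round-robin mating forms the S-cross chain with the wrap-around", {
  map <- mini_map()
  set.seed(84)
  panel <- generate_founders(18, map)
  pop <- panel$pop
  set.seed(85)
  prog <- round_robin_mate(pop, map, progeny_per_cross = 10)
  expect_equal(n_ind(prog), 180)
  cnt <- table(c(prog$mother[seq(1, 180, by = 10)],
                 prog$father[seq(1, 180, by = 10)]))
  expect_true(all(cnt == 2))          # every parent in exactly 2 crosses
  expect_true(all(prog$mother != prog$father))  # no selfing
  prog3 <- round_robin_mate(pop[1:3], map, progeny_per_cross = 10)
  expect_equal(n_ind(prog3), 30)
  expect_error(round_robin_mate(pop[1], map), "at least 2")
})

test_that("ring migration swaps plants and conserves the selected multiset", {
  map <- mini_map()
  set.seed(86)
  panel <- generate_founders(18, map)
  sets <- lapply(1:6, function(i) panel$pop[(i - 1) * 3 + 1:3])
  set.seed(87)
  out <- migrate_ring(sets, migration_size = 1)
  expect_true(all(vapply(out, n_ind, integer(1)) == 3))
  for (i in 1:6) {
    foreign <- sum(!(out[[i]]$id %in% sets[[i]]$id))
    expect_equal(foreign, 1)
  }
  expect_setequal(unlist(lapply(out, `[[`, "id")),
                  unlist(lapply(sets, `[[`, "id")))
  expect_identical(migrate_ring(sets, 0), sets)
  expect_error(migrate_ring(sets, 3), "smaller")
})

test_that("bulked population size is conserved over all cycles", {
  setup <- mini_setup()
  cfg <- scheme_config("bulked", pop_size = 30, n_subpop = 6,
                       subpop_size = 5, cycles = 6, intensity = 0.2,
                       progeny_per_cross = 5)
  tr <- run_scheme(cfg, setup, seed = 88)
  expect_true(all(tr$n == 30))
  expect_equal(sort(unique(tr$cycle)), 0:6)
  expect_true(all(tr$n_selected[tr$cycle > 0] == 6))
})

test_that("island subpopulations without migration reproduce independent discrete runs", {
  setup <- mini_setup()
  cfgI <- scheme_config("island", pop_size = 30, n_subpop = 6,
                        subpop_size = 5, cycles = 5, intensity = 0.4,
                        progeny_per_cross = 5, migration = FALSE)
  trI <- run_scheme(cfgI, setup, seed = 89)
  sub_setup <- setup
  sub_setup$families <- lapply(seq_along(setup$families), function(i)
    setup$families[[i]][setup$subsets[[i]]])
  cfgD <- scheme_config("discrete", pop_size = 5, cycles = 5,
                        intensity = 0.4, progeny_per_cross = 5)
  trD <- run_scheme(cfgD, sub_setup, seed = 89)
  num <- c("mean_gv", "max_gv", "var_gv", "het", "fixed", "accuracy",
           "attained")
  # rows are recorded in identical (cycle, unit) loop order in both runs
  oI <- trI[, num]
  oD <- trD[, num]
  expect_equal(unname(as.matrix(oI)), unname(as.matrix(oD)),
               tolerance = 1e-12)
})

test_that("all final alleles trace back to the founder parents", {
  setup <- mini_setup()
  cfg <- scheme_config("island", pop_size = 30, n_subpop = 6, subpop_size = 5,
                       cycles = 4, intensity = 0.4, progeny_per_cross = 5)
  tr <- run_scheme(cfg, setup, seed = 90)
  panel <- mini_panel()
  pidx <- c(setup$parents$common, setup$parents$others)
  par_h <- panel$pop$hap1[pidx, , drop = FALSE]
  for (pop in attr(tr, "final_populations")) {
    for (h in list(pop$hap1, pop$hap2)) {
      for (j in seq_len(ncol(h))) {
        expect_true(all(h[, j] %in% par_h[, j]))
      }
    }
  }
})

test_that("a zero-heritability trait yields no genetic response", {
  panel <- mini_panel()
  map <- panel$map
  set.seed(91)
  arch0 <- build_architecture(panel, n_qtl = 20, effective_n = 8,
                              total_h2 = 0)
  setup <- mini_setup()
  setup$arch <- arch0
  cfg <- scheme_config("bulked", pop_size = 30, n_subpop = 6, subpop_size = 5,
                       cycles = 3, intensity = 0.2, progeny_per_cross = 5)
  tr <- run_scheme(cfg, setup, seed = 92)
  expect_true(all(tr$attained[tr$cycle > 0] == 0))
  expect_true(all(tr$mean_gv == 0))
})

test_that("post-breeding inbreeding decays heterozygosity as h0/2^g", {
  map <- mini_map()
  m <- nrow(map)
  set.seed(93)
  h0 <- 0.2
  n <- 600
  h1 <- matrix(0L, n, m); h2 <- matrix(0L, n, m)
  het_mask <- matrix(runif(n * m) < h0, n, m)
  h2[het_mask] <- 1L
  pop <- gs_pop(h1, h2)
  res <- post_breeding_inbreed(pop, map, generations = 3)
  expect_equal(res$generation, 0:3)
  h_start <- 1 - res$homozygosity[1]
  for (g in 1:3) {
    expected <- h_start / 2^g
    se <- sqrt(expected * (1 - expected) / (n * m))
    expect_lt(abs((1 - res$homozygosity[g + 1]) - expected), 4 * se)
  }
  # fully homozygous input stays at 100%
  hom <- gs_pop(h1[1:5, ], h1[1:5, ])
  res2 <- post_breeding_inbreed(hom, map, generations = 2)
  expect_true(all(res2$homozygosity == 1))
})

test_that("model updating deploys a refit model of the right size", {
  setup <- mini_setup()
  n_train <- length(setup$phenotypes)
  cfg <- scheme_config("bulked", pop_size = 30, n_subpop = 6, subpop_size = 5,
                       cycles = 5, intensity = 0.2, progeny_per_cross = 5,
                       update_schedule = list(derive = 1, deploy = 3,
                                              lines_per_parent = 2))
  tr <- run_model_update_scenario(cfg, setup, seed = 94)
  # 6 selected plants x 2 lines each join the training set at deployment
  expect_equal(attr(tr, "model")$n, n_train + 12)
  # without a schedule the trajectory is the plain bulked run
  cfg0 <- scheme_config("bulked", pop_size = 30, n_subpop = 6,
                        subpop_size = 5, cycles = 5, intensity = 0.2,
                        progeny_per_cross = 5)
  tr0 <- run_scheme(cfg0, setup, seed = 94)
  expect_equal(tr$attained[tr$cycle <= 2], tr0$attained[tr0$cycle <= 2])
  expect_error(scheme_config("bulked", update_schedule =
                               list(derive = 5, deploy = 30)), "1..cycles")
  expect_error(run_model_update_scenario(
    scheme_config("island"), setup, seed = 1), "bulked")
})

test_that("scheme configuration invariants are enforced", {
  expect_error(scheme_config("bulked", pop_size = 175), "positive integer")
  expect_error(scheme_config("island", n_subpop = 5, subpop_size = 30,
                             pop_size = 180), "must equal pop_size")
  cfg <- scheme_config("island")
  expect_equal(cfg$subpop_size * cfg$n_subpop, cfg$pop_size)
})
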