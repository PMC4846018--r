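#' Configuration of a recurrent genomic-selection scheme
#'
#' Encodes one breeding-scheme scenario.  Three population topologies are
#' supported: `"discrete"` (each bi-parental family evolves on its own),
#' `"bulked"` (one admixed population drawing equally from every family) and
#' `"island"` (the per-family subsets kept as separate subpopulations,
#' connected by one-directional ring migration of selected plants).
#'
#' @param scheme one of `"discrete"`, `"bulked"`, `"island"`.
#' @param pop_size breeding-unit size for discrete/bulked (default 180).
#' @param intensity selection intensity; `intensity * unit size` must be a
#'   positive integer (180 x 0.10 = 18; 30 x 0.10 = 3).
#' @param progeny_per_cross offspring per round-robin cross.
#' @param cycles number of selection cycles.
#' @param ssd_generations selfing generations from F1 to the initial inbred
#'   lines (5 gives F6).
#' @param n_subpop number of island subpopulations (also the number of
#'   bi-parental families).
#' @param subpop_size lines per subpopulation; `n_subpop * subpop_size` must
#'   equal `pop_size` so schemes are size-matched.
#' @param migration_size selected plants exchanged per subpopulation per
#'   migration event (0 disables migration).
#' @param migration_interval cycles between migration events.
#' @param island_init `"by_family"` (each family is one subpopulation) or
#'   `"random"` (lines shuffled across subpopulations).
#' @param migration logical switch for the island migration step.
#' @param update_schedule optional mid-program model update: list with
#'   `derive` (cycles at which update lines are derived from the selected
#'   plants), `deploy` (cycles at which the refit model replaces the current
#'   one, pairwise with `derive`), and `lines_per_parent` (selfed progeny
#'   per selected plant).
#' @return An object of class `scheme_config`.
#' @export
scheme_config <- function(scheme = c("bulked", "discrete", "island"),
                          pop_size = 180, intensity = 0.10,
                          progeny_per_cross = 10, cycles = 20,
                          ssd_generations = 5,
                          n_subpop = 6, subpop_size = 30,
                          migration_size = 1, migration_interval = 1,
                          island_init = c("by_family", "random"),
                          migration = TRUE, update_schedule = NULL) {
  scheme <- match.arg(scheme)
  island_init <- match.arg(island_init)
  unit_size <- if (scheme == "island") subpop_size else pop_size
  k <- intensity * unit_size
  if (abs(k - round(k)) > 1e-9 || round(k) < 1)
    stop("selection intensity times unit size must be a positive integer")
  if (scheme == "island" && n_subpop * subpop_size != pop_size)
    stop("n_subpop * subpop_size must equal pop_size")
  if (!is.null(update_schedule)) {
    us <- update_schedule
    if (length(us$derive) != length(us$deploy))
      stop("update schedule derive and deploy cycles must pair up")
    if (any(us$derive < 1) || any(us$deploy > cycles) ||
        any(us$deploy <= us$derive))
      stop("update schedule cycles must lie in 1..cycles with deploy after derive")
    if (is.null(us$lines_per_parent)) us$lines_per_parent <- 10
    update_schedule <- us
  }
  structure(list(scheme = scheme, pop_size = pop_size, intensity = intensity,
                 progeny_per_cross = progeny_per_cross, cycles = cycles,
                 ssd_generations = ssd_generations, n_subpop = n_subpop,
                 subpop_size = subpop_size, migration_size = migration_size,
                 migration_interval = migration_interval,
                 island_init = island_init, migration = migration,
                 update_schedule = update_schedule),
            class = "scheme_config")
}

#' @export
print.scheme_config <- function(x, ...) {
  cat(sprintf("%s GS scheme: %d lines, %d cycles, intensity %.2f\n",
              x$scheme, x$pop_size, x$cycles, x$intensity))
  if (x$scheme == "island")
    cat(sprintf("  %d subpopulations of %d; migration size %d every %d cycle(s)%s\n",
                x$n_subpop, x$subpop_size, x$migration_size,
                x$migration_interval,
                if (!x$migration) " (disabled)" else ""))
  invisible(x)
}

#' Construct the initial breeding and training populations
#'
#' Crosses the common parent with each other parent to give the F1 of each
#' bi-parental family, then advances `n_lines` independent single-seed
#' descent chains per F1 for `ssd_generations` selfing generations (F6 lines
#' by default).  Uses the current RNG.
#'
#' @param panel a `founder_panel`.
#' @param parents output of [choose_diverse_parents()]: `common` and
#'   `others` founder indices.
#' @param n_lines inbred lines per family.
#' @param ssd_generations selfing generations from the F1.
#' @return List of [gs_pop()] families (one per non-common parent), each of
#'   `n_lines` inbred lines, family labels set to the non-common parent id.
#' @export
make_initial_populations <- function(panel, parents, n_lines = 180,
                                     ssd_generations = 5) {
  map <- panel$map
  lapply(parents$others, function(op) {
    f1 <- cross(panel$pop, parents$common, op, map, n_progeny = 1,
                id_prefix = paste0("f1_", panel$pop$id[op], "_"))
    fam_label <- panel$pop$id[op]
    f1$family <- fam_label
    # n_lines independent SSD chains from the same F1 genotype
    f1n <- f1[rep(1L, n_lines)]
    f1n$id <- sprintf("%s_%03d", f1$id, seq_len(n_lines))
    lines <- ssd_advance(f1n, map, generations = ssd_generations)
    lines$family <- rep(fam_label, n_lines)
    lines
  })
}

#' Truncation selection on predicted values
#'
#' Selects the `intensity * n` candidates with the highest predicted values;
#' the product must be integral (a configuration invariant).  Ties are
#' broken uniformly at random using the current RNG.
#'
#' @param predicted numeric vector of predicted values.
#' @param intensity selection intensity in (0, 1].
#' @return Integer indices of the selected candidates.
#' @export
select_top <- function(predicted, intensity) {
  n <- length(predicted)
  k <- intensity * n
  if (abs(k - round(k)) > 1e-9 || round(k) < 1)
    stop("intensity * number of candidates must be a positive integer")
  k <- as.integer(round(k))
  ord <- order(predicted, stats::runif(n), decreasing = TRUE)
  sort(ord[seq_len(k)])
}

#' Single round-robin mating
#'
#' Places the selected plants in an RNG-shuffled chain and performs the S
#' chain crosses plant1 x plant2, ..., plantS x plant1 (the wrap-around
#' included), so every selected plant parents exactly two crosses; adjacent
#' chain members are distinct, so self-pollination never occurs.
#'
#' @param pop a [gs_pop()] of S >= 2 selected plants.
#' @param map the [genetic_map()].
#' @param progeny_per_cross offspring per cross.
#' @param id_prefix prefix for progeny ids.
#' @return A [gs_pop()] of `S * progeny_per_cross` offspring.
#' @export
round_robin_mate <- function(pop, map, progeny_per_cross = 10,
                             id_prefix = "rr") {
  S <- n_ind(pop)
  if (S < 2) stop("round-robin mating needs at least 2 plants")
  chain <- sample.int(S)
  mothers <- chain
  fathers <- c(chain[-1], chain[1])
  cross(pop, mothers, fathers, map, n_progeny = progeny_per_cross,
        id_prefix = id_prefix)
}

#' Ring migration between subpopulations' selected sets
#'
#' Subpopulations are placed in a fresh random ring order; each sends
#' `migration_size` randomly chosen selected plants to its ring successor
#' and the emigrants' slots are filled by the immigrants, so every selected
#' set keeps its size and the multiset union of plants is conserved.  Uses
#' the current RNG.  Mating is performed after migration within each
#' subpopulation.
#'
#' @param selected_sets list of [gs_pop()], the per-subpopulation selected
#'   plants.
#' @param migration_size plants exchanged per subpopulation
#'   (`< min` selected count; 0 is a no-op).
#' @return The updated list of selected sets.
#' @export
migrate_ring <- function(selected_sets, migration_size = 1) {
  if (migration_size == 0) return(selected_sets)
  sizes <- vapply(selected_sets, n_ind, integer(1))
  if (migration_size >= min(sizes))
    stop("migration_size must be smaller than the per-subpopulation selected count")
  ns <- length(selected_sets)
  ring <- sample.int(ns)
  emig_idx <- lapply(selected_sets, function(s)
    sample.int(n_ind(s), migration_size))
  out <- selected_sets
  for (j in seq_len(ns)) {
    from <- ring[j]
    to <- ring[if (j == ns) 1L else j + 1L]
    keep <- setdiff(seq_len(n_ind(selected_sets[[to]])), emig_idx[[to]])
    out[[to]] <- pop_bind(selected_sets[[to]][keep],
                          selected_sets[[from]][emig_idx[[from]]])
  }
  out
}

# deterministic sub-seed derivation (kept below 2^31)
derive_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 1000000007
  as.integer((abs(as.numeric(seed)) * 131 + h * 31 + 17) %% 2147483629)
}

# per-unit selection step: predict, measure accuracy, select top fraction
select_unit <- function(pop, model, arch, intensity, seed) {
  set.seed(seed)
  pred <- predict(model, newdata = genotypes(pop))
  gv <- genotypic_value(pop, arch)
  acc <- if (stats::var(pred) == 0 || stats::var(gv) == 0) NA_real_ else
    stats::cor(pred, gv)
  sel <- select_top(pred, intensity)
  list(selected = pop[sel], accuracy = acc, idx = sel)
}

unit_state <- function(pop, arch) {
  gv <- genotypic_value(pop, arch)
  hf <- heterozygosity_and_fixation(pop)
  list(n = n_ind(pop), mean_gv = mean(gv), max_gv = max(gv),
       var_gv = stats::var(gv), het = hf$het, fixed = hf$fixed)
}

#' Run one recurrent genomic-selection scheme
#'
#' The engine behind all three topologies.  Per cycle and breeding unit:
#' predict GEBVs with the (shared) G-BLUP model, apply truncation selection,
#' optionally migrate selected plants between island subpopulations, mate
#' the selected plants in a single round robin, and record trajectory
#' metrics.  The same prediction model is used for all cycles unless the
#' configuration carries a model-update schedule.  All randomness derives
#' hierarchically from `seed` per (cycle, unit, operation), so schemes
#' sharing a replicate setup start from identical populations and island
#' subpopulations with migration disabled reproduce independent discrete
#' runs of the same subsets exactly.
#'
#' @param config a [scheme_config()].
#' @param setup a replicate setup from [replicate_setup()] (initial
#'   families, phenotypes, subsets, fitted model, architecture, map).
#' @param seed integer seed for this scheme run's random stream.
#' @return A `gs_trajectory`: data frame with one row per cycle and breeding
#'   unit (cycle 0 = initial state) holding population size, mean/max/
#'   variance of true genotypic values, heterozygosity, fixed-locus
#'   proportion, prediction accuracy, attained genotypic value and selected
#'   count; attributes carry the per-family selected counts, the per-family
#'   best-line baselines and the configuration.
#' @export
run_scheme <- function(config, setup, seed = 1) {
  stopifnot(inherits(config, "scheme_config"))
  map <- setup$map; arch <- setup$arch; model <- setup$model
  n_int <- function(x) as.integer(round(x))

  units <- switch(config$scheme,
    discrete = setup$families,
    bulked = list(pop_bind(lapply(seq_along(setup$families), function(i)
      setup$families[[i]][setup$subsets[[i]]]))),
    island = {
      subs <- lapply(seq_along(setup$families), function(i)
        setup$families[[i]][setup$subsets[[i]]])
      if (config$island_init == "random") {
        set.seed(derive_seed(seed, "island_random_init"))
        all <- pop_bind(subs)
        perm <- sample.int(n_ind(all))
        grp <- rep(seq_along(subs), each = config$subpop_size)
        lapply(seq_along(subs), function(i) all[perm[grp == i]])
      } else subs
    })
  unit_names <- switch(config$scheme,
    discrete = vapply(setup$families, function(f) f$family[1], character(1)),
    bulked = "bulked",
    island = sprintf("subpop%d", seq_along(units)))

  schedule <- config$update_schedule
  pending <- list()   # derived update lines awaiting deployment

  rows <- list(); fam_counts <- list()
  rec <- function(cycle, i, st, acc = NA_real_, att = NA_real_, nsel = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      cycle = cycle, unit = unit_names[i], n = st$n, mean_gv = st$mean_gv,
      max_gv = st$max_gv, var_gv = st$var_gv, het = st$het,
      fixed = st$fixed, accuracy = acc, attained = att, n_selected = nsel,
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(units)) rec(0, i, unit_state(units[[i]], arch))

  for (cyc in seq_len(config$cycles)) {
    # deploy a refit model when scheduled
    if (!is.null(schedule)) {
      hit <- which(schedule$deploy == cyc)
      if (length(hit) && length(pending) >= hit[1] &&
          !is.null(pending[[hit[1]]])) {
        upd <- pending[[hit[1]]]
        model <- update(model, y_new = upd$y, genotypes_new = upd$geno)
      }
    }

    sels <- vector("list", length(units))
    for (i in seq_along(units)) {
      s <- select_unit(units[[i]], model, arch, config$intensity,
                       derive_seed(seed, sprintf("c%d_u%d_sel", cyc, i)))
      sels[[i]] <- s
      fams <- factor(s$selected$family,
                     levels = vapply(setup$families, function(f)
                       f$family[1], character(1)))
      cnt <- table(fams)
      fam_counts[[length(fam_counts) + 1L]] <- data.frame(
        cycle = cyc, unit = unit_names[i], family = names(cnt),
        count = as.integer(cnt), stringsAsFactors = FALSE)
    }

    # derive model-update lines from this cycle's selected plants
    if (!is.null(schedule)) {
      hit <- which(schedule$derive == cyc)
      if (length(hit)) {
        set.seed(derive_seed(seed, sprintf("c%d_update_derive", cyc)))
        sel_pop <- pop_bind(lapply(sels, `[[`, "selected"))
        S <- n_ind(sel_pop)
        self1 <- cross(sel_pop, seq_len(S), seq_len(S), map,
                       n_progeny = schedule$lines_per_parent,
                       id_prefix = sprintf("upd%d_", cyc))
        upd_lines <- ssd_advance(self1, map,
                                 generations = config$ssd_generations - 1)
        upd_lines$id <- sprintf("upd%d_%04d", cyc, seq_len(n_ind(upd_lines)))
        gmat <- genotypes(upd_lines)
        pending[[hit[1]]] <- list(y = phenotype(upd_lines, arch), geno = gmat)
      }
    }

    selected_sets <- lapply(sels, `[[`, "selected")
    if (config$scheme == "island" && config$migration &&
        config$migration_size > 0 &&
        cyc %% config$migration_interval == 0) {
      set.seed(derive_seed(seed, sprintf("c%d_mig", cyc)))
      selected_sets <- migrate_ring(selected_sets, config$migration_size)
    }

    for (i in seq_along(units)) {
      set.seed(derive_seed(seed, sprintf("c%d_u%d_mate", cyc, i)))
      att <- attained_genotypic_value(selected_sets[[i]], arch)
      units[[i]] <- round_robin_mate(selected_sets[[i]], map,
                                     config$progeny_per_cross,
                                     id_prefix = sprintf("c%d_u%d_", cyc, i))
      rec(cyc, i, unit_state(units[[i]], arch), acc = sels[[i]]$accuracy,
          att = att, nsel = n_ind(selected_sets[[i]]))
    }
  }

  traj <- do.call(rbind, rows)
  attr(traj, "scheme") <- config$scheme
  attr(traj, "seed") <- seed
  attr(traj, "config") <- config
  attr(traj, "family_counts") <- do.call(rbind, fam_counts)
  attr(traj, "baseline") <- setup$baseline
  attr(traj, "final_populations") <- units
  attr(traj, "model") <- model
  class(traj) <- c("gs_trajectory", "data.frame")
  traj
}

#' Run the bulked scheme with a model-update schedule
#'
#' Convenience wrapper: requires a bulked configuration carrying an
#' `update_schedule` and runs it through [run_scheme()].  At each derivation
#' cycle the selected plants are selfed (`lines_per_parent` progeny each)
#' and advanced four further SSD generations; the resulting lines are
#' phenotyped and the refit model replaces the current one at the paired
#' deployment cycle, modelling the time lag between line derivation and
#' model availability.
#'
#' @param config a bulked [scheme_config()] with `update_schedule` set.
#' @param setup,seed as in [run_scheme()].
#' @return A `gs_trajectory`.
#' @export
run_model_update_scenario <- function(config, setup, seed = 1) {
  if (config$scheme != "bulked")
    stop("model-update scenarios are defined for the bulked scheme")
  if (is.null(config$update_schedule))
    stop("config carries no update schedule")
  run_scheme(config, setup, seed)
}

#' Post-breeding inbreeding of a population
#'
#' Advances every line by single-seed descent and reports the mean
#' homozygous-locus proportion per generation; heterozygosity halves per
#' generation in expectation.  Uses the current RNG.
#'
#' @param pop a [gs_pop()].
#' @param map the [genetic_map()].
#' @param generations selfing generations (>= 1).
#' @return Data frame with `generation` (0 = input) and `homozygosity`.
#' @export
post_breeding_inbreed <- function(pop, map, generations = 3) {
  stopifnot(generations >= 1)
  out <- data.frame(generation = 0, homozygosity = 1 - mean(heterozygosity(pop)))
  cur <- pop
  for (g in seq_len(generations)) {
    cur <- ssd_advance(cur, map, generations = 1)
    out <- rbind(out, data.frame(generation = g,
                                 homozygosity = 1 - mean(heterozygosity(cur))))
  }
  out
}

#' @export
print.gs_trajectory <- function(x, ...) {
  cat(sprintf("GS trajectory: %s scheme, %d cycles, %d unit(s)\n",
              attr(x, "scheme"), max(x$cycle), length(unique(x$unit))))
  fin <- x[x$cycle == max(x$cycle), ]
  cat(sprintf("  final attained genotypic value: %.3f (best unit)\n",
              max(fin$attained)))
  invisible(x)
}

#' @export
summary.gs_trajectory <- function(object, ...) {
  agg <- stats::aggregate(cbind(attained, accuracy, var_gv, het, fixed) ~ cycle,
                          data = object, FUN = mean, na.action = stats::na.pass)
  best <- stats::aggregate(attained ~ cycle, data = object, FUN = max,
                           na.action = stats::na.omit)
  names(best)[2] <- "attained_best_unit"
  out <- merge(agg, best, by = "cycle", all.x = TRUE)
  out <- out[order(out$cycle), ]
  rownames(out) <- NULL
  out
}

#' Plot an attained-value trajectory
#'
#' @param x a `gs_trajectory`.
#' @param metric column to plot against cycle (default `"attained"`).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gs_trajectory <- function(x, metric = "attained", ...) {
  un <- unique(x$unit)
  cyc <- sort(unique(x$cycle))
  m <- sapply(un, function(u) x[[metric]][x$unit == u][order(x$cycle[x$unit == u])])
  graphics::matplot(cyc, m, type = "l", lty = 1, xlab = "selection cycle",
                    ylab = metric, ...)
  invisible(x)
}
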