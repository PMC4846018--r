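#' Set up one simulation replicate
#'
#' Builds everything the breeding schemes of one replicate share, so that
#' scheme comparisons are matched pairs: the QTL architecture, the crossing
#' parents, the six F6 families with their (single) phenotype draw, the
#' per-family subsets used by the bulked and island schemes, the fitted
#' G-BLUP model (trained once on all initial lines), and the per-family
#' best-line baselines.  All randomness derives hierarchically from
#' `rep_seed`, independently per operation.
#'
#' @param panel a `founder_panel` (shared across replicates, as a fixed
#'   genotyped diversity panel would be).
#' @param rep_seed integer seed of this replicate.
#' @param n_parents crossing parents (1 common + `n_parents - 1` others).
#' @param n_lines inbred lines per family.
#' @param subpop_size lines drawn from each family for the bulked/island
#'   initial population.
#' @param ssd_generations selfing generations from F1.
#' @param n_qtl,effective_n,total_h2 trait-architecture parameters.
#' @return A replicate setup list: `map`, `arch`, `parents`, `families`,
#'   `phenotypes`, `subsets`, `model`, `baseline`.
#' @export
replicate_setup <- function(panel, rep_seed, n_parents = 7, n_lines = 180,
                            subpop_size = 30, ssd_generations = 5,
                            n_qtl = 100, effective_n = 40, total_h2 = 0.6) {
  map <- panel$map
  set.seed(derive_seed(rep_seed, "architecture"))
  arch <- build_architecture(panel, n_qtl = n_qtl,
                             effective_n = effective_n, total_h2 = total_h2)
  set.seed(derive_seed(rep_seed, "parents"))
  parents <- choose_diverse_parents(panel, n_parents = n_parents)
  set.seed(derive_seed(rep_seed, "initial_populations"))
  families <- make_initial_populations(panel, parents, n_lines = n_lines,
                                       ssd_generations = ssd_generations)
  training <- pop_bind(families)
  set.seed(derive_seed(rep_seed, "phenotypes"))
  phenotypes <- phenotype(training, arch)
  set.seed(derive_seed(rep_seed, "subsets"))
  subsets <- lapply(families, function(f) sort(sample.int(n_ind(f),
                                                          subpop_size)))
  model <- gblup(phenotypes, genotypes = genotypes(training),
                 exclude = arch$qtl)
  baseline <- vapply(families, baseline_best_line, numeric(1), arch = arch)
  names(baseline) <- vapply(families, function(f) f$family[1], character(1))
  list(map = map, arch = arch, parents = parents, families = families,
       phenotypes = phenotypes, subsets = subsets, model = model,
       baseline = baseline)
}

#' Run the canonical scheme-comparison suite
#'
#' For each replicate: one shared setup ([replicate_setup()]), then one run
#' per scenario from that identical starting state.  The default scenario
#' set is the headline comparison: discrete, bulked, island with
#' every-cycle single-plant ring migration, and the island variant with
#' migration disabled (the variance-collapse control).
#'
#' @param panel a `founder_panel`.
#' @param n_rep number of matched replicates.
#' @param seed root seed.
#' @param scenarios named list of [scheme_config()]s.
#' @param cycles selection cycles (applied to the default scenarios).
#' @param setup_args extra arguments passed to [replicate_setup()].
#' @return A list with `trajectories` (nested: replicate -> scenario ->
#'   `gs_trajectory`) and `summary`, a data frame keyed by (scenario,
#'   replicate, cycle) with the per-cycle overall attained value (max over
#'   units), mean accuracy, mean per-unit genetic variance, heterozygosity,
#'   fixation, and the number of families with zero selected plants at
#'   that cycle (for single-unit schemes).
#' @export
run_comparison_suite <- function(panel, n_rep = 10, seed = 1,
                                 scenarios = NULL, cycles = 20,
                                 setup_args = list()) {
  if (is.null(scenarios))
    scenarios <- list(
      discrete = scheme_config("discrete", cycles = cycles),
      bulked = scheme_config("bulked", cycles = cycles),
      island = scheme_config("island", cycles = cycles),
      island_nomig = scheme_config("island", cycles = cycles,
                                   migration = FALSE))
  trajs <- vector("list", n_rep)
  sums <- list()
  for (r in seq_len(n_rep)) {
    rep_seed <- derive_seed(seed, sprintf("replicate%d", r))
    setup <- do.call(replicate_setup,
                     c(list(panel = panel, rep_seed = rep_seed), setup_args))
    trajs[[r]] <- lapply(seq_along(scenarios), function(s) {
      tr <- run_scheme(scenarios[[s]], setup,
                       seed = derive_seed(rep_seed, names(scenarios)[s]))
      # keep the stored trajectories light across many replicates
      attr(tr, "final_populations") <- NULL
      attr(tr, "model") <- NULL
      tr
    })
    names(trajs[[r]]) <- names(scenarios)
    for (s in names(scenarios)) {
      tr <- trajs[[r]][[s]]
      agg <- summary(tr)
      fc <- attr(tr, "family_counts")
      zero1 <- if (!is.null(fc))
        vapply(sort(unique(fc$cycle)), function(cc) {
          cnt <- stats::aggregate(count ~ family, data = fc[fc$cycle == cc, ],
                                  FUN = sum)
          sum(cnt$count == 0)
        }, numeric(1)) else rep(NA_real_, max(tr$cycle))
      sums[[length(sums) + 1L]] <- data.frame(
        scenario = s, replicate = r, cycle = agg$cycle,
        attained = agg$attained_best_unit, accuracy = agg$accuracy,
        var_gv = agg$var_gv, het = agg$het, fixed = agg$fixed,
        families_lost = c(NA, zero1)[seq_along(agg$cycle)],
        baseline_best = max(attr(tr, "baseline")),
        stringsAsFactors = FALSE)
    }
  }
  list(trajectories = trajs, summary = do.call(rbind, sums))
}

#' Run a full simulation experiment to disk
#'
#' For each replicate, generates the shared setup and runs every scenario
#' from the identical starting state; writes one trajectory CSV per
#' scenario per replicate, a combined per-cycle summary CSV, and a run
#' manifest (root seed, per-replicate seeds, configuration) to the output
#' directory.  Reruns with the same root seed produce byte-identical
#' trajectory files.
#'
#' @param scenarios named list of [scheme_config()]s.
#' @param n_rep number of matched replicates.
#' @param seed root seed; founders are generated once from it (unless a
#'   `panel` is supplied), replicates derive their own streams.
#' @param out_dir output directory (created if missing).
#' @param panel optional `founder_panel`; default: generate with
#'   [generate_founders()] defaults from the root seed.
#' @param setup_args extra arguments for [replicate_setup()].
#' @return Invisibly, the paths of the files written.
#' @export
run_experiment <- function(scenarios, n_rep = 10, seed = 1, out_dir = ".",
                           panel = NULL, setup_args = list()) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory is not writable")
  if (is.null(names(scenarios)) || any(names(scenarios) == ""))
    stop("scenarios must be a named list")
  if (is.null(panel)) {
    set.seed(derive_seed(seed, "founders"))
    panel <- generate_founders()
  }
  files <- character(0)
  res <- run_comparison_suite(panel, n_rep = n_rep, seed = seed,
                              scenarios = scenarios, setup_args = setup_args)
  for (r in seq_len(n_rep)) {
    for (s in names(scenarios)) {
      f <- file.path(out_dir, sprintf("trajectory_%s_rep%03d.csv", s, r))
      utils::write.csv(as.data.frame(res$trajectories[[r]][[s]]), f,
                       row.names = FALSE)
      files <- c(files, f)
    }
  }
  f <- file.path(out_dir, "summary.csv")
  utils::write.csv(res$summary, f, row.names = FALSE)
  files <- c(files, f)
  manifest <- list(
    package_version = as.character(utils::packageVersion("islandGS")),
    root_seed = seed, n_replicates = n_rep,
    replicate_seeds = vapply(seq_len(n_rep), function(r)
      derive_seed(seed, sprintf("replicate%d", r)), integer(1)),
    scenarios = lapply(scenarios, unclass))
  f <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, f)
  files <- c(files, f)
  invisible(files)
}

#' Read scheme configurations from a YAML scenario file
#'
#' The file maps scenario names to [scheme_config()] argument lists, e.g.
#' `island_slow: {scheme: island, migration_interval: 3}`.
#'
#' @param path YAML file path.
#' @return Named list of [scheme_config()]s.
#' @export
read_scenarios <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw)))
    stop("scenario file must map scenario names to configuration lists")
  lapply(raw, function(args) do.call(scheme_config, args))
}
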