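#' Pipeline configuration
#'
#' Exactly one of \code{input} (paths to genotype/trait files) or
#' \code{simulation} (a block describing what to simulate) must be
#' supplied. A single global seed deterministically derives per-stage
#' seeds (by stage-name hashing), so each stage is independently
#' reproducible.
#'
#' @param input \code{NULL}, or list with \code{genotype_csv} (and
#'   optionally \code{genotype_dialect}, \code{trait_csv},
#'   \code{group_csv} mapping sample to group).
#' @param simulation \code{NULL}, or list with \code{n_loci},
#'   \code{divergence} (Balding-Nichols F), \code{n_per_group},
#'   \code{hybrid_class}, \code{missing_rate}, and optionally
#'   \code{trait_model} (a \code{\link{trait_model}}).
#' @param groups named list/vector with entries \code{hybrid},
#'   \code{parent1}, \code{parent2}.
#' @param filter a \code{\link{filter_config}}.
#' @param admixture a \code{\link{admixture_config}}.
#' @param traits a \code{\link{trait_test_config}}.
#' @param abc \code{NULL}, or list with \code{cross}, \code{priors},
#'   \code{n_per_scenario}, \code{n_loci}, \code{n_trees}.
#' @param seed global integer seed.
#' @return a \code{pipeline_config}.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL,
                            groups = list(hybrid = "F1", parent1 = "P1",
                                          parent2 = "P2"),
                            filter = filter_config(),
                            admixture = admixture_config(),
                            traits = trait_test_config(),
                            abc = NULL, seed = 1L) {
  if (is.null(input) == is.null(simulation))
    stop("exactly one of 'input' and 'simulation' must be given")
  structure(list(input = input, simulation = simulation, groups = groups,
                 filter = filter, admixture = admixture, traits = traits,
                 abc = abc, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full hybrid-diagnosis pipeline
#'
#' Stages, in fixed order: obtain data (simulate or read), run the locus
#' filter cascade, estimate parental panels and call per-individual
#' hybrid classes, classify quantitative traits, and (optionally) run
#' the ABC scenario choice. The consolidated report records every
#' stage's outputs plus a provenance block with the seeds used, and is
#' deterministic under a fixed seed.
#'
#' @param cfg a \code{\link{pipeline_config}}.
#' @return list with \code{filter_report}, \code{hybrid_calls},
#'   \code{trait_results}, \code{trait_counts}, \code{scenario_choice}
#'   (or \code{NULL}), \code{provenance}.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) stop("cfg must be a pipeline_config")
  seeds <- list(simulate = derive_seed(cfg$seed, "simulate"),
                filter = derive_seed(cfg$seed, "filter"),
                abc = derive_seed(cfg$seed, "abc"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- data -----------------------------------------------------------
  traits_tb <- NULL
  if (!is.null(cfg$simulation)) {
    sim <- cfg$simulation
    dat <- stage("simulate", {
      panels <- simulate_parental_freqs(sim$n_loci, sim$divergence,
                                        seed = seeds$simulate)
      parts <- list(
        simulate_genotypes("P1", sim$n_per_group, panels,
                           derive_seed(seeds$simulate, "P1")),
        simulate_genotypes("P2", sim$n_per_group, panels,
                           derive_seed(seeds$simulate, "P2")),
        simulate_genotypes(sim$hybrid_class, sim$n_per_group, panels,
                           derive_seed(seeds$simulate, "H")))
      m <- bind_samples(parts)
      if (!is.null(sim$missing_rate) && sim$missing_rate > 0)
        m <- inject_missingness(m, sim$missing_rate,
                                derive_seed(seeds$simulate, "missing"))
      m
    })
    if (!is.null(sim$trait_model))
      traits_tb <- stage("simulate_traits",
        simulate_traits(sim$trait_model, sim$hybrid_class,
                        c(P1 = sim$n_per_group, P2 = sim$n_per_group,
                          H = sim$n_per_group),
                        seed = derive_seed(seeds$simulate, "traits")))
    groups <- list(hybrid = cfg$simulation$hybrid_class,
                   parent1 = "P1", parent2 = "P2")
    trait_groups <- list(hybrid = "H", parent1 = "P1", parent2 = "P2")
  } else {
    dat <- stage("read", {
      dialect <- cfg$input$genotype_dialect
      if (is.null(dialect)) dialect <- "dosage_one_row"
      m <- read_genotype_csv(cfg$input$genotype_csv, dialect = dialect)
      if (!is.null(cfg$input$group_csv)) {
        gmap <- utils::read.csv(cfg$input$group_csv,
                                stringsAsFactors = FALSE)
        labels <- stats::setNames(gmap$group, gmap$sample_id)[m$sample_ids]
        m <- snp_matrix(m$genotypes, m$sample_ids, m$locus_meta,
                        group_labels = unname(labels))
      }
      m
    })
    if (!is.null(cfg$input$trait_csv))
      traits_tb <- stage("read_traits", read_trait_csv(cfg$input$trait_csv))
    groups <- cfg$groups
    trait_groups <- cfg$groups
  }

  # -- filter ---------------------------------------------------------
  filt <- stage("filter", run_filter_cascade(dat, cfg$filter))

  # -- admixture ------------------------------------------------------
  calls <- stage("admixture", {
    gl <- filt$matrix$group_labels
    par_idx <- gl %in% c(groups$parent1, groups$parent2)
    panels <- estimate_panel_freqs(subset_samples(filt$matrix, par_idx),
                                   labels = gl[par_idx],
                                   pseudocount = cfg$admixture$pseudocount)
    ord <- match(c(groups$parent1, groups$parent2), panels$population_ids)
    panels <- panel_freqs(panels$freqs[ord, , drop = FALSE],
                          c(groups$parent1, groups$parent2))
    call_hybrid_classes(filt$matrix, panels, cfg$admixture)
  })

  # -- traits ---------------------------------------------------------
  trait_out <- if (!is.null(traits_tb))
    stage("traits", classify_all(traits_tb, hybrid = trait_groups$hybrid,
                                 parent1 = trait_groups$parent1,
                                 parent2 = trait_groups$parent2,
                                 cfg = cfg$traits))
  else NULL

  # -- scenario choice ------------------------------------------------
  scen_out <- if (!is.null(cfg$abc)) stage("abc", {
    ab <- cfg$abc
    specs <- build_cross_scenarios(ab$cross)
    priors <- if (is.null(ab$priors)) prior_config() else ab$priors
    tab <- build_reference_table(specs, priors,
                                 n_per_scenario = ab$n_per_scenario,
                                 n_loci = ab$n_loci, seed = seeds$abc)
    obs <- compute_sumstats(filt$matrix, groups$parent1, groups$parent2,
                            groups$hybrid)
    abc_model_choice(obs, tab, n_trees = ab$n_trees,
                     seed = derive_seed(seeds$abc, "forest"))
  }) else NULL

  list(filter_report = filt$report,
       hybrid_calls = calls,
       trait_results = if (is.null(trait_out)) NULL else trait_out$results,
       trait_counts = if (is.null(trait_out)) NULL else trait_out$counts,
       scenario_choice = scen_out,
       provenance = list(seed = cfg$seed, stage_seeds = seeds,
                         n_samples = n_samples(dat),
                         n_loci_input = n_loci(dat),
                         n_loci_filtered = n_loci(filt$matrix)))
}

#' Stack snp_matrix objects sharing the same loci
#'
#' @param parts list of \code{snp_matrix} objects with identical locus
#'   metadata.
#' @return a combined \code{snp_matrix}.
#' @export
bind_samples <- function(parts) {
  meta <- parts[[1]]$locus_meta
  for (p in parts[-1])
    if (!identical(p$locus_meta$locus_id, meta$locus_id))
      stop("all parts must share the same loci")
  g <- do.call(rbind, lapply(parts, function(p) p$genotypes))
  snp_matrix(g,
             sample_ids = unlist(lapply(parts, function(p) p$sample_ids)),
             locus_meta = meta,
             group_labels = unlist(lapply(parts, function(p)
               unname(p$group_labels))))
}
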