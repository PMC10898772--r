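#' Prior configuration for admixture-scenario simulation
#'
#' Uniform priors: effective sizes Ne per population, event times t in
#' generations (ordering constraints between named times are enforced at
#' draw time), admixture rates r, and the generation time in years used
#' to convert generations to calendar time.
#'
#' @param ne length-2 interval for Ne (default 10 to 100,000).
#' @param t length-2 interval for event times in generations (default 10
#'   to 500,000).
#' @param r length-2 interval for admixture rates (default 0 to 1).
#' @param gen_time length-2 interval in years per generation (default 2
#'   to 4).
#' @return a \code{prior_config} list.
#' @export
prior_config <- function(ne = c(10, 100000), t = c(10, 500000),
                         r = c(0, 1), gen_time = c(2, 4)) {
  chk <- function(x, nm, lo = 0) {
    if (length(x) != 2 || any(x < lo) || x[1] > x[2])
      stop(nm, " prior must be an ordered, nonnegative interval")
  }
  chk(ne, "ne"); chk(t, "t"); chk(r, "r"); chk(gen_time, "gen_time")
  if (any(ne <= 0) || any(gen_time <= 0))
    stop("ne and gen_time bounds must be positive")
  structure(list(ne = ne, t = t, r = r, gen_time = gen_time),
            class = "prior_config")
}

# Event constructors for scenario specifications.
ev_split <- function(parent, children, time) {
  list(type = "split", parent = parent, children = children, time = time)
}
ev_admix <- function(source_a, source_b, rate, target, time) {
  list(type = "admix", source_a = source_a, source_b = source_b,
       rate = rate, target = target, time = time)
}

#' Construct an admixture-scenario specification
#'
#' A scenario is a root population plus an ordered (oldest first) list of
#' events: population splits and admixture events, each stamped with a
#' named time symbol. Time symbols listed in \code{time_order} are
#' constrained strictly decreasing (older events first) when parameters
#' are drawn.
#'
#' @param id scenario identifier.
#' @param root name of the ancestral population.
#' @param events list built from split/admixture event records.
#' @param time_order character vector of time symbols, oldest first.
#' @param sampled named character vector mapping output group labels to
#'   population names, e.g. \code{c(hybrid = "hyb")}.
#' @param default_samples named integer vector of samples per output
#'   group label.
#' @return a \code{scenario_spec}.
#' @export
scenario_spec <- function(id, root, events, time_order, sampled,
                          default_samples) {
  alive <- root
  tsyms <- character(0)
  rsyms <- character(0)
  for (ev in events) {
    tsyms <- c(tsyms, ev$time)
    if (ev$type == "split") {
      if (!ev$parent %in% alive)
        stop(id, ": split parent ", ev$parent, " not alive")
      alive <- c(setdiff(alive, ev$parent), ev$children)
    } else if (ev$type == "admix") {
      if (!all(c(ev$source_a, ev$source_b) %in% alive))
        stop(id, ": admixture source not alive")
      if (ev$target %in% alive)
        stop(id, ": admixture target ", ev$target, " already exists")
      alive <- c(alive, ev$target)
      rsyms <- c(rsyms, ev$rate)
    } else stop("unknown event type")
  }
  if (!all(tsyms %in% time_order))
    stop(id, ": every event time must appear in time_order")
  ord <- match(tsyms, time_order)
  if (is.unsorted(ord))
    stop(id, ": events must be listed oldest first per time_order")
  if (!all(sampled %in% alive))
    stop(id, ": sampled population not alive at present")
  structure(list(id = id, root = root, events = events,
                 time_order = time_order, time_symbols = unique(tsyms),
                 rate_symbols = unique(rsyms),
                 populations = alive, sampled = sampled,
                 default_samples = default_samples),
            class = "scenario_spec")
}

#' Scenario sets for the two studied crosses
#'
#' \code{magnifica_caucasica}: four scenarios — the hybrid cohort is (1)
#' an F1 of the magnifica-type parent with subspecies A, (2) an F1 with
#' subspecies B, (3) a hybrid formed at t3 that backcrossed into a
#' parental lineage which split off at the same hybridization time, or
#' (4) a hybrid formed at t3 that backcrossed at t1 into a parental
#' lineage which split off later (t2). \code{lingua_caucasica}: two
#' scenarios — an F1 with subspecies A or with subspecies B. Default
#' per-group sample sizes mirror the study design (6 + 6 individuals of
#' the two subspecies, 5 or 3 of the second parent, 4 or 3 hybrids).
#'
#' @param cross \code{"magnifica_caucasica"} or
#'   \code{"lingua_caucasica"}.
#' @return list of \code{\link{scenario_spec}} objects.
#' @export
build_cross_scenarios <- function(cross = c("magnifica_caucasica",
                                            "lingua_caucasica")) {
  cross <- match.arg(cross)
  if (cross == "magnifica_caucasica") {
    par2 <- "magnifica"
    n_samp <- c(magnifica = 5L, nikolai = 6L, caucasica = 6L, hybrid = 4L)
  } else {
    par2 <- "lingua"
    n_samp <- c(lingua = 3L, nikolai = 6L, caucasica = 6L, hybrid = 3L)
  }
  sampled <- stats::setNames(c(par2, "nikolai", "caucasica", "hybrid"),
                             c(par2, "nikolai", "caucasica", "hybrid"))
  base_splits <- list(
    ev_split("ANC", c(par2, "cauc_sl"), "t_root"),
    ev_split("cauc_sl", c("nikolai", "caucasica"), "t_sub"))

  f1_spec <- function(id, other) scenario_spec(
    id, root = "ANC",
    events = c(base_splits,
               list(ev_admix(par2, other, "r1", "hybrid", "t1"))),
    time_order = c("t_root", "t_sub", "t1"),
    sampled = sampled, default_samples = n_samp)

  if (cross == "lingua_caucasica")
    return(list(f1_spec("F1_nikolai", "nikolai"),
                f1_spec("F1_caucasica", "caucasica")))

  bc_spec <- function(id, split_time) scenario_spec(
    id, root = "ANC",
    events = c(base_splits, list(
      ev_admix(par2, "nikolai", "r2", "hyb0", "t3"),
      ev_split(par2, c(par2, "mag_bc"), split_time),
      ev_admix("hyb0", "mag_bc", "r1", "hybrid", "t1"))),
    time_order = unique(c("t_root", "t_sub", "t3", split_time, "t1")),
    sampled = sampled, default_samples = n_samp)

  list(f1_spec("F1_nikolai", "nikolai"),
       f1_spec("F1_caucasica", "caucasica"),
       bc_spec("backcross_same_time", "t3"),
       bc_spec("backcross_later", "t2"))
}

#' Draw one parameter vector from the priors for a scenario
#'
#' Ne is drawn per population, admixture rates per rate symbol, and the
#' scenario's time symbols jointly uniform subject to the strict
#' ordering constraint (realized by sorting a fresh set of uniform
#' draws, which is distributionally identical to rejection sampling).
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param priors a \code{\link{prior_config}}.
#' @return list with \code{ne} (named), \code{times} (named, decreasing
#'   in \code{time_order}), \code{rates} (named).
#' @export
draw_scenario_params <- function(spec, priors = prior_config()) {
  pops <- unique(c(spec$root, spec$populations,
                   unlist(lapply(spec$events, function(e)
                     if (e$type == "split") e$children else e$target))))
  ne <- stats::setNames(stats::runif(length(pops), priors$ne[1],
                                     priors$ne[2]), pops)
  syms <- spec$time_order[spec$time_order %in% spec$time_symbols]
  tt <- sort(stats::runif(length(syms), priors$t[1], priors$t[2]),
             decreasing = TRUE)
  times <- stats::setNames(tt, syms)
  rates <- stats::setNames(
    stats::runif(length(spec$rate_symbols), priors$r[1], priors$r[2]),
    spec$rate_symbols)
  list(ne = ne, times = times, rates = rates)
}

#' Simulate a SNP dataset under an admixture scenario
#'
#' Forward allele-frequency approximation: each locus starts from an
#' ancestral frequency ~ Uniform(0.05, 0.95); along every branch of
#' duration t generations in a population of size Ne the frequency
#' drifts by a Balding-Nichols Beta step of strength
#' F = 1 - exp(-t / (2 Ne)); an admixture event sets the target
#' frequency to r p_A + (1 - r) p_B. Sampled genotypes are
#' Binomial(2, p) per individual, except for populations created by an
#' admixture event within the last generation, which are sampled gamete
#' by gamete (one from each source) to preserve F1 heterozygosity
#' structure.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param params parameters from \code{\link{draw_scenario_params}}.
#' @param n_loci number of loci.
#' @param samples_per_pop named counts per output group label; defaults
#'   to the spec's \code{default_samples}.
#' @param seed integer RNG seed.
#' @return a \code{\link{snp_matrix}} with group labels.
#' @export
simulate_scenario <- function(spec, params, n_loci,
                              samples_per_pop = spec$default_samples,
                              seed = 1L) {
  if (n_loci < 1) stop("n_loci must be at least 1")
  if (any(params$rates < 0) || any(params$rates > 1))
    stop("admixture rates must lie in [0, 1]")
  with_seed(seed, {
    p0 <- stats::runif(n_loci, 0.05, 0.95)
    pops <- list()
    pops[[spec$root]] <- list(freq = p0,
                              t_last = params$times[[spec$events[[1]]$time]],
                              gamete = NULL)
    drift_to <- function(nm, t_now) {
      st <- pops[[nm]]
      dt <- st$t_last - t_now
      if (dt > 0) {
        Fb <- 1 - exp(-dt / (2 * params$ne[[nm]]))
        st$freq <- drift_bn(st$freq, Fb)
        st$t_last <- t_now
        pops[[nm]] <<- st
      }
      pops[[nm]]$freq
    }
    for (ev in spec$events) {
      t_now <- params$times[[ev$time]]
      if (ev$type == "split") {
        p <- drift_to(ev$parent, t_now)
        pops[[ev$parent]] <- NULL
        for (ch in ev$children)
          pops[[ch]] <- list(freq = p, t_last = t_now, gamete = NULL)
      } else {
        pa <- drift_to(ev$source_a, t_now)
        pb <- drift_to(ev$source_b, t_now)
        r <- params$rates[[ev$rate]]
        pops[[ev$target]] <- list(
          freq = r * pa + (1 - r) * pb, t_last = t_now,
          gamete = if (t_now <= 1) list(pa = pa, pb = pb) else NULL)
      }
    }
    gmats <- list(); labels <- character(0); ids <- character(0)
    for (lab in names(spec$sampled)) {
      nm <- spec$sampled[[lab]]
      n <- samples_per_pop[[lab]]
      if (is.null(n) || n < 1) next
      st <- pops[[nm]]
      if (!is.null(st$gamete)) {
        g <- matrix(stats::rbinom(n * n_loci, 1, rep(st$gamete$pa, each = n)) +
                    stats::rbinom(n * n_loci, 1, rep(st$gamete$pb, each = n)),
                    nrow = n)
      } else {
        p <- drift_to(nm, 0)
        g <- matrix(stats::rbinom(n * n_loci, 2, rep(p, each = n)), nrow = n)
      }
      gmats[[lab]] <- g
      labels <- c(labels, rep(lab, n))
      ids <- c(ids, paste0(lab, "_", seq_len(n)))
    }
    g <- do.call(rbind, gmats)
    colnames(g) <- paste0("L", seq_len(n_loci))
    snp_matrix(g, sample_ids = ids, group_labels = labels)
  })
}

#' Hudson's Fst between two labeled groups
#'
#' Ratio-of-averages Hudson estimator: per locus the numerator is
#' (p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) / (n2 - 1) and the
#' denominator p1 (1 - p2) + p2 (1 - p1), with n the number of called
#' allele copies; locus terms are summed before dividing. Loci with
#' fewer than two called alleles in either group, or zero denominator,
#' are excluded.
#'
#' @param m a \code{snp_matrix} with group labels.
#' @param group_a,group_b the two group labels.
#' @return Fst estimate (scalar; \code{NaN} if no usable locus).
#' @export
hudson_fst <- function(m, group_a, group_b) {
  gl <- m$group_labels
  ga <- m$genotypes[gl == group_a, , drop = FALSE]
  gb <- m$genotypes[gl == group_b, , drop = FALSE]
  na <- 2 * colSums(!is.na(ga)); nb <- 2 * colSums(!is.na(gb))
  pa <- colSums(ga, na.rm = TRUE) / na
  pb <- colSums(gb, na.rm = TRUE) / nb
  num <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  den <- pa * (1 - pb) + pb * (1 - pa)
  use <- na >= 2 & nb >= 2 & is.finite(num) & is.finite(den) & den > 0
  sum(num[use]) / sum(den[use])
}

#' Summary statistics for ABC scenario choice
#'
#' Fixed-order vector over three labeled groups: per-group expected
#' heterozygosity (mean over loci of 2 p (1 - p) at the sample allele
#' frequency); the three pairwise Hudson Fst values; the hybrid group's
#' mean hybrid index and mean interclass heterozygosity against panels
#' estimated from the two parental groups; and the mean absolute
#' parental frequency difference. When no ancestry-diagnostic locus
#' exists the interclass statistic takes the sentinel value -1 and the
#' result carries attribute \code{degenerate = TRUE}.
#'
#' @param m a \code{snp_matrix} with group labels.
#' @param parent1,parent2,hybrid group labels of the three cohorts.
#' @param delta diagnostic-locus threshold for the H statistic.
#' @return named numeric vector of 9 statistics.
#' @export
compute_sumstats <- function(m, parent1, parent2, hybrid, delta = 0.8) {
  gl <- m$group_labels
  for (g in c(parent1, parent2, hybrid))
    if (!any(gl == g)) stop("group '", g, "' absent")
  exp_het <- function(grp) {
    g <- m$genotypes[gl == grp, , drop = FALSE]
    n <- colSums(!is.na(g))
    p <- colSums(g, na.rm = TRUE) / (2 * n)
    mean(2 * p * (1 - p), na.rm = TRUE)
  }
  he <- c(exp_het(parent1), exp_het(parent2), exp_het(hybrid))

  fst <- c(hudson_fst(m, parent1, parent2),
           hudson_fst(m, parent1, hybrid),
           hudson_fst(m, parent2, hybrid))
  fst[!is.finite(fst)] <- 0

  par_idx <- gl %in% c(parent1, parent2)
  panels <- suppressWarnings(estimate_panel_freqs(
    subset_samples(m, par_idx), labels = gl[par_idx], pseudocount = 0.5))
  # panel order: estimate_panel_freqs sorts labels; reorder to parent1 first
  ord <- match(c(parent1, parent2), panels$population_ids)
  panels <- panel_freqs(panels$freqs[ord, , drop = FALSE],
                        c(parent1, parent2))
  hyb_rows <- which(gl == hybrid)
  informative <- any(panels$freqs[1, ] != panels$freqs[2, ])
  qs <- if (informative)
    vapply(hyb_rows, function(i)
      hybrid_index(m$genotypes[i, ], panels, grid_step = 0.01,
                   support = FALSE)$q, numeric(1))
    else 0.5  # flat likelihood: report the uninformative midpoint
  diag_ok <- any(abs(panels$freqs[1, ] - panels$freqs[2, ]) >= delta)
  hs <- if (diag_ok)
    vapply(hyb_rows, function(i)
      interclass_heterozygosity(m$genotypes[i, ], panels, delta)$H,
      numeric(1))
    else -1
  absdiff <- mean(abs(panels$freqs[1, ] - panels$freqs[2, ]))

  out <- c(he_p1 = he[1], he_p2 = he[2], he_hyb = he[3],
           fst_p1_p2 = fst[1], fst_p1_hyb = fst[2], fst_p2_hyb = fst[3],
           mean_q_hyb = mean(qs), mean_h_hyb = mean(hs),
           mean_absdiff_p1_p2 = absdiff)
  if (!diag_ok || !informative) attr(out, "degenerate") <- TRUE
  out
}

# Subset a snp_matrix by sample index, keeping loci.
subset_samples <- function(m, keep) {
  snp_matrix(m$genotypes[keep, , drop = FALSE],
             sample_ids = m$sample_ids[keep],
             locus_meta = m$locus_meta,
             group_labels = unname(m$group_labels[keep]))
}

#' Build an ABC reference table by simulating scenarios under the priors
#'
#' For each scenario, draws parameters from the priors, simulates a SNP
#' dataset and records the summary-statistic vector, labeled with the
#' scenario id.
#'
#' @param specs list of \code{\link{scenario_spec}} objects.
#' @param priors a \code{\link{prior_config}}.
#' @param n_per_scenario simulations per scenario (default 1,000; the
#'   full-scale analysis uses 10,000).
#' @param n_loci loci per simulated dataset.
#' @param samples_per_pop named counts per group, or \code{NULL} for each
#'   spec's defaults.
#' @param seed integer base seed.
#' @param parent1,parent2,hybrid group labels passed to
#'   \code{\link{compute_sumstats}}; parent defaults are the two
#'   caucasica-type subspecies labels used by
#'   \code{\link{build_cross_scenarios}}.
#' @return a \code{reference_table}: list with \code{stats} (matrix),
#'   \code{scenario} (factor), \code{params} (data frame).
#' @export
build_reference_table <- function(specs, priors = prior_config(),
                                  n_per_scenario = 1000L, n_loci = 200L,
                                  samples_per_pop = NULL, seed = 1L,
                                  parent1 = "nikolai", parent2 = "caucasica",
                                  hybrid = "hybrid") {
  stats_rows <- list(); scen <- character(0); par_rows <- list()
  for (spec in specs) {
    spp <- if (is.null(samples_per_pop)) spec$default_samples
           else samples_per_pop
    for (j in seq_len(n_per_scenario)) {
      sj <- derive_seed(seed, paste0(spec$id, ":", j))
      params <- with_seed(sj, draw_scenario_params(spec, priors))
      sim <- simulate_scenario(spec, params, n_loci, spp,
                               seed = derive_seed(sj, "sim"))
      st <- compute_sumstats(sim, parent1, parent2, hybrid)
      stats_rows[[length(stats_rows) + 1L]] <- st
      scen <- c(scen, spec$id)
      par_rows[[length(par_rows) + 1L]] <-
        c(params$times, params$rates)
    }
  }
  stats <- do.call(rbind, stats_rows)
  structure(list(stats = stats, scenario = factor(scen),
                 params = par_rows, stat_names = colnames(stats)),
            class = "reference_table")
}

#' Random-forest ABC model choice
#'
#' Trains a random-forest classifier on the reference table's summary
#' statistics and votes on the observed vector; the winning scenario's
#' vote share is reported as a posterior-probability proxy, and the
#' forest's out-of-bag confusion matrix is returned for diagnostics.
#'
#' @param observed named statistic vector (same statistics as the table).
#' @param table a \code{reference_table}.
#' @param n_trees number of trees (default 500).
#' @param seed integer RNG seed (forest training is randomized).
#' @return list with \code{scenario}, \code{vote_share}, \code{votes}
#'   (named, sums to 1), \code{oob_confusion}.
#' @export
abc_model_choice <- function(observed, table, n_trees = 500L, seed = 1L) {
  if (nlevels(table$scenario) < 2)
    stop("model choice needs at least two scenarios")
  obs <- matrix(observed, nrow = 1,
                dimnames = list(NULL, names(observed)))
  if (ncol(obs) != ncol(table$stats) ||
      !identical(colnames(obs), colnames(table$stats)))
    stop("observed statistics do not match the reference table")
  rf <- with_seed(seed,
    randomForest::randomForest(x = table$stats, y = table$scenario,
                               ntree = n_trees))
  votes <- predict(rf, newdata = as.data.frame(obs), type = "vote")[1, ]
  votes <- votes / sum(votes)
  best <- names(votes)[which.max(votes)]
  list(scenario = best, vote_share = unname(votes[best]), votes = votes,
       oob_confusion = rf$confusion)
}

#' Convert generations to calendar time
#'
#' years = generations x generation time; the mya figure is the years
#' divided by one million and truncated (toward zero) at three decimals,
#' the convention used when reporting hybridization-time ranges.
#'
#' @param g number of generations (>= 0).
#' @param gen_time_years years per generation (> 0); may be a vector,
#'   e.g. \code{c(2, 4)} for a range.
#' @return data frame with columns \code{gen_time_years}, \code{years},
#'   \code{mya}.
#' @export
convert_generations_to_time <- function(g, gen_time_years) {
  if (any(g < 0)) stop("generations must be nonnegative")
  if (any(gen_time_years <= 0)) stop("generation time must be positive")
  years <- g * gen_time_years
  mya <- trunc(years / 1e6 * 1000) / 1000
  data.frame(gen_time_years = gen_time_years, years = years, mya = mya)
}
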