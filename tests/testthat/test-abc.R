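test_that("the two crosses expose their documented scenario sets", {
  mag <- build_cross_scenarios("magnifica_caucasica")
  lin <- build_cross_scenarios("lingua_caucasica")
  expect_length(mag, 4)
  expect_length(lin, 2)
  for (s in c(mag, lin)) expect_s3_class(s, "scenario_spec")
  expect_error(build_cross_scenarios("unknown"))
  # scenario constructor rejects events out of time order
  expect_error(scenario_spec(
    "bad", root = "A",
    events = list(hybridtraits:::ev_split("A", c("B", "C"), "t1"),
                  hybridtraits:::ev_admix("B", "C", "r1", "H", "t2")),
    time_order = c("t2", "t1"),
    sampled = c(h = "H"), default_samples = c(h = 2L)),
    "oldest first")
})

test_that("prior draws stay in bounds and respect the time ordering", {
  pr <- prior_config(ne = c(100, 1000), t = c(10, 5000), r = c(0.2, 0.8))
  spec <- build_cross_scenarios("magnifica_caucasica")[[4]]
  set.seed(301)
  for (i in 1:100) {
    pars <- draw_scenario_params(spec, pr)
    expect_true(all(pars$ne >= 100 & pars$ne <= 1000))
    expect_true(all(pars$times >= 10 & pars$times <= 5000))
    expect_true(all(pars$rates >= 0.2 & pars$rates <= 0.8))
    ord <- pars$times[spec$time_order[spec$time_order %in%
                                        names(pars$times)]]
    expect_true(all(diff(ord) < 0))  # strictly decreasing (older first)
  }
})

test_that("zero-duration branches do not drift", {
  spec <- build_cross_scenarios("lingua_caucasica")[[1]]
  pars <- list(
    ne = stats::setNames(rep(1e9, 7),
                         c("ANC", "lingua", "cauc_sl", "nikolai",
                           "caucasica", "hybrid", "x")),
    times = c(t_root = 100, t_sub = 100, t1 = 100),
    rates = c(r1 = 0.5))
  sim <- simulate_scenario(spec, pars, 500,
                           samples_per_pop = c(lingua = 50, nikolai = 50,
                                               caucasica = 50, hybrid = 50),
                           seed = 302)
  # huge Ne + equal event times: every population shares the ancestral
  # frequencies, so pairwise differentiation is nil
  expect_lt(abs(hudson_fst(sim, "nikolai", "caucasica")), 0.01)
  expect_lt(abs(hudson_fst(sim, "lingua", "nikolai")), 0.01)
})

test_that("an r = 1 admixture copies source A's frequencies", {
  spec <- build_cross_scenarios("lingua_caucasica")[[1]]
  ne <- stats::setNames(rep(1e9, 6),
                        c("ANC", "lingua", "cauc_sl", "nikolai",
                          "caucasica", "hybrid"))
  ne[c("cauc_sl", "nikolai", "caucasica")] <- 200
  pars <- list(ne = ne, times = c(t_root = 2000, t_sub = 1500, t1 = 10),
               rates = c(r1 = 1))
  sim <- simulate_scenario(spec, pars, 800,
                           samples_per_pop = c(lingua = 60, nikolai = 60,
                                               caucasica = 60, hybrid = 60),
                           seed = 303)
  expect_lt(abs(hudson_fst(sim, "lingua", "hybrid")), 0.01)
  expect_gt(hudson_fst(sim, "nikolai", "hybrid"), 0.2)
})

test_that("branch drift matches the 1 - exp(-t/2Ne) closed form", {
  # two populations split t generations ago, Ne each: Hudson Fst
  # between them estimates the per-branch F
  spec <- scenario_spec(
    "pair", root = "A",
    events = list(hybridtraits:::ev_split("A", c("B", "C"), "t1")),
    time_order = "t1", sampled = c(B = "B", C = "C"),
    default_samples = c(B = 100L, C = 100L))
  t <- 400; ne <- 1000  # t / 2Ne = 0.2
  pars <- list(ne = c(A = 1000, B = ne, C = ne), times = c(t1 = t),
               rates = numeric(0))
  sim <- simulate_scenario(spec, pars, 5000, seed = 304)
  expect_equal(hudson_fst(sim, "B", "C"), 1 - exp(-t / (2 * ne)),
               tolerance = 0.02 / (1 - exp(-0.2)))
})

test_that("scenario simulation is bit-reproducible under a fixed seed", {
  spec <- build_cross_scenarios("lingua_caucasica")[[2]]
  set.seed(305)
  pars <- draw_scenario_params(spec, prior_config())
  a <- simulate_scenario(spec, pars, 100, seed = 306)
  b <- simulate_scenario(spec, pars, 100, seed = 306)
  expect_identical(a$genotypes, b$genotypes)
})

test_that("Hudson Fst matches an independent per-locus implementation", {
  set.seed(307)
  for (i in 1:10) {
    p <- simulate_parental_freqs(100, runif(1, 0.05, 0.4), seed = 308 + i)
    m <- bind_samples(list(simulate_genotypes("P1", 12, p, seed = 320 + i),
                           simulate_genotypes("P2", 15, p, seed = 340 + i)))
    ours <- hudson_fst(m, "P1", "P2")
    # independent oracle: explicit per-locus loop
    g1 <- m$genotypes[m$group_labels == "P1", ]
    g2 <- m$genotypes[m$group_labels == "P2", ]
    num <- den <- 0
    for (l in seq_len(ncol(g1))) {
      x1 <- g1[, l][!is.na(g1[, l])]; x2 <- g2[, l][!is.na(g2[, l])]
      n1 <- 2 * length(x1); n2 <- 2 * length(x2)
      if (n1 < 2 || n2 < 2) next
      p1 <- sum(x1) / n1; p2 <- sum(x2) / n2
      d <- p1 * (1 - p2) + p2 * (1 - p1)
      if (d <= 0) next
      num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
        p2 * (1 - p2) / (n2 - 1)
      den <- den + d
    }
    expect_equal(ours, num / den, tolerance = 1e-6)
  }
})

test_that("summary statistics behave at the degenerate extremes", {
  # identical populations: Fst near zero
  p <- simulate_parental_freqs(2000, 0, seed = 310)
  m <- bind_samples(list(simulate_genotypes("P1", 20, p, seed = 311),
                         relabel(simulate_genotypes("P1", 20, p, seed = 312),
                                 "P2"),
                         relabel(simulate_genotypes("P1", 10, p, seed = 313),
                                 "H")))
  st <- compute_sumstats(m, "P1", "P2", "H")
  expect_lt(abs(st[["fst_p1_p2"]]), 0.01)

  # fixed-difference parents with an F1 cohort: Fst = 1, mean H = 1
  pan <- diagnostic_panels(200)
  m2 <- bind_samples(list(simulate_genotypes("P1", 10, pan, seed = 314),
                          simulate_genotypes("P2", 10, pan, seed = 315),
                          relabel(simulate_genotypes("F1", 5, pan,
                                                     seed = 316), "H")))
  st2 <- compute_sumstats(m2, "P1", "P2", "H")
  expect_equal(st2[["fst_p1_p2"]], 1, tolerance = 1e-9)
  expect_equal(st2[["mean_h_hyb"]], 1)
  expect_equal(st2[["mean_q_hyb"]], 0.5, tolerance = 0.01)
})

test_that("model choice memorizes well-separated training data and is deterministic", {
  set.seed(317)
  n <- 150
  stats1 <- cbind(a = rnorm(n, 0), b = rnorm(n, 0))
  stats2 <- cbind(a = rnorm(n, 8), b = rnorm(n, 8))
  tab <- structure(list(stats = rbind(stats1, stats2),
                        scenario = factor(rep(c("s1", "s2"), each = n)),
                        params = NULL, stat_names = c("a", "b")),
                   class = "reference_table")
  obs <- stats2[1, ]
  r1 <- abc_model_choice(obs, tab, n_trees = 200, seed = 318)
  expect_equal(r1$scenario, "s2")
  expect_gt(r1$vote_share, 0.9)
  expect_equal(sum(r1$votes), 1, tolerance = 1e-12)
  r2 <- abc_model_choice(obs, tab, n_trees = 200, seed = 318)
  expect_identical(r1$votes, r2$votes)
  expect_error(abc_model_choice(c(x = 1), tab), "do not match")
})

test_that("generation-to-time conversion truncates mya at three decimals", {
  out <- convert_generations_to_time(161864, c(2, 4))
  expect_equal(out$mya, c(0.323, 0.647))
  out2 <- convert_generations_to_time(6132.97, c(2, 4))
  expect_equal(out2$mya, c(0.012, 0.024))
  expect_equal(convert_generations_to_time(0, 3)$years, 0)
  expect_equal(convert_generations_to_time(0, 3)$mya, 0)
  expect_error(convert_generations_to_time(-1, 2), "nonnegative")
  expect_error(convert_generations_to_time(10, 0), "positive")
})
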