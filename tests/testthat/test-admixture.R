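test_that("panel frequency estimation follows the pseudocount formula", {
  m <- snp_matrix(cbind(L1 = c(2, 2, 2), L2 = c(0, 1, 2)),
                  sample_ids = c("a", "b", "c"),
                  group_labels = rep("pop", 3))
  p0 <- estimate_panel_freqs(bind_samples(list(m, relabel(m, "pop2"))),
                             pseudocount = 0)
  expect_equal(unname(p0$freqs[1, ]), c(1, 0.5))
  # pseudocount 0.5 shrinks a fixed locus: (6 + 0.5) / (6 + 1)
  p5 <- estimate_panel_freqs(bind_samples(list(m, relabel(m, "pop2"))),
                             pseudocount = 0.5)
  expect_equal(p5$freqs[1, "L1"], 6.5 / 7)
})

test_that("zero called alleles at a locus falls back to p = 0.5", {
  m <- snp_matrix(cbind(L1 = c(NA, NA), L2 = c(0, 2)),
                  sample_ids = c("a", "b"), group_labels = c("A", "B"))
  expect_warning(p <- estimate_panel_freqs(m, pseudocount = 0),
                 "zero called")
  expect_equal(unname(p$freqs[, "L1"]), c(0.5, 0.5))
})

test_that("hybrid index hits the closed-form answers at diagnostic loci", {
  pan <- diagnostic_panels(40)
  hi2 <- hybrid_index(rep(2, 40), pan)
  expect_equal(hi2$q, 1, tolerance = 1e-6)
  hi1 <- hybrid_index(rep(1, 40), pan)
  expect_equal(hi1$q, 0.5, tolerance = 1e-6)
  expect_true(hi1$q_support[1] < 0.5 && hi1$q_support[2] > 0.5)
})

test_that("hybrid index errors on unusable input", {
  pan <- diagnostic_panels(5)
  expect_error(hybrid_index(rep(NA_real_, 5), pan), "missing")
  same <- panel_freqs(rbind(rep(0.3, 5), rep(0.3, 5)))
  expect_error(hybrid_index(rep(1, 5), same), "unidentifiable")
})

test_that("the MLE matches an exhaustive fine-grid search", {
  set.seed(101)
  for (i in 1:20) {
    L <- 60
    p1 <- runif(L); p2 <- runif(L)
    pan <- panel_freqs(rbind(p1, p2))
    q_true <- runif(1)
    g <- rbinom(L, 2, q_true * p1 + (1 - q_true) * p2)
    fit <- hybrid_index(g, pan)
    grid <- seq(0, 1, by = 1e-3)
    ll <- vapply(grid, function(q)
      sum(dbinom(g, 2, pmin(pmax(q * p1 + (1 - q) * p2, 1e-12),
                            1 - 1e-12), log = TRUE)), numeric(1))
    expect_lt(abs(fit$q - grid[which.max(ll)]), 1e-3)
    expect_gte(fit$loglik, max(ll) - 1e-9)
  }
})

test_that("swapping panel order maps q to 1 - q", {
  set.seed(102)
  p1 <- runif(80); p2 <- runif(80)
  g <- rbinom(80, 2, 0.7 * p1 + 0.3 * p2)
  qa <- hybrid_index(g, panel_freqs(rbind(p1, p2)))$q
  qb <- hybrid_index(g, panel_freqs(rbind(p2, p1)))$q
  expect_equal(qa, 1 - qb, tolerance = 1e-6)
})

test_that("EM ancestry vectors agree with the two-panel MLE and stay on the simplex", {
  set.seed(103)
  p <- simulate_parental_freqs(300, 0.3, seed = 104)
  f1 <- simulate_genotypes("F1", 5, p, seed = 105)
  pan <- panel_freqs(p$freqs)
  for (i in 1:5) {
    g <- f1$genotypes[i, ]
    em <- admixture_vector_em(g, pan)
    mle <- hybrid_index(g, pan)
    expect_equal(unname(em$q[1]), mle$q, tolerance = 1e-3)
    expect_equal(sum(em$q), 1, tolerance = 1e-9)
    expect_true(all(diff(em$loglik) >= -1e-9))
    expect_true(em$converged)
  }
})

test_that("EM recovers pure ancestry with three fixed-difference panels", {
  L <- 60
  freqs <- rbind(c(rep(1, 20), rep(0, 40)),
                 c(rep(0, 20), rep(1, 20), rep(0, 20)),
                 c(rep(0, 40), rep(1, 20)))
  pan <- panel_freqs(freqs, c("A", "B", "C"))
  g <- 2 * freqs[3, ]
  em <- admixture_vector_em(g, pan)
  expect_equal(unname(em$q), c(0, 0, 1), tolerance = 1e-3)
  em2 <- admixture_vector_em(g, pan)
  expect_identical(em$q, em2$q)  # deterministic
})

test_that("interclass heterozygosity separates F1, backcross and pure", {
  pan <- diagnostic_panels(2000)
  expect_equal(interclass_heterozygosity(rep(1, 2000), pan)$H, 1)
  expect_equal(interclass_heterozygosity(rep(2, 2000), pan)$H, 0)
  bc <- simulate_genotypes("BC1P1", 1, pan, seed = 106)
  h <- interclass_heterozygosity(bc$genotypes[1, ], pan)
  expect_equal(h$n_diagnostic, 2000)
  expect_equal(h$H, 0.5, tolerance = 0.03 / 0.5)
  flat <- panel_freqs(rbind(rep(0.5, 10), rep(0.6, 10)))
  expect_error(interclass_heterozygosity(rep(1, 10), flat), "delta")
})

test_that("class windows map (q, H) to the documented calls", {
  expect_equal(classify_hybrid_class(0.50, 0.95), "F1")
  expect_equal(classify_hybrid_class(0.80, 0.50), "backcross_P1")
  expect_equal(classify_hybrid_class(0.20, 0.50), "backcross_P2")
  expect_equal(classify_hybrid_class(0.98, 0.02), "pure_P1")
  expect_equal(classify_hybrid_class(0.03, 0.01), "pure_P2")
  expect_equal(classify_hybrid_class(0.50, 0.30), "ambiguous")
  expect_error(classify_hybrid_class(1.2, 0.5), "0, 1")
})

test_that("cohort-level calls recover the simulated truth", {
  p <- simulate_parental_freqs(500, 0.3, seed = 107)
  pan <- panel_freqs(p$freqs)
  cohorts <- list(P1 = "pure_P1", F1 = "F1", BC1P1 = "backcross_P1")
  for (cls in names(cohorts)) {
    m <- simulate_genotypes(cls, 10, p, seed = derive(cls))
    calls <- call_hybrid_classes(m, pan)
    expect_gte(mean(calls$call == cohorts[[cls]]), 0.8)
  }
})
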