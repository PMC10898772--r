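test_that("assumption checks implement the per-group rules", {
  set.seed(201)
  norm3 <- list(H = rnorm(30), P1 = rnorm(30), P2 = rnorm(30))
  a <- check_assumptions(norm3)
  expect_type(a$normality_ok, "logical")
  expect_length(a$shapiro_p, 3)

  # type-I calibration of the normality gate across seeds
  ok <- vapply(1:200, function(i) {
    set.seed(i)
    check_assumptions(list(rnorm(30), rnorm(30), rnorm(30)))$normality_ok
  }, logical(1))
  expect_gte(mean(ok), 0.75)  # three gates at alpha 0.05 each

  # skewed, tie-heavy group is typically flagged
  bad <- vapply(1:50, function(i) {
    set.seed(i)
    check_assumptions(list(rexp(50), rnorm(50), rnorm(50)))$normality_ok
  }, logical(1))
  expect_lte(mean(bad), 0.1)

  # a group below the minimum size disallows the parametric path
  set.seed(202)
  tiny <- check_assumptions(list(rnorm(2), rnorm(30), rnorm(30)))
  expect_false(tiny$normality_ok)
  expect_error(check_assumptions(list(1, rnorm(5), rnorm(5))),
               "at least 2")
})

test_that("the omnibus test holds its size under the null", {
  set.seed(203)
  rejects <- vapply(1:300, function(i) {
    v <- list(H = rnorm(30), P1 = rnorm(30), P2 = rnorm(30))
    omnibus_and_posthoc(v)$p_value < 0.05
  }, logical(1))
  expect_equal(mean(rejects), 0.05, tolerance = 0.03 / 0.05)
})

test_that("well-separated groups are significant on both paths", {
  set.seed(204)
  v <- list(H = rnorm(20, 0), P1 = rnorm(20, 5), P2 = rnorm(20, 10))
  res <- omnibus_and_posthoc(v)
  expect_true(all(res$pairwise_p < 0.05))
  # force the nonparametric path by breaking normality (heavy skew)
  vskew <- lapply(v, function(x) exp(x / 2))
  res2 <- omnibus_and_posthoc(vskew)
  expect_equal(res2$path, "kruskal_dunn")
  expect_true(all(res2$pairwise_p < 0.05))
})

test_that("the parametric path matches aov/TukeyHSD computed directly", {
  set.seed(205)
  for (i in 1:5) {
    v <- list(H = rnorm(15, 1), P1 = rnorm(12, 0), P2 = rnorm(18, 2))
    res <- omnibus_and_posthoc(v)
    if (res$path != "anova_tukey") next
    y <- unlist(v); grp <- factor(rep(names(v), lengths(v)),
                                  levels = names(v))
    fit <- aov(y ~ grp)
    expect_equal(res$p_value, summary(fit)[[1]][1, "Pr(>F)"],
                 tolerance = 1e-10)
    if (res$p_value < 0.05) {
      tk <- TukeyHSD(fit)$grp
      expect_equal(unname(res$pairwise_p["H-P1"]),
                   unname(tk["P1-H", "p adj"]), tolerance = 1e-10)
    }
  }
})

test_that("Dunn z-tests reproduce a hand-worked example", {
  # groups (1,2,3), (4,5,6), (7,8,9): no ties, mean ranks 2, 5, 8
  # v0 = N(N+1)/12 = 7.5; z(1,2) = -3 / sqrt(7.5 * 2/3) = -1.34164
  v <- list(H = c(1, 2, 3), P1 = c(4, 5, 6), P2 = c(7, 8, 9))
  p <- hybridtraits:::dunn_test(v, adjust = "none")
  expect_equal(unname(p["H-P1"]), 2 * pnorm(-3 / sqrt(5)), tolerance = 1e-10)
  expect_equal(unname(p["H-P2"]), 2 * pnorm(-6 / sqrt(5)), tolerance = 1e-10)
  pb <- hybridtraits:::dunn_test(v, adjust = "bonferroni")
  expect_equal(unname(pb["H-P1"]),
               min(1, 3 * 2 * pnorm(-3 / sqrt(5))), tolerance = 1e-10)

  # tie correction: duplicated values lower the variance term
  vt <- list(H = c(1, 1, 2), P1 = c(2, 3, 3), P2 = c(4, 4, 5))
  pt <- hybridtraits:::dunn_test(vt, adjust = "none")
  expect_true(all(pt >= 0 & pt <= 1))
})

test_that("the nonparametric path is invariant under monotone transforms", {
  set.seed(206)
  v <- list(H = rexp(25), P1 = rexp(25) + 1, P2 = rexp(25) + 3)
  r1 <- omnibus_and_posthoc(v)
  r2 <- omnibus_and_posthoc(lapply(v, function(x) log(x + 1)))
  expect_equal(r1$path, "kruskal_dunn")
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
  expect_equal(unname(r1$pairwise_p), unname(r2$pairwise_p),
               tolerance = 1e-10)
})

test_that("identical values across groups short-circuit to p = 1", {
  v <- list(H = rep(2, 5), P1 = rep(2, 5), P2 = rep(2, 5))
  res <- omnibus_and_posthoc(v)
  expect_equal(res$p_value, 1)
  expect_true(all(is.na(res$pairwise_p)))
  expect_equal(classify_trait(res), "not_significant")
})

test_that("the classifier decision tree is total and matches its definition", {
  sig <- 0.001; ns <- 0.5
  # hybrid mean below / between / above the parents (parents at 0 and 10)
  mh_cases <- c(below = -3, between = 5, above = 13, at_parent = 10)
  combos <- expand.grid(hp1 = c(sig, ns), hp2 = c(sig, ns),
                        p12 = c(sig, ns), mh = mh_cases)
  for (i in seq_len(nrow(combos))) {
    cl <- classify_trait(fake_trait_test(combos$hp1[i], combos$hp2[i],
                                         combos$p12[i], combos$mh[i],
                                         0, 10))
    expect_true(cl %in% c("positive_transgressive", "negative_transgressive",
                          "intermediate", "parent1_like", "parent2_like",
                          "codominant", "not_significant"))
  }
  # specific mappings
  expect_equal(classify_trait(fake_trait_test(ns, sig, sig, 1, 0, 10)),
               "parent1_like")
  expect_equal(classify_trait(fake_trait_test(sig, ns, sig, 9, 0, 10)),
               "parent2_like")
  expect_equal(classify_trait(fake_trait_test(ns, ns, sig, 5, 0, 10)),
               "codominant")
  expect_equal(classify_trait(fake_trait_test(ns, ns, ns, 5, 0, 10)),
               "not_significant")
  expect_equal(classify_trait(fake_trait_test(sig, sig, sig, 5, 0, 10)),
               "intermediate")
  expect_equal(classify_trait(fake_trait_test(sig, sig, ns, 13, 0, 10)),
               "positive_transgressive")
  expect_equal(classify_trait(fake_trait_test(sig, sig, ns, -2, 0, 10)),
               "negative_transgressive")
  # boundary: hybrid mean exactly at a parental mean stays intermediate
  expect_equal(classify_trait(fake_trait_test(sig, sig, ns, 10, 0, 10)),
               "intermediate")
  # non-significant omnibus wins regardless of pairwise values
  expect_equal(classify_trait(fake_trait_test(sig, sig, sig, 13, 0, 10,
                                              omnibus_p = 0.6)),
               "not_significant")
})

test_that("relabeling the parents swaps the parent-like categories", {
  set.seed(207)
  tm <- planted_trait_model(reps = 1)
  tt <- simulate_traits(tm, "F1", c(P1 = 40, P2 = 40, H = 40), seed = 208)
  fwd <- classify_all(tt, hybrid = "H", parent1 = "P1", parent2 = "P2")
  rev <- classify_all(tt, hybrid = "H", parent1 = "P2", parent2 = "P1")
  swap <- c(parent1_like = "parent2_like", parent2_like = "parent1_like")
  for (i in seq_len(nrow(fwd$results))) {
    a <- fwd$results$classification[i]
    b <- rev$results$classification[i]
    expect_equal(b, if (a %in% names(swap)) swap[[a]] else a,
                 info = fwd$results$character[i])
  }
})

test_that("classify_all counts partition the analyzed characters", {
  tm <- planted_trait_model(reps = 2)
  tt <- simulate_traits(tm, "F1", c(P1 = 30, P2 = 30, H = 30), seed = 209)
  res <- classify_all(tt)
  expect_equal(sum(res$counts), nrow(res$results))
  expect_equal(nrow(res$results), nrow(tm))
  # all-missing group for one character -> skipped and reported
  tt$values[tt$group_labels == "H", tm$character[1]] <- NA
  res2 <- classify_all(tt)
  expect_equal(res2$skipped, tm$character[1])
  expect_equal(sum(res2$counts), nrow(tm) - 1)
})

test_that("mean/SE table matches the closed form", {
  sch <- default_trait_schema()
  tt <- trait_table(data.frame(AL = c(1, 2, 3, 4, 4, 4)),
                    group_labels = c("A", "A", "A", "B", "B", "B"))
  ms <- mean_se_table(tt)
  a <- ms[ms$group == "A", ]
  expect_equal(a$mean, 2)
  expect_equal(a$se, sd(c(1, 2, 3)) / sqrt(3), tolerance = 1e-12)
  expect_equal(a$se, 0.5773503, tolerance = 1e-6)
  b <- ms[ms$group == "B", ]
  expect_equal(b$se, 0)
})
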