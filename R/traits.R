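#' Configuration for the per-character trait test pathway
#'
#' @param alpha significance level for every test (default 0.05).
#' @param levene_center \code{"median"} (Brown-Forsythe, default) or
#'   \code{"mean"} centering for the variance-homogeneity test.
#' @param dunn_adjust p-value adjustment over the three pairwise Dunn
#'   comparisons: \code{"bonferroni"} (default), \code{"holm"} or
#'   \code{"none"}.
#' @param min_group_size smallest group size allowed on the parametric
#'   path (default 3; the normality check fails below it).
#' @return a \code{trait_test_config} list.
#' @export
trait_test_config <- function(alpha = 0.05, levene_center = c("median", "mean"),
                              dunn_adjust = c("bonferroni", "holm", "none"),
                              min_group_size = 3L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(alpha = alpha,
                 levene_center = match.arg(levene_center),
                 dunn_adjust = match.arg(dunn_adjust),
                 min_group_size = as.integer(min_group_size)),
            class = "trait_test_config")
}

#' Check normality and variance-homogeneity assumptions for three groups
#'
#' Normality holds iff every group passes Shapiro-Wilk at alpha and has
#' at least \code{min_group_size} observations (a constant group counts
#' as violating normality). Variance homogeneity holds iff Levene's test
#' (median-centered by default) is non-significant.
#'
#' @param values list of three numeric vectors (hybrid, parent1, parent2).
#' @param cfg a \code{\link{trait_test_config}}.
#' @return list with \code{normality_ok}, \code{variance_ok},
#'   \code{shapiro_p} (per group), \code{levene_p}.
#' @export
check_assumptions <- function(values, cfg = trait_test_config()) {
  if (any(vapply(values, length, integer(1)) < 2))
    stop("every group needs at least 2 observations")
  shapiro_p <- vapply(values, function(v) {
    if (length(v) < cfg$min_group_size) return(NA_real_)
    if (stats::sd(v) == 0) return(0)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  normality_ok <- !any(is.na(shapiro_p)) && all(shapiro_p >= cfg$alpha)
  y <- unlist(values, use.names = FALSE)
  grp <- factor(rep(seq_along(values), vapply(values, length, integer(1))))
  levene_p <- if (stats::sd(y) == 0) 1 else
    car::leveneTest(y, grp, center = cfg$levene_center)[1, "Pr(>F)"]
  list(normality_ok = normality_ok,
       variance_ok = levene_p >= cfg$alpha,
       shapiro_p = shapiro_p, levene_p = levene_p)
}

# Dunn's post-hoc z-tests after Kruskal-Wallis, with tie correction.
# Returns a named vector of (adjusted) two-sided p-values per pair.
dunn_test <- function(values, adjust = "bonferroni") {
  k <- length(values)
  n <- vapply(values, length, integer(1))
  N <- sum(n)
  r <- rank(unlist(values, use.names = FALSE))
  grp <- rep(seq_len(k), n)
  rbar <- tapply(r, grp, mean)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(k, 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    (rbar[i] - rbar[j]) / sqrt(v0 * (1 / n[i] + 1 / n[j]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  p <- stats::p.adjust(p, method = if (adjust == "none") "none" else adjust)
  names(p) <- apply(pairs, 2, function(ij)
    paste(names(values)[ij], collapse = "-"))
  p
}

#' Omnibus test and post-hoc pairwise comparisons for one character
#'
#' Chooses the parametric path (one-way ANOVA + Tukey-Kramer HSD) when
#' both assumptions hold, otherwise the nonparametric path
#' (Kruskal-Wallis with tie correction + Dunn's z-tests with the
#' configured adjustment). Post-hoc comparisons are computed only when
#' the omnibus test is significant at alpha; with a non-significant
#' omnibus the pairwise p-values are \code{NA}. If all values are
#' identical the omnibus p is 1.
#'
#' @param values named list of three numeric vectors, in the order
#'   hybrid, parent1, parent2.
#' @param cfg a \code{\link{trait_test_config}}.
#' @return a \code{trait_test} list: \code{path}, \code{assumptions},
#'   \code{statistic}, \code{p_value}, \code{pairwise_p} (named H-P1,
#'   H-P2, P1-P2), \code{means}, \code{se}.
#' @export
omnibus_and_posthoc <- function(values, cfg = trait_test_config()) {
  if (length(values) != 3) stop("exactly three groups are required")
  if (is.null(names(values))) names(values) <- c("H", "P1", "P2")
  means <- vapply(values, mean, numeric(1))
  se <- vapply(values, function(v) stats::sd(v) / sqrt(length(v)), numeric(1))
  y <- unlist(values, use.names = FALSE)
  grp <- factor(rep(names(values), vapply(values, length, integer(1))),
                levels = names(values))
  pair_names <- c(paste(names(values)[1], names(values)[2], sep = "-"),
                  paste(names(values)[1], names(values)[3], sep = "-"),
                  paste(names(values)[2], names(values)[3], sep = "-"))
  pairwise <- stats::setNames(rep(NA_real_, 3), pair_names)

  if (stats::sd(y) == 0) {
    return(structure(list(path = "degenerate",
                          assumptions = NULL, statistic = NA_real_,
                          p_value = 1, pairwise_p = pairwise,
                          means = means, se = se), class = "trait_test"))
  }
  assum <- check_assumptions(values, cfg)
  parametric <- assum$normality_ok && assum$variance_ok
  if (parametric) {
    fit <- stats::aov(y ~ grp)
    tab <- summary(fit)[[1]]
    stat <- tab[1, "F value"]
    p <- tab[1, "Pr(>F)"]
    if (p < cfg$alpha) {
      tk <- stats::TukeyHSD(fit)$grp
      # rows are named "g2-g1"; map onto our pair order
      for (pn in pair_names) {
        ab <- strsplit(pn, "-", fixed = TRUE)[[1]]
        row <- rownames(tk) %in% c(paste(ab[1], ab[2], sep = "-"),
                                   paste(ab[2], ab[1], sep = "-"))
        pairwise[pn] <- tk[row, "p adj"]
      }
    }
    path <- "anova_tukey"
  } else {
    kw <- stats::kruskal.test(y, grp)
    stat <- unname(kw$statistic)
    p <- kw$p.value
    if (!is.na(p) && p < cfg$alpha) {
      dp <- dunn_test(values, adjust = cfg$dunn_adjust)
      pairwise[names(dp)] <- dp
    }
    path <- "kruskal_dunn"
  }
  structure(list(path = path, assumptions = assum, statistic = stat,
                 p_value = p, pairwise_p = pairwise, means = means,
                 se = se), class = "trait_test")
}

#' Classify one character into the seven transgression categories
#'
#' Decision tree over the omnibus result, the three pairwise significance
#' calls (hybrid vs parent1, hybrid vs parent2, parent1 vs parent2) and
#' the ordering of the sample means: (1) omnibus non-significant or all
#' pairwise non-significant -> \code{not_significant}; (2) hybrid differs
#' from neither parent while the parents differ -> \code{codominant};
#' (3) hybrid differs from exactly one parent -> \code{parent1_like} /
#' \code{parent2_like} (like the parent it does NOT differ from);
#' (4) hybrid differs from both parents: mean above both ->
#' \code{positive_transgressive}, below both ->
#' \code{negative_transgressive}, otherwise (including a mean exactly
#' equal to a parental mean) -> \code{intermediate}.
#'
#' @param result a \code{trait_test} from
#'   \code{\link{omnibus_and_posthoc}}.
#' @param alpha significance level for the pairwise calls.
#' @return one of \code{"positive_transgressive"},
#'   \code{"negative_transgressive"}, \code{"intermediate"},
#'   \code{"parent1_like"}, \code{"parent2_like"}, \code{"codominant"},
#'   \code{"not_significant"}.
#' @export
classify_trait <- function(result, alpha = 0.05) {
  pw <- result$pairwise_p
  if (is.na(result$p_value) || result$p_value >= alpha || all(is.na(pw)))
    return("not_significant")
  s_hp1 <- !is.na(pw[1]) && pw[1] < alpha
  s_hp2 <- !is.na(pw[2]) && pw[2] < alpha
  s_p12 <- !is.na(pw[3]) && pw[3] < alpha
  mh <- result$means[1]; m1 <- result$means[2]; m2 <- result$means[3]
  if (!s_hp1 && !s_hp2) {
    if (s_p12) return("codominant")
    return("not_significant")
  }
  if (!s_hp1 && s_hp2) return("parent1_like")
  if (s_hp1 && !s_hp2) return("parent2_like")
  if (mh > max(m1, m2)) return("positive_transgressive")
  if (mh < min(m1, m2)) return("negative_transgressive")
  "intermediate"
}

#' Test and classify every quantitative character in a trait table
#'
#' Runs the assumption-gated test pathway and the seven-category
#' classification per quantitative character and tallies category
#' counts. Characters with fewer than two non-missing values in any
#' group are skipped and reported.
#'
#' @param traits a \code{\link{trait_table}}.
#' @param hybrid,parent1,parent2 group labels identifying the three
#'   cohorts.
#' @param cfg a \code{\link{trait_test_config}}.
#' @return list with \code{results} (data frame: character, path,
#'   omnibus statistic and p, pairwise p-values, group means/SE,
#'   classification), \code{counts} (named integer vector over the seven
#'   categories), \code{skipped} (character codes).
#' @export
classify_all <- function(traits, hybrid = "H", parent1 = "P1",
                         parent2 = "P2", cfg = trait_test_config()) {
  quant <- traits$schema$code[traits$schema$kind == "quantitative"]
  quant <- intersect(quant, colnames(traits$values))
  gl <- traits$group_labels
  for (g in c(hybrid, parent1, parent2))
    if (!any(gl == g)) stop("group '", g, "' absent from the trait table")
  cats <- c("positive_transgressive", "negative_transgressive",
            "intermediate", "parent1_like", "parent2_like", "codominant",
            "not_significant")
  rows <- list(); skipped <- character(0)
  for (cc in quant) {
    v <- traits$values[[cc]]
    by_grp <- list(H = v[gl == hybrid], P1 = v[gl == parent1],
                   P2 = v[gl == parent2])
    by_grp <- lapply(by_grp, function(x) x[!is.na(x)])
    if (any(vapply(by_grp, length, integer(1)) < 2)) {
      skipped <- c(skipped, cc)
      next
    }
    res <- omnibus_and_posthoc(by_grp, cfg)
    cl <- classify_trait(res, alpha = cfg$alpha)
    rows[[cc]] <- data.frame(
      character = cc, path = res$path, statistic = res$statistic,
      p_value = res$p_value,
      p_H_P1 = res$pairwise_p[1], p_H_P2 = res$pairwise_p[2],
      p_P1_P2 = res$pairwise_p[3],
      mean_H = res$means[1], se_H = res$se[1],
      mean_P1 = res$means[2], se_P1 = res$se[2],
      mean_P2 = res$means[3], se_P2 = res$se[3],
      classification = cl, stringsAsFactors = FALSE)
  }
  results <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
             else NULL
  counts <- stats::setNames(integer(length(cats)), cats)
  if (!is.null(results)) {
    tb <- table(factor(results$classification, levels = cats))
    counts[names(tb)] <- as.integer(tb)
  }
  list(results = results, counts = counts, skipped = skipped)
}

#' Per-character group means and standard errors
#'
#' @param traits a \code{\link{trait_table}}.
#' @return data frame: character, group, n, mean, se (SE = sample
#'   SD / sqrt(n), missing values excluded per character).
#' @export
mean_se_table <- function(traits) {
  quant <- traits$schema$code[traits$schema$kind == "quantitative"]
  quant <- intersect(quant, colnames(traits$values))
  gl <- traits$group_labels
  out <- list()
  for (cc in quant) {
    for (g in unique(gl)) {
      v <- traits$values[[cc]][gl == g]
      v <- v[!is.na(v)]
      out[[paste(cc, g)]] <- data.frame(
        character = cc, group = g, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        se = if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
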