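#' Simulate diverged parental allele-frequency panels
#'
#' Draws an ancestral alt-allele frequency per locus from a uniform
#' distribution and lets each population drift away from it under the
#' Balding-Nichols model: given ancestral frequency p and divergence F,
#' the population frequency is Beta(p(1-F)/F, (1-p)(1-F)/F), so that
#' E[p_pop] = p and Var[p_pop] = F p (1-p). \code{F = 0} short-circuits
#' to zero drift (all panels equal the ancestral frequencies).
#'
#' @param n_loci number of loci.
#' @param F divergence parameter per branch, in [0, 1).
#' @param seed integer RNG seed.
#' @param ancestral_bounds lower/upper bound of the ancestral frequency
#'   distribution, within (0, 1).
#' @param n_pops number of parental populations (default 2).
#' @return a \code{panel_freqs} object: list with \code{freqs}
#'   (populations x loci matrix) and \code{population_ids}.
#' @export
simulate_parental_freqs <- function(n_loci, F, seed,
                                    ancestral_bounds = c(0.1, 0.9),
                                    n_pops = 2) {
  if (F < 0 || F >= 1) stop("F must lie in [0, 1)")
  if (any(ancestral_bounds <= 0) || any(ancestral_bounds >= 1) ||
      ancestral_bounds[1] > ancestral_bounds[2])
    stop("ancestral_bounds must be an ordered interval within (0, 1)")
  with_seed(seed, {
    p0 <- stats::runif(n_loci, ancestral_bounds[1], ancestral_bounds[2])
    freqs <- matrix(NA_real_, nrow = n_pops, ncol = n_loci)
    for (k in seq_len(n_pops)) {
      freqs[k, ] <- if (F == 0) p0 else drift_bn(p0, F)
    }
    panel_freqs(freqs, paste0("P", seq_len(n_pops)))
  })
}

# One Balding-Nichols drift step of strength F applied to frequencies p.
# Frequencies already fixed at 0 or 1 stay fixed.
drift_bn <- function(p, F) {
  if (F <= 0) return(p)
  out <- p
  seg <- p > 0 & p < 1
  if (any(seg)) {
    a <- p[seg] * (1 - F) / F
    b <- (1 - p[seg]) * (1 - F) / F
    out[seg] <- stats::rbeta(sum(seg), a, b)
  }
  out
}

#' Construct a panel of per-population allele frequencies
#'
#' @param freqs populations x loci matrix of alt-allele frequencies.
#' @param population_ids character vector of population names.
#' @return a \code{panel_freqs} object.
#' @export
panel_freqs <- function(freqs, population_ids = rownames(freqs)) {
  freqs <- as.matrix(freqs)
  if (is.null(population_ids))
    population_ids <- paste0("P", seq_len(nrow(freqs)))
  if (nrow(freqs) < 2) stop("at least two populations are required")
  if (any(is.na(freqs)) || any(freqs < 0) || any(freqs > 1))
    stop("frequencies must lie in [0, 1]")
  rownames(freqs) <- population_ids
  structure(list(freqs = freqs, population_ids = as.character(population_ids)),
            class = "panel_freqs")
}

#' Simulate genotypes of a known hybrid class
#'
#' Genotypes are built gamete by gamete so that F1/F2/backcross classes
#' have the correct heterozygosity structure at diagnostic loci. Pure
#' classes draw both gametes Bernoulli(p) from their own panel; an F1
#' takes one gamete from each panel; an F1-derived gamete (used for F2 and
#' backcrosses) picks its panel of origin uniformly before the Bernoulli
#' draw; BC1 pairs one F1-derived gamete with one pure parental gamete.
#'
#' @param cls one of \code{"P1"}, \code{"P2"}, \code{"F1"}, \code{"F2"},
#'   \code{"BC1P1"}, \code{"BC1P2"}.
#' @param n number of individuals.
#' @param panels a two-population \code{\link{panel_freqs}}.
#' @param seed integer RNG seed.
#' @return a \code{\link{snp_matrix}} with group labels set to \code{cls}.
#' @export
simulate_genotypes <- function(cls, n, panels, seed) {
  cls <- match.arg(cls, c("P1", "P2", "F1", "F2", "BC1P1", "BC1P2"))
  if (nrow(panels$freqs) != 2)
    stop("simulate_genotypes requires exactly two parental panels")
  p1 <- panels$freqs[1, ]
  p2 <- panels$freqs[2, ]
  L <- length(p1)
  with_seed(seed, {
    gam_pure <- function(p) matrix(stats::rbinom(n * L, 1, rep(p, each = n)),
                                   nrow = n)
    gam_f1 <- function() {
      pick1 <- matrix(stats::runif(n * L) < 0.5, nrow = n)
      pm <- matrix(rep(p2, each = n), nrow = n)
      pm[pick1] <- matrix(rep(p1, each = n), nrow = n)[pick1]
      matrix(stats::rbinom(n * L, 1, pm), nrow = n)
    }
    g <- switch(cls,
      P1    = gam_pure(p1) + gam_pure(p1),
      P2    = gam_pure(p2) + gam_pure(p2),
      F1    = gam_pure(p1) + gam_pure(p2),
      F2    = gam_f1() + gam_f1(),
      BC1P1 = gam_f1() + gam_pure(p1),
      BC1P2 = gam_f1() + gam_pure(p2))
    colnames(g) <- paste0("L", seq_len(L))
    snp_matrix(g, sample_ids = paste0(cls, "_", seq_len(n)),
               group_labels = rep(cls, n))
  })
}

#' Trait model for the synthetic generator
#'
#' Per character: parental means \code{mu_P1}, \code{mu_P2} (trait units),
#' a common within-group standard deviation \code{sigma}, a dominance
#' coefficient \code{d} (F1 mean = midparent + d (mu_P1 - mu_P2) / 2) and
#' a transgression offset \code{tau} in units of sigma added to the
#' hybrid-group mean.
#'
#' @param character character codes.
#' @param mu_P1,mu_P2 parental group means.
#' @param sigma common within-group SD (> 0).
#' @param d dominance coefficient, in [-1.5, 1.5].
#' @param tau transgression offset in sigma units.
#' @return a \code{trait_model} data frame.
#' @export
trait_model <- function(character, mu_P1, mu_P2, sigma = 1, d = 0, tau = 0) {
  tm <- data.frame(character = as.character(character), mu_P1 = mu_P1,
                   mu_P2 = mu_P2, sigma = sigma, d = d, tau = tau,
                   stringsAsFactors = FALSE)
  if (any(tm$sigma <= 0)) stop("sigma must be positive")
  if (any(abs(tm$d) > 1.5)) stop("d must lie in [-1.5, 1.5]")
  if (any(!is.finite(tm$tau))) stop("tau must be finite")
  class(tm) <- c("trait_model", "data.frame")
  tm
}

# Expected hybrid-group mean under the additive/dominance model,
# before the transgression offset.
hybrid_class_mean <- function(mu1, mu2, d, cls) {
  mid <- (mu1 + mu2) / 2
  f1 <- mid + d * (mu1 - mu2) / 2
  switch(cls,
         P1 = mu1, P2 = mu2, F1 = f1,
         F2 = mid + d * (mu1 - mu2) / 4,
         BC1P1 = (f1 + mu1) / 2,
         BC1P2 = (f1 + mu2) / 2)
}

#' Simulate per-group quantitative traits
#'
#' Draws Normal(mu_group, sigma) values per character for the two parental
#' groups and a hybrid group whose mean follows the additive/dominance
#' model of the hybrid class (BC1 means sit halfway between the F1 mean
#' and the recurrent parent), plus \code{tau * sigma}.
#'
#' @param model a \code{\link{trait_model}}.
#' @param hybrid_cls hybrid class of the H group (e.g. \code{"F1"},
#'   \code{"BC1P1"}).
#' @param group_sizes named counts for \code{P1}, \code{P2}, \code{H}
#'   (each >= 2).
#' @param seed integer RNG seed.
#' @param schema trait schema for the resulting table; characters absent
#'   from the bundled schema are carried with a quantitative ad-hoc schema.
#' @return a \code{\link{trait_table}} with groups P1, P2 and H.
#' @export
simulate_traits <- function(model, hybrid_cls, group_sizes, seed,
                            schema = NULL) {
  if (any(group_sizes < 2)) stop("each group needs at least 2 individuals")
  hybrid_cls <- match.arg(hybrid_cls,
                          c("P1", "P2", "F1", "F2", "BC1P1", "BC1P2"))
  n1 <- group_sizes[["P1"]]; n2 <- group_sizes[["P2"]]; nh <- group_sizes[["H"]]
  groups <- c(rep("P1", n1), rep("P2", n2), rep("H", nh))
  with_seed(seed, {
    vals <- sapply(seq_len(nrow(model)), function(i) {
      mu1 <- model$mu_P1[i]; mu2 <- model$mu_P2[i]
      s <- model$sigma[i]
      muh <- hybrid_class_mean(mu1, mu2, model$d[i], hybrid_cls) +
        model$tau[i] * s
      c(stats::rnorm(n1, mu1, s), stats::rnorm(n2, mu2, s),
        stats::rnorm(nh, muh, s))
    })
    vals <- matrix(vals, nrow = length(groups),
                   dimnames = list(NULL, model$character))
    if (is.null(schema)) {
      schema <- default_trait_schema()
      extra <- setdiff(model$character, schema$code)
      if (length(extra))
        schema <- rbind(schema,
                        data.frame(code = extra, description = extra,
                                   kind = "quantitative",
                                   encoding = NA_character_))
      class(schema) <- c("trait_schema", "data.frame")
    }
    trait_table(vals, group_labels = groups, schema = schema)
  })
}

#' Set genotype calls to missing at random
#'
#' Each call is independently set missing with the given probability;
#' locus metadata and group labels are untouched.
#'
#' @param m a \code{snp_matrix}.
#' @param rate missing probability in [0, 1].
#' @param seed integer RNG seed.
#' @return a \code{snp_matrix}.
#' @export
inject_missingness <- function(m, rate, seed) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if (rate == 0) return(m)
  with_seed(seed, {
    g <- m$genotypes
    drop <- matrix(stats::runif(length(g)) < rate, nrow = nrow(g))
    g[drop] <- NA
    snp_matrix(g, sample_ids = m$sample_ids, locus_meta = m$locus_meta,
               group_labels = unname(m$group_labels))
  })
}
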