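#' Admixture calling configuration
#'
#' Class windows follow first principles: an F1 expects ancestry q = 0.5
#' with interclass heterozygosity near 1, a first backcross expects
#' q = 0.75 with H near 0.5, a pure parent q near 1 (or 0). Windows are
#' applied pure -> F1 -> backcross -> ambiguous.
#'
#' @param pseudocount added allele count per allele when estimating panel
#'   frequencies (default 0.5, Jeffreys-like, keeps likelihoods finite at
#'   fixed loci).
#' @param diagnostic_delta minimum |p1 - p2| for a locus to count as
#'   ancestry-diagnostic in the H statistic (default 0.8).
#' @param pure_q minimum q (toward either parent) for a pure call.
#' @param f1_q two-sided q window for an F1 call.
#' @param f1_h minimum H for an F1 call.
#' @param backcross_q q window (toward parent 1) for a backcross call;
#'   mirrored for parent 2.
#' @param grid_step coarse grid resolution for the likelihood maximizer.
#' @param em_tol,em_max_iter EM convergence tolerance and iteration cap.
#' @return an \code{admixture_config} list.
#' @export
admixture_config <- function(pseudocount = 0.5, diagnostic_delta = 0.8,
                             pure_q = 0.9, f1_q = c(0.40, 0.60), f1_h = 0.8,
                             backcross_q = c(0.60, 0.90),
                             grid_step = 0.005, em_tol = 1e-8,
                             em_max_iter = 1000L) {
  structure(list(pseudocount = pseudocount,
                 diagnostic_delta = diagnostic_delta,
                 pure_q = pure_q, f1_q = f1_q, f1_h = f1_h,
                 backcross_q = backcross_q, grid_step = grid_step,
                 em_tol = em_tol, em_max_iter = as.integer(em_max_iter)),
            class = "admixture_config")
}

#' Estimate reference-panel allele frequencies from labeled samples
#'
#' Per population and locus: p = (alt allele count + pseudocount) /
#' (called alleles + 2 pseudocount). A population with zero called
#' alleles at a locus gets p = 0.5 with a warning.
#'
#' @param m a \code{snp_matrix}.
#' @param labels named character vector sample -> population, or
#'   \code{NULL} to use the matrix's group labels.
#' @param pseudocount nonnegative shrinkage count (default 0.5).
#' @return a \code{\link{panel_freqs}}.
#' @export
estimate_panel_freqs <- function(m, labels = m$group_labels,
                                 pseudocount = 0.5) {
  if (is.null(labels)) stop("population labels are required")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  labels <- labels[m$sample_ids]
  pops <- sort(unique(labels[!is.na(labels)]))
  if (!length(pops)) stop("no labeled samples")
  freqs <- matrix(NA_real_, nrow = length(pops), ncol = n_loci(m))
  warned <- FALSE
  for (k in seq_along(pops)) {
    g <- m$genotypes[!is.na(labels) & labels == pops[k], , drop = FALSE]
    alt <- colSums(g, na.rm = TRUE)
    an <- 2 * colSums(!is.na(g))
    p <- (alt + pseudocount) / (an + 2 * pseudocount)
    if (any(an == 0)) {
      p[an == 0] <- 0.5
      warned <- TRUE
    }
    freqs[k, ] <- p
  }
  if (warned)
    warning("population(s) with zero called alleles at some loci; p set to 0.5")
  colnames(freqs) <- colnames(m$genotypes)
  panel_freqs(freqs, pops)
}

# Log-likelihood of one individual's dosages at ancestry q for two panels.
# Each of the 2 allele copies comes from panel 1 with probability q.
hi_loglik <- function(q, g, p1, p2) {
  pa <- q * p1 + (1 - q) * p2
  pa <- pmin(pmax(pa, 1e-12), 1 - 1e-12)
  sum(stats::dbinom(g, 2, pa, log = TRUE))
}

# Vectorized grid evaluation of hi_loglik: one matrix dbinom call.
hi_loglik_grid <- function(grid, g, p1, p2) {
  pa <- grid %o% p1 + (1 - grid) %o% p2
  pa <- pmin(pmax(pa, 1e-12), 1 - 1e-12)
  gm <- matrix(g, nrow = length(grid), ncol = length(g), byrow = TRUE)
  rowSums(stats::dbinom(gm, 2, pa, log = TRUE))
}

#' Maximum-likelihood hybrid index against two parental panels
#'
#' The hybrid index q is the ancestry proportion toward parent 1: each of
#' an individual's two allele copies at a locus descends from panel 1
#' with probability q, so the alt-allele probability is
#' q p1 + (1 - q) p2 and the genotype is Binomial(2, .). The likelihood
#' is maximized on a coarse grid refined by golden-section search; the
#' support interval collects all q within 2 log-likelihood units of the
#' maximum.
#'
#' @param g one individual's dosage vector (0/1/2/NA).
#' @param panels a two-population \code{\link{panel_freqs}}.
#' @param grid_step coarse grid resolution (default 0.005).
#' @param support compute the 2-unit log-likelihood support interval
#'   (default \code{TRUE}; skipping it saves a fine-grid sweep).
#' @return list with \code{q}, \code{q_support} (length-2 interval, or
#'   \code{NA} when not requested), \code{loglik} and \code{n_loci} used.
#' @export
hybrid_index <- function(g, panels, grid_step = 0.005, support = TRUE) {
  if (nrow(panels$freqs) != 2) stop("hybrid_index requires two panels")
  p1 <- panels$freqs[1, ]; p2 <- panels$freqs[2, ]
  use <- !is.na(g)
  if (!any(use)) stop("all loci missing for this individual")
  if (all(p1[use] == p2[use]))
    stop("panels identical at every called locus: q unidentifiable")
  g <- g[use]; p1 <- p1[use]; p2 <- p2[use]

  grid <- seq(0, 1, by = grid_step)
  ll <- hi_loglik_grid(grid, g, p1, p2)
  i <- which.max(ll)
  lo <- max(0, grid[i] - grid_step)
  hi <- min(1, grid[i] + grid_step)
  opt <- stats::optimize(hi_loglik, interval = c(lo, hi), g = g, p1 = p1,
                         p2 = p2, maximum = TRUE, tol = 1e-9)
  q_hat <- opt$maximum
  ll_hat <- opt$objective
  if (ll[i] > ll_hat) { q_hat <- grid[i]; ll_hat <- ll[i] }

  supp <- c(NA_real_, NA_real_)
  if (support) {
    fine <- seq(0, 1, by = 0.001)
    llf <- hi_loglik_grid(fine, g, p1, p2)
    supp <- range(fine[llf >= ll_hat - 2])
  }
  list(q = q_hat, q_support = supp, loglik = ll_hat, n_loci = length(g))
}

#' EM estimate of a K-way ancestry vector
#'
#' Supervised analogue of model-based clustering output for K reference
#' panels: maximizes the binomial mixture likelihood
#' sum_l log Binomial(g_l; 2, sum_k q_k p_kl) over the probability
#' simplex by expectation-maximization on allele-origin indicators. The
#' log-likelihood is non-decreasing across iterations.
#'
#' @param g one individual's dosage vector.
#' @param panels a \code{\link{panel_freqs}} with K >= 2 populations.
#' @param tol stop when the log-likelihood gain falls below this.
#' @param max_iter iteration cap; non-convergence returns the last
#'   iterate with \code{converged = FALSE}.
#' @return list with \code{q} (length K, sums to 1), \code{loglik} (per
#'   iteration trace), \code{converged}.
#' @export
admixture_vector_em <- function(g, panels, tol = 1e-8, max_iter = 1000L) {
  P <- panels$freqs
  K <- nrow(P)
  use <- !is.na(g)
  if (!any(use)) stop("all loci missing for this individual")
  g <- g[use]
  P <- pmin(pmax(P[, use, drop = FALSE], 1e-9), 1 - 1e-9)
  q <- rep(1 / K, K)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    pa <- as.vector(q %*% P)              # alt-allele prob per locus
    ll <- sum(stats::dbinom(g, 2, pa, log = TRUE))
    ll_trace <- c(ll_trace, ll)
    # E-step: expected allele-origin counts per panel
    walt <- sweep(P, 1, q, `*`)           # q_k p_kl
    wref <- sweep(1 - P, 1, q, `*`)       # q_k (1 - p_kl)
    walt <- sweep(walt, 2, colSums(walt), `/`)
    wref <- sweep(wref, 2, colSums(wref), `/`)
    counts <- walt %*% g + wref %*% (2 - g)
    q_new <- as.vector(counts) / (2 * length(g))
    if (it > 1 && ll - ll_trace[it - 1] < tol) {
      converged <- TRUE
      break
    }
    q <- q_new
  }
  names(q) <- panels$population_ids
  list(q = q, loglik = ll_trace, converged = converged)
}

#' Interclass heterozygosity at ancestry-diagnostic loci
#'
#' H is the fraction of non-missing diagnostic loci (panel frequency
#' difference |p1 - p2| >= delta) at which the individual is heterozygous.
#' H is near 1 for F1 hybrids, near 0.5 for first backcrosses, near 0 for
#' pure parents.
#'
#' @param g one individual's dosage vector.
#' @param panels a two-population \code{\link{panel_freqs}}.
#' @param delta minimum panel frequency difference (default 0.8).
#' @return list with \code{H} and \code{n_diagnostic}.
#' @export
interclass_heterozygosity <- function(g, panels, delta = 0.8) {
  if (nrow(panels$freqs) != 2)
    stop("interclass_heterozygosity requires two panels")
  diag <- abs(panels$freqs[1, ] - panels$freqs[2, ]) >= delta
  use <- diag & !is.na(g)
  if (!any(use))
    stop("no diagnostic loci at delta = ", delta, "; lower delta")
  list(H = mean(g[use] == 1), n_diagnostic = sum(use))
}

#' Rule-based hybrid class call from (q, H)
#'
#' Windows (applied pure -> F1 -> backcross -> ambiguous): q >= pure_q
#' toward either parent is a pure call; q within \code{f1_q} with
#' H >= \code{f1_h} is F1; q within \code{backcross_q} (toward parent 1,
#' mirrored for parent 2) is a backcross; anything else is ambiguous.
#'
#' @param q admixture proportion toward parent 1, in [0, 1].
#' @param H interclass heterozygosity, in [0, 1].
#' @param cfg an \code{\link{admixture_config}}.
#' @return the call as a character scalar: one of \code{pure_P1},
#'   \code{pure_P2}, \code{F1}, \code{backcross_P1}, \code{backcross_P2},
#'   \code{ambiguous}.
#' @export
classify_hybrid_class <- function(q, H, cfg = admixture_config()) {
  if (q < 0 || q > 1 || H < 0 || H > 1) stop("q and H must lie in [0, 1]")
  if (q >= cfg$pure_q) return("pure_P1")
  if (q <= 1 - cfg$pure_q) return("pure_P2")
  if (q >= cfg$f1_q[1] && q <= cfg$f1_q[2] && H >= cfg$f1_h) return("F1")
  if (q > cfg$backcross_q[1] && q <= cfg$backcross_q[2])
    return("backcross_P1")
  if (q >= 1 - cfg$backcross_q[2] && q < 1 - cfg$backcross_q[1])
    return("backcross_P2")
  "ambiguous"
}

#' Per-individual hybrid class calls for a whole matrix
#'
#' Convenience wrapper: estimates q (with support interval) and H for
#' every sample against the two parental panels and applies the class
#' windows.
#'
#' @param m a \code{snp_matrix}.
#' @param panels a two-population \code{\link{panel_freqs}}.
#' @param cfg an \code{\link{admixture_config}}.
#' @return data frame: sample, q, q_lo, q_hi, H, n_diagnostic, call.
#' @export
call_hybrid_classes <- function(m, panels, cfg = admixture_config()) {
  rows <- lapply(m$sample_ids, function(s) {
    g <- m$genotypes[s, ]
    hi <- hybrid_index(g, panels, grid_step = cfg$grid_step)
    ih <- interclass_heterozygosity(g, panels, delta = cfg$diagnostic_delta)
    data.frame(sample = s, q = hi$q, q_lo = hi$q_support[1],
               q_hi = hi$q_support[2], H = ih$H,
               n_diagnostic = ih$n_diagnostic,
               call = classify_hybrid_class(hi$q, ih$H, cfg),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
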