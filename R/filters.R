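#' Locus filter configuration
#'
#' Thresholds for the five-stage filtering cascade. All keep decisions are
#' inclusive: a locus is kept when its statistic is greater than or equal
#' to the threshold.
#'
#' @param callrate_threshold minimum per-locus call rate (default 0.95).
#' @param reproducibility_threshold minimum reproducibility score
#'   (default 1.0 — any locus scored below 1 is removed).
#' @param maf_threshold minimum minor allele frequency (default 0.05).
#' @param secondaries_seed seed for the random one-SNP-per-tag choice.
#' @param strict_callrate if \code{TRUE}, append a 100\% call-rate stage
#'   after the MAF stage, leaving only loci with no missing data.
#' @return a \code{filter_config} list.
#' @export
filter_config <- function(callrate_threshold = 0.95,
                          reproducibility_threshold = 1.0,
                          maf_threshold = 0.05,
                          secondaries_seed = 1L,
                          strict_callrate = FALSE) {
  for (v in c(callrate_threshold, reproducibility_threshold, maf_threshold))
    if (v < 0 || v > 1) stop("thresholds must lie in [0, 1]")
  structure(list(callrate_threshold = callrate_threshold,
                 reproducibility_threshold = reproducibility_threshold,
                 maf_threshold = maf_threshold,
                 secondaries_seed = as.integer(secondaries_seed),
                 strict_callrate = isTRUE(strict_callrate)),
            class = "filter_config")
}

#' Remove monomorphic loci
#'
#' Polymorphism is judged at the allele level: a locus is kept iff both
#' alleles are observed among non-missing calls, i.e. it has at least one
#' heterozygote or both homozygote classes. An all-heterozygote locus is
#' polymorphic; a locus with only 0s (or only 2s) is not.
#'
#' @param m a \code{snp_matrix}.
#' @return a filtered \code{snp_matrix}.
#' @export
filter_monomorphic <- function(m) {
  g <- m$genotypes
  n_called <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  keep <- n_called > 0 & alt > 0 & alt < 2 * n_called
  if (!any(keep)) stop("all loci are monomorphic: empty matrix")
  subset_loci(m, keep)
}

#' Filter loci by call rate
#'
#' @param m a \code{snp_matrix}.
#' @param threshold minimum fraction of non-missing calls; a locus is
#'   kept when call rate >= threshold.
#' @return a filtered \code{snp_matrix}.
#' @export
filter_callrate <- function(m, threshold = 0.95) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  cr <- colMeans(!is.na(m$genotypes))
  subset_loci(m, cr >= threshold)
}

#' Filter loci by reproducibility score
#'
#' Loci whose DArT reproducibility falls below the threshold are removed;
#' data lacking the score carry the default score 1, so the filter is a
#' no-op there.
#'
#' @param m a \code{snp_matrix}.
#' @param threshold minimum reproducibility; keep when >= threshold.
#' @return a filtered \code{snp_matrix}.
#' @export
filter_reproducibility <- function(m, threshold = 1.0) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  subset_loci(m, m$locus_meta$reproducibility >= threshold)
}

#' Remove secondaries: keep one random SNP per sequence tag
#'
#' SNPs sharing a sequence tag are tightly linked; one per tag is kept,
#' chosen uniformly at random under the given seed so the survivor set is
#' reproducible. Loci with a missing tag id are each treated as their own
#' tag, with a warning.
#'
#' @param m a \code{snp_matrix}.
#' @param seed integer RNG seed for the per-tag choice.
#' @return a filtered \code{snp_matrix}.
#' @export
filter_secondaries <- function(m, seed = 1L) {
  tags <- m$locus_meta$tag_id
  if (any(is.na(tags) | tags == "")) {
    warning("loci with missing tag_id treated as singleton tags")
    miss <- is.na(tags) | tags == ""
    tags[miss] <- paste0(".singleton", seq_len(sum(miss)))
  }
  keep <- with_seed(seed, {
    idx <- split(seq_along(tags), tags)
    sort(vapply(idx, function(i) {
      if (length(i) == 1L) i else i[sample.int(length(i), 1L)]
    }, integer(1)))
  })
  subset_loci(m, keep)
}

#' Filter loci by minor allele frequency
#'
#' MAF is computed on non-missing calls as min(p, 1 - p) with p the mean
#' dosage divided by 2; a locus is kept when MAF >= threshold. Loci with
#' no non-missing call are removed with a warning.
#'
#' @param m a \code{snp_matrix}.
#' @param threshold minimum MAF, in [0, 0.5].
#' @return a filtered \code{snp_matrix}.
#' @export
filter_maf <- function(m, threshold = 0.05) {
  if (threshold < 0 || threshold > 0.5) stop("threshold must lie in [0, 0.5]")
  g <- m$genotypes
  called <- colSums(!is.na(g))
  if (any(called == 0))
    warning(sum(called == 0), " locus/loci with no calls removed")
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- called > 0 & maf >= threshold
  subset_loci(m, keep)
}

#' Run the full locus filtering cascade
#'
#' Applies, in order: monomorphic removal, call-rate filter,
#' reproducibility filter, secondaries removal (one random SNP per tag),
#' and MAF filter; with \code{strict_callrate} a final 100\% call-rate
#' stage is appended after MAF, leaving only loci with no missing data.
#' A per-stage audit report records locus counts before/after each stage.
#'
#' @param m a \code{snp_matrix}.
#' @param cfg a \code{\link{filter_config}}.
#' @return list with \code{matrix} (the filtered \code{snp_matrix}) and
#'   \code{report} (data frame: stage, loci_before, loci_removed,
#'   loci_after).
#' @export
run_filter_cascade <- function(m, cfg = filter_config()) {
  stages <- list(
    monomorphic     = function(x) filter_monomorphic(x),
    callrate        = function(x) filter_callrate(x, cfg$callrate_threshold),
    reproducibility = function(x)
      filter_reproducibility(x, cfg$reproducibility_threshold),
    secondaries     = function(x) filter_secondaries(x, cfg$secondaries_seed),
    maf             = function(x) filter_maf(x, cfg$maf_threshold))
  if (cfg$strict_callrate)
    stages$strict_callrate <- function(x) filter_callrate(x, 1.0)

  report <- data.frame(stage = character(0), loci_before = integer(0),
                       loci_removed = integer(0), loci_after = integer(0),
                       stringsAsFactors = FALSE)
  cur <- m
  for (nm in names(stages)) {
    before <- n_loci(cur)
    cur <- stages[[nm]](cur)
    after <- n_loci(cur)
    report <- rbind(report,
                    data.frame(stage = nm, loci_before = before,
                               loci_removed = before - after,
                               loci_after = after, stringsAsFactors = FALSE))
  }
  if (n_loci(cur) == 0) stop("filter cascade removed every locus")
  list(matrix = cur, report = report)
}
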