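#' Construct a SNP dosage matrix
#'
#' The central genotype container: an individuals x loci matrix of
#' alt-allele dosages (0, 1, 2 or \code{NA} for a missing call) together
#' with per-locus metadata (locus id, sequence-tag id, reproducibility
#' score) and optional per-sample population labels.
#'
#' @param genotypes numeric matrix, one row per individual, one column per
#'   locus; values must be 0, 1, 2 or \code{NA}.
#' @param sample_ids character vector of unique sample identifiers;
#'   defaults to the matrix rownames.
#' @param locus_meta data frame with columns \code{locus_id},
#'   \code{tag_id} and \code{reproducibility} (one row per locus). Missing
#'   columns are filled with defaults: \code{tag_id = locus_id},
#'   \code{reproducibility = 1} (so a reproducibility filter is a no-op on
#'   data lacking the score).
#' @param group_labels optional character vector of population labels, one
#'   per sample.
#' @return an object of class \code{snp_matrix}.
#' @export
snp_matrix <- function(genotypes, sample_ids = rownames(genotypes),
                       locus_meta = NULL, group_labels = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(genotypes)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (length(sample_ids) != nrow(genotypes))
    stop("sample_ids length must equal the number of rows")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2 or NA")

  if (is.null(locus_meta)) {
    ids <- colnames(genotypes)
    if (is.null(ids)) ids <- paste0("L", seq_len(ncol(genotypes)))
    locus_meta <- data.frame(locus_id = ids, stringsAsFactors = FALSE)
  }
  locus_meta <- as.data.frame(locus_meta, stringsAsFactors = FALSE)
  if (nrow(locus_meta) != ncol(genotypes))
    stop("locus_meta must have one row per locus")
  if (is.null(locus_meta$locus_id))
    locus_meta$locus_id <- paste0("L", seq_len(ncol(genotypes)))
  locus_meta$locus_id <- as.character(locus_meta$locus_id)
  if (anyDuplicated(locus_meta$locus_id)) stop("duplicate locus_id")
  if (is.null(locus_meta$tag_id)) locus_meta$tag_id <- locus_meta$locus_id
  locus_meta$tag_id <- as.character(locus_meta$tag_id)
  if (is.null(locus_meta$reproducibility)) locus_meta$reproducibility <- 1
  rep_ok <- locus_meta$reproducibility
  if (any(is.na(rep_ok)) || any(rep_ok < 0) || any(rep_ok > 1))
    stop("reproducibility must lie in [0, 1]")

  if (!is.null(group_labels)) {
    group_labels <- as.character(group_labels)
    if (length(group_labels) != length(sample_ids))
      stop("group_labels must have one entry per sample")
    names(group_labels) <- sample_ids
  }

  rownames(genotypes) <- sample_ids
  colnames(genotypes) <- locus_meta$locus_id
  structure(
    list(genotypes = genotypes, sample_ids = sample_ids,
         group_labels = group_labels, locus_meta = locus_meta),
    class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("snp_matrix: %d samples x %d loci\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  if (!is.null(x$group_labels)) {
    tb <- table(x$group_labels)
    cat("  groups:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Number of samples / loci in a snp_matrix
#' @param m a \code{snp_matrix}
#' @return integer count
#' @export
n_samples <- function(m) nrow(m$genotypes)

#' @rdname n_samples
#' @export
n_loci <- function(m) ncol(m$genotypes)

#' Subset a snp_matrix by locus index
#'
#' Keeps the sample set intact; used by every locus filter.
#'
#' @param m a \code{snp_matrix}
#' @param keep logical or integer index over loci
#' @return a \code{snp_matrix} with the selected loci
#' @export
subset_loci <- function(m, keep) {
  snp_matrix(m$genotypes[, keep, drop = FALSE],
             sample_ids = m$sample_ids,
             locus_meta = m$locus_meta[keep, , drop = FALSE],
             group_labels = unname(m$group_labels))
}

# Run code under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Deterministically derive a sub-seed from a base seed and a stage name.
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}
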