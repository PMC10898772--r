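#' Read a genotype CSV in one-row dosage or two-row presence/absence form
#'
#' Two dialects are supported. \code{dosage_one_row}: one row per locus,
#' metadata columns (\code{locus_id}, optionally \code{tag_id},
#' \code{reproducibility}) followed by one column per sample holding the
#' alt-allele dosage 0/1/2 or the missing sentinel. \code{dart_two_row}:
#' DArT-style scoring with two consecutive rows per locus sharing a
#' \code{locus_id} — the first row scores presence (1) / absence (0) of the
#' reference allele, the second of the alternative allele. Presence pairs
#' map to dosage as (ref, alt): (1,0) -> 0, (1,1) -> 1, (0,1) -> 2,
#' (0,0) -> missing.
#'
#' @param path path to the CSV file; header row names the samples.
#' @param dialect \code{"dosage_one_row"} or \code{"dart_two_row"}.
#' @param missing sentinel string for a missing call in the one-row
#'   dialect (default \code{"-"}).
#' @return a \code{\link{snp_matrix}}.
#' @export
read_genotype_csv <- function(path, dialect = c("dosage_one_row", "dart_two_row"),
                              missing = "-") {
  dialect <- match.arg(dialect)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!"locus_id" %in% colnames(raw)) stop("genotype CSV needs a locus_id column")
  meta_cols <- intersect(c("locus_id", "tag_id", "reproducibility"), colnames(raw))
  sample_cols <- setdiff(colnames(raw), meta_cols)
  if (!length(sample_cols)) stop("genotype CSV has no sample columns")

  if (dialect == "dosage_one_row") {
    ids <- raw$locus_id
    if (anyDuplicated(ids)) stop("duplicate locus_id")
    g <- as.matrix(raw[, sample_cols, drop = FALSE])
    g[g == missing] <- NA
    g <- matrix(as.numeric(g), nrow = nrow(raw),
                dimnames = list(NULL, sample_cols))
    ok <- g[!is.na(g)]
    if (length(ok) && !all(ok %in% c(0, 1, 2)))
      stop("dosage outside {0, 1, 2}")
    meta <- build_locus_meta(raw, ids)
  } else {
    if (nrow(raw) %% 2 != 0)
      stop("two-row dialect requires an even number of rows")
    idx_ref <- seq(1, nrow(raw), by = 2)
    idx_alt <- idx_ref + 1
    ids <- raw$locus_id[idx_ref]
    if (!all(ids == raw$locus_id[idx_alt]))
      stop("two-row dialect: row pairs must share locus_id")
    if (anyDuplicated(ids)) stop("duplicate locus_id")
    pres <- as.matrix(raw[, sample_cols, drop = FALSE])
    pres <- matrix(as.numeric(pres), nrow = nrow(raw))
    if (any(is.na(pres)) || !all(pres %in% c(0, 1)))
      stop("two-row dialect: presence scores must be 0 or 1")
    ref <- pres[idx_ref, , drop = FALSE]
    alt <- pres[idx_alt, , drop = FALSE]
    g <- matrix(NA_real_, nrow = length(ids), ncol = length(sample_cols),
                dimnames = list(NULL, sample_cols))
    g[ref == 1 & alt == 0] <- 0
    g[ref == 1 & alt == 1] <- 1
    g[ref == 0 & alt == 1] <- 2
    meta <- build_locus_meta(raw[idx_ref, , drop = FALSE], ids)
  }
  snp_matrix(t(g), sample_ids = sample_cols, locus_meta = meta)
}

build_locus_meta <- function(raw, ids) {
  meta <- data.frame(locus_id = ids, stringsAsFactors = FALSE)
  if ("tag_id" %in% colnames(raw)) meta$tag_id <- raw$tag_id
  if ("reproducibility" %in% colnames(raw))
    meta$reproducibility <- as.numeric(raw$reproducibility)
  meta
}

#' Write a genotype CSV
#'
#' Inverse of \code{\link{read_genotype_csv}} for both dialects; group
#' labels are not part of the file format and must be tracked separately.
#'
#' @param m a \code{snp_matrix}.
#' @param path output path.
#' @param dialect \code{"dosage_one_row"} or \code{"dart_two_row"}.
#' @param missing missing sentinel for the one-row dialect.
#' @export
write_genotype_csv <- function(m, path,
                               dialect = c("dosage_one_row", "dart_two_row"),
                               missing = "-") {
  dialect <- match.arg(dialect)
  meta <- m$locus_meta[, intersect(c("locus_id", "tag_id", "reproducibility"),
                                   colnames(m$locus_meta)), drop = FALSE]
  g <- t(m$genotypes)  # loci x samples
  if (dialect == "dosage_one_row") {
    vals <- matrix(as.character(g), nrow = nrow(g))
    vals[is.na(g)] <- missing
    out <- cbind(meta, as.data.frame(vals, stringsAsFactors = FALSE))
    colnames(out) <- c(colnames(meta), m$sample_ids)
  } else {
    ref <- ifelse(is.na(g), 0, ifelse(g <= 1, 1, 0))
    alt <- ifelse(is.na(g), 0, ifelse(g >= 1, 1, 0))
    n <- nrow(g)
    inter <- matrix(NA_real_, nrow = 2 * n, ncol = ncol(g))
    inter[seq(1, 2 * n, by = 2), ] <- ref
    inter[seq(2, 2 * n, by = 2), ] <- alt
    meta2 <- meta[rep(seq_len(n), each = 2), , drop = FALSE]
    out <- cbind(meta2, as.data.frame(inter, stringsAsFactors = FALSE))
    colnames(out) <- c(colnames(meta), m$sample_ids)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genotypes from a minimal VCF
#'
#' Reads the GT field of a VCF; biallelic SNP records are converted to
#' alt-allele dosage (0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2, ./. -> missing);
#' non-biallelic records are skipped with a warning. Reproducibility
#' metadata defaults to 1.
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @return a \code{\link{snp_matrix}}.
#' @export
read_vcf_minimal <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  if (any(!bi))
    warning(sum(!bi), " non-biallelic record(s) skipped")
  if (!any(bi)) stop("no biallelic records in VCF")
  vcf <- vcf[bi, ]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  map <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  g <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  known <- !is.na(gt) & gt %in% names(map)
  miss <- is.na(gt) | gt %in% c("./.", ".")
  if (any(!known & !miss))
    stop("malformed GT value(s): ",
         paste(utils::head(unique(gt[!known & !miss])), collapse = ", "))
  g[known] <- map[gt[known]]
  fix <- vcfR::getFIX(vcf)
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  meta <- data.frame(locus_id = make.unique(ids),
                     position = as.integer(fix[, "POS"]),
                     stringsAsFactors = FALSE)
  snp_matrix(t(g), sample_ids = colnames(gt), locus_meta = meta)
}

#' Read a quantitative/qualitative trait CSV
#'
#' Expects a header with a group column plus character-code columns from
#' the schema; decimal separator is the dot regardless of locale.
#'
#' @param path path to the CSV file.
#' @param schema a \code{trait_schema} (default: bundled schema).
#' @param group_col name of the group-label column (default
#'   \code{"group"}).
#' @param strict error (rather than drop with a warning) on columns not in
#'   the schema.
#' @return a \code{\link{trait_table}}.
#' @export
read_trait_csv <- function(path, schema = default_trait_schema(),
                           group_col = "group", strict = TRUE) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         dec = ".")
  if (!group_col %in% colnames(raw))
    stop("trait CSV is missing the group column '", group_col, "'")
  groups <- as.character(raw[[group_col]])
  ids <- if ("sample_id" %in% colnames(raw)) raw$sample_id else NULL
  vals <- raw[, setdiff(colnames(raw), c(group_col, "sample_id")),
              drop = FALSE]
  for (cc in intersect(colnames(vals), schema$code)) {
    if (!is.numeric(vals[[cc]]))
      stop("non-numeric value in quantitative column ", cc)
  }
  trait_table(vals, group_labels = groups, schema = schema,
              sample_ids = ids, strict = strict)
}

#' Write an analysis report to JSON or TSV
#'
#' JSON output preserves the report's key order and writes numbers at a
#' fixed precision so that identical reports produce byte-identical files;
#' TSV output requires a data frame.
#'
#' @param report a list (JSON) or data frame (TSV).
#' @param path output path.
#' @param format \code{"json"} or \code{"tsv"}.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 8,
                         pretty = TRUE, na = "null")
  } else {
    if (!is.data.frame(report))
      stop("TSV reports require a data frame")
    num <- vapply(report, is.numeric, logical(1))
    report[num] <- lapply(report[num], function(x) round(x, 8))
    utils::write.table(report, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
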