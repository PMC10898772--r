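# Small programmatic fixtures shared across test files.

# A toy snp_matrix with known structure: 4 samples x 6 loci.
toy_matrix <- function() {
  g <- rbind(
    S1 = c(0, 1, 2, 0, 2, NA),
    S2 = c(0, 1, 2, 1, 2, 1),
    S3 = c(0, 2, 2, 2, 2, 0),
    S4 = c(0, 0, 2, 1, NA, 2))
  meta <- data.frame(
    locus_id = paste0("L", 1:6),
    tag_id = c("t1", "t1", "t2", "t3", "t4", "t4"),
    reproducibility = c(1, 1, 0.99, 1, 1, 0.95),
    stringsAsFactors = FALSE)
  snp_matrix(g, locus_meta = meta,
             group_labels = c("A", "A", "B", "B"))
}

# Fully diagnostic two-population panel (p1 = 1, p2 = 0 at every locus).
diagnostic_panels <- function(n_loci = 50) {
  panel_freqs(rbind(rep(1, n_loci), rep(0, n_loci)), c("P1", "P2"))
}

# Write a small uncompressed VCF with given records to a temp file.
write_toy_vcf <- function(records, samples = c("S1", "S2", "S3")) {
  path <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

# A trait_model planting one character per classification category,
# reps per category, with strong effects.
planted_trait_model <- function(reps = 3) {
  cats <- c("positive_transgressive", "negative_transgressive",
            "intermediate", "parent1_like", "parent2_like", "codominant",
            "not_significant")
  abbr <- c(positive_transgressive = "pt", negative_transgressive = "nt",
            intermediate = "im", parent1_like = "pl1", parent2_like = "pl2",
            codominant = "cd", not_significant = "ns")
  rows <- lapply(cats, function(cat) {
    do.call(rbind, lapply(seq_len(reps), function(i) {
      code <- paste0(abbr[[cat]], i)
      switch(cat,
        positive_transgressive = trait_model(code, 0, 5, sigma = 1, tau = 8),
        negative_transgressive = trait_model(code, 0, 5, sigma = 1, tau = -8),
        intermediate           = trait_model(code, 0, 10, sigma = 1),
        parent1_like           = trait_model(code, 0, 10, sigma = 1, d = 1),
        parent2_like           = trait_model(code, 0, 10, sigma = 1, d = -1),
        codominant             = trait_model(code, 0, 1.2, sigma = 1),
        not_significant        = trait_model(code, 5, 5, sigma = 1))
    }))
  })
  model <- do.call(rbind, rows)
  class(model) <- c("trait_model", "data.frame")
  attr(model, "truth") <- stats::setNames(rep(cats, each = reps),
                                          model$character)
  model
}

# Copy a snp_matrix under a new group label with distinct sample ids.
relabel <- function(m, label) {
  snp_matrix(m$genotypes, sample_ids = paste0(label, "_", m$sample_ids),
             locus_meta = m$locus_meta,
             group_labels = rep(label, length(m$sample_ids)))
}

# Small deterministic seed from a string, for per-case seeding in loops.
derive <- function(name) sum(utf8ToInt(name)) + 7L

# Build a synthetic trait_test object for classifier enumeration tests.
fake_trait_test <- function(p_hp1, p_hp2, p_p12, mh, m1, m2,
                            omnibus_p = 0.001) {
  structure(list(path = "anova_tukey", assumptions = NULL,
                 statistic = 10, p_value = omnibus_p,
                 pairwise_p = c("H-P1" = p_hp1, "H-P2" = p_hp2,
                                "P1-P2" = p_p12),
                 means = c(H = mh, P1 = m1, P2 = m2),
                 se = c(0.1, 0.1, 0.1)),
            class = "trait_test")
}
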