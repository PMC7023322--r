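# in-code fixtures shared across the suite

# genotype matrix from a samples x sites integer matrix
make_gm <- function(calls, chrom = "chr1", pos = NULL, ids = NULL) {
  calls <- as.matrix(calls)
  n_sites <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(n_sites) * 1000L
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(calls)))
  if (length(chrom) == 1L) chrom <- rep(chrom, n_sites)
  genotype_matrix(calls, ids, data.frame(
    chrom = chrom, pos = pos,
    ref = rep("A", n_sites), alt = rep("G", n_sites),
    stringsAsFactors = FALSE))
}

# random genotype matrix with optional missingness
random_gm <- function(n_samples, n_sites, miss = 0, chrom = "chr1",
                      pos = NULL) {
  calls <- matrix(sample(0:2, n_samples * n_sites, replace = TRUE),
                  nrow = n_samples)
  if (miss > 0)
    calls[matrix(runif(length(calls)) < miss, nrow = n_samples)] <- NA
  make_gm(calls, chrom = chrom, pos = pos)
}

# two-group population map over a genotype matrix's samples
make_popmap <- function(gm, n_focal, labels = c("sport", "non_sport")) {
  n <- n_samples(gm)
  structure(
    stats::setNames(c(rep(labels[1], n_focal), rep(labels[2], n - n_focal)),
                    gm$sample_ids),
    class = "population_map")
}

# single window spanning every site of a one-chromosome matrix
whole_grid <- function(gm, window_size = NULL) {
  if (is.null(window_size))
    window_size <- max(gm$sites$pos)
  make_windows(c(chr1 = max(gm$sites$pos)), window_size, window_size)
}

# small VCF text file for parser tests
write_test_vcf <- function(path, records, samples = c("s1", "s2", "s3")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    "##contig=<ID=chrX,length=1000000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}
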