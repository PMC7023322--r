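#' Genotype matrix container
#'
#' The central data structure of the package: a diploid allele-count matrix
#' over biallelic SNPs, with per-site coordinates.  Genotypes are coded as the
#' number of ALT alleles carried (0, 1, 2) with \code{NA} for missing calls.
#' Sites are kept strictly sorted by (chromosome, position), positions are
#' 1-based, and every site is a biallelic SNP (single-nucleotide REF and ALT).
#'
#' @param calls integer matrix, samples in rows and sites in columns, values
#'   in \{0, 1, 2, NA\}.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   row of \code{calls}.
#' @param sites data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} (one row per column of \code{calls}); additional numeric
#'   columns are kept as per-site quality annotations (e.g. \code{QD},
#'   \code{MQ}, \code{FS}, \code{MQRankSum}, \code{GQ_mean}).
#'
#' @return An object of class \code{genotype_matrix}: a list with elements
#'   \code{sample_ids}, \code{sites}, \code{calls}.
#' @export
genotype_matrix <- function(calls, sample_ids, sites) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  sample_ids <- as.character(sample_ids)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)

  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique")
  if (nrow(calls) != length(sample_ids))
    stop("calls must have one row per sample")
  if (ncol(calls) != nrow(sites))
    stop("calls must have one column per site")
  required <- c("chrom", "pos", "ref", "alt")
  if (!all(required %in% names(sites)))
    stop("sites must have columns chrom, pos, ref, alt")

  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (any(sites$pos < 1L))
    stop("site positions must be 1-based (>= 1)")
  nt <- c("A", "C", "G", "T")
  if (!all(sites$ref %in% nt) || !all(sites$alt %in% nt))
    stop("ref and alt must be single nucleotides (A/C/G/T); non-SNP records must be dropped upstream")
  if (any(sites$ref == sites$alt))
    stop("ref and alt must differ at every site")

  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord) || any(ord != seq_along(ord))) {
    sites <- sites[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  if (anyDuplicated(sites[, c("chrom", "pos")]))
    stop("duplicate site coordinates")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")

  rownames(calls) <- sample_ids
  rownames(sites) <- NULL
  structure(
    list(sample_ids = sample_ids, sites = sites, calls = calls),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d biallelic SNPs on %d chromosome(s)\n",
    n_samples(x), n_sites(x), length(unique(x$sites$chrom))
  ))
  miss <- mean(is.na(x$calls))
  cat(sprintf("missing call rate: %.3f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Number of samples / sites in a genotype matrix
#' @param gm a \code{genotype_matrix}
#' @return integer count
#' @export
n_samples <- function(gm) length(gm$sample_ids)

#' @rdname n_samples
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' Subset a genotype matrix by site index or by sample id
#'
#' @param gm a \code{genotype_matrix}
#' @param sites integer or logical index over sites (columns)
#' @param samples character vector of sample ids, or integer/logical index
#' @return a new \code{genotype_matrix}
#' @export
subset_genotypes <- function(gm, sites = NULL, samples = NULL) {
  calls <- gm$calls
  site_df <- gm$sites
  ids <- gm$sample_ids
  if (!is.null(sites)) {
    calls <- calls[, sites, drop = FALSE]
    site_df <- site_df[sites, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) {
      idx <- match(samples, ids)
      if (anyNA(idx)) stop("unknown sample id(s): ",
                           paste(samples[is.na(idx)], collapse = ", "))
    } else idx <- samples
    calls <- calls[idx, , drop = FALSE]
    ids <- ids[idx]
  }
  genotype_matrix(calls, ids, site_df)
}

# calls for one group as a samples x sites matrix
group_calls <- function(gm, group_samples) {
  idx <- match(group_samples, gm$sample_ids)
  if (anyNA(idx))
    stop("samples not present in genotype matrix: ",
         paste(group_samples[is.na(idx)], collapse = ", "))
  gm$calls[idx, , drop = FALSE]
}

# per-site observed allele counts within a sample subset:
# a list with c_obs (observed allele number) and c_alt (ALT allele count)
site_allele_counts <- function(calls) {
  obs <- !is.na(calls)
  c_obs <- 2L * colSums(obs)
  c_alt <- colSums(calls, na.rm = TRUE)
  list(c_obs = c_obs, c_alt = c_alt)
}
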