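#' QC configuration
#'
#' Thresholds defining the "high-quality SNP" set the scan runs on.  Defaults
#' follow common whole-genome resequencing practice: minor allele frequency
#' >= 0.01, Hardy-Weinberg exact p >= 0.001, per-site call rate >= 0.9 (site
#' missingness < 10\%) and per-sample call rate >= 0.9 (individuals with more
#' than 10\% missing genotypes are removed).  When the VCF carries variant
#' quality annotations, GATK-style thresholds are applied per site: mapping
#' quality >= 25, quality-by-depth >= 2, mean genotype quality >= 40, Fisher
#' strand <= 60, mapping-quality rank sum >= -12.5.  Annotation filters are
#' silently skipped (and logged) for annotation columns absent from the data.
#'
#' @param maf_min minimum minor allele frequency, in [0, 0.5]
#' @param hwe_p_min minimum Hardy-Weinberg exact-test p-value
#' @param site_call_rate_min minimum fraction of genotyped samples per site
#' @param sample_call_rate_min minimum fraction of genotyped sites per sample
#' @param annotation_thresholds named list of per-site annotation thresholds;
#'   set to \code{NULL} to disable annotation filtering entirely
#' @return a list of class \code{qc_config}
#' @export
qc_config <- function(maf_min = 0.01,
                      hwe_p_min = 0.001,
                      site_call_rate_min = 0.9,
                      sample_call_rate_min = 0.9,
                      annotation_thresholds = list(
                        mapping_quality_min = 25,
                        quality_by_depth_min = 2,
                        genotype_quality_min = 40,
                        fisher_strand_max = 60,
                        mq_rank_sum_min = -12.5
                      )) {
  stopifnot(maf_min >= 0, maf_min <= 0.5,
            hwe_p_min >= 0, hwe_p_min <= 1,
            site_call_rate_min >= 0, site_call_rate_min <= 1,
            sample_call_rate_min >= 0, sample_call_rate_min <= 1)
  structure(list(
    maf_min = maf_min, hwe_p_min = hwe_p_min,
    site_call_rate_min = site_call_rate_min,
    sample_call_rate_min = sample_call_rate_min,
    annotation_thresholds = annotation_thresholds
  ), class = "qc_config")
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact conditional test of Hardy-Weinberg genotype proportions:
#' conditional on the observed allele counts, the p-value sums the
#' probabilities of all heterozygote counts that are no more probable than
#' the observed one.  This is the standard exact test used for SNP QC; it is
#' preferred over the chi-square approximation at small sample sizes.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts
#' @return p-value in [0, 1]
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1L) stop("at least one genotyped individual required")
  n_a <- 2L * n_hom_ref + n_het   # ref alleles
  n_b <- 2L * n_hom_alt + n_het   # alt alleles
  if (n_a == 0L || n_b == 0L) return(1)  # monomorphic: single configuration
  n_minor <- min(n_a, n_b)
  # possible het counts share the parity of the minor allele count
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  logp <- hwe_het_log_prob(hets, n, n_a)
  logp <- logp - max(logp)
  p_obs <- logp[match(n_het, hets)]
  if (is.na(p_obs)) stop("observed het count impossible given allele counts")
  probs <- exp(logp) / sum(exp(logp))
  min(1, sum(probs[logp <= p_obs + 1e-12]))
}

# log P(het = h | n genotypes, n_a ref alleles), up to a constant
hwe_het_log_prob <- function(h, n, n_a) {
  n_b <- 2L * n - n_a
  h * log(2) + lgamma(n + 1) -
    lgamma((n_a - h) / 2 + 1) - lgamma(h + 1) - lgamma((n_b - h) / 2 + 1)
}

# vectorised over sites via unique genotype-count triples
hwe_exact_p_vec <- function(n_hom_ref, n_het, n_hom_alt) {
  key <- paste(n_hom_ref, n_het, n_hom_alt, sep = ":")
  uk <- !duplicated(key)
  pu <- mapply(hwe_exact_test, n_hom_ref[uk], n_het[uk], n_hom_alt[uk])
  unname(pu[match(key, key[uk])])
}

#' Site-level quality control
#'
#' Filters sites in a fixed order and reports per-filter removal counts:
#' minor allele frequency, then the Hardy-Weinberg exact test, then site
#' call rate, then (when annotation columns exist) the per-site annotation
#' thresholds.  Each filter sees only sites that survived the previous ones,
#' so the removal counts sum with the retained count to the input count.
#'
#' @param gm a \code{\link{genotype_matrix}}
#' @param cfg a \code{\link{qc_config}}
#' @return list with \code{gm} (filtered matrix), \code{removed} (named
#'   integer vector of removal counts in application order) and
#'   \code{skipped_annotations} (annotation filters without data)
#' @export
apply_site_qc <- function(gm, cfg = qc_config()) {
  if (n_sites(gm) == 0L) stop("empty genotype matrix")
  keep <- rep(TRUE, n_sites(gm))
  removed <- c(maf = 0L, hwe = 0L, call_rate = 0L, annotations = 0L)

  cnt <- site_allele_counts(gm$calls)
  maf <- ifelse(cnt$c_obs > 0,
                pmin(cnt$c_alt, cnt$c_obs - cnt$c_alt) / cnt$c_obs, 0)
  fail <- keep & maf < cfg$maf_min
  removed["maf"] <- sum(fail); keep <- keep & !fail

  if (any(keep)) {
    calls <- gm$calls[, keep, drop = FALSE]
    n_hom_ref <- colSums(calls == 0L, na.rm = TRUE)
    n_het <- colSums(calls == 1L, na.rm = TRUE)
    n_hom_alt <- colSums(calls == 2L, na.rm = TRUE)
    p <- hwe_exact_p_vec(n_hom_ref, n_het, n_hom_alt)
    fail_h <- p < cfg$hwe_p_min
    removed["hwe"] <- sum(fail_h)
    keep[keep] <- !fail_h
  }

  call_rate <- colMeans(!is.na(gm$calls))
  fail <- keep & call_rate < cfg$site_call_rate_min
  removed["call_rate"] <- sum(fail); keep <- keep & !fail

  skipped <- character(0)
  ann_map <- list(
    mapping_quality_min = c("MQ", "ge"),
    quality_by_depth_min = c("QD", "ge"),
    genotype_quality_min = c("GQ_mean", "ge"),
    fisher_strand_max = c("FS", "le"),
    mq_rank_sum_min = c("MQRankSum", "ge")
  )
  if (length(cfg$annotation_thresholds)) {
    fail_ann <- rep(FALSE, n_sites(gm))
    for (nm in names(cfg$annotation_thresholds)) {
      spec <- ann_map[[nm]]
      if (is.null(spec)) stop("unknown annotation threshold: ", nm)
      col <- gm$sites[[spec[1]]]
      if (is.null(col)) { skipped <- c(skipped, spec[1]); next }
      thr <- cfg$annotation_thresholds[[nm]]
      bad <- if (spec[2] == "ge") col < thr else col > thr
      fail_ann <- fail_ann | (!is.na(bad) & bad)
    }
    fail <- keep & fail_ann
    removed["annotations"] <- sum(fail); keep <- keep & !fail
  }

  if (!any(keep)) {
    warning("all sites removed by QC")
    out <- gm
    out$sites <- gm$sites[0, , drop = FALSE]
    out$calls <- gm$calls[, 0, drop = FALSE]
  } else {
    out <- subset_genotypes(gm, sites = which(keep))
  }
  list(gm = out, removed = removed, skipped_annotations = unique(skipped))
}

#' Sample-level quality control
#'
#' Removes individuals whose missing-genotype fraction exceeds
#' \code{1 - sample_call_rate_min} (strictly greater than; an individual
#' missing exactly the threshold fraction is retained).  The site set is
#' left unchanged.
#'
#' @param gm a \code{\link{genotype_matrix}}
#' @param cfg a \code{\link{qc_config}}
#' @return list with \code{gm} and \code{removed_samples}
#' @export
apply_sample_qc <- function(gm, cfg = qc_config()) {
  if (n_sites(gm) == 0L) stop("empty genotype matrix")
  miss <- rowMeans(is.na(gm$calls))
  drop <- miss > (1 - cfg$sample_call_rate_min) + 1e-12
  if (all(drop)) stop("sample QC removed every sample")
  out <- if (any(drop)) subset_genotypes(gm, samples = which(!drop)) else gm
  list(gm = out, removed_samples = gm$sample_ids[drop])
}
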