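#' Runs-of-homozygosity detection parameters
#'
#' Parameters of the PLINK-style scanning-window ROH algorithm; defaults are
#' the PLINK \code{--homozyg} defaults commonly used for whole-genome data:
#' 50-SNP windows allowing at most 1 heterozygous and 5 missing calls, runs
#' split at inter-SNP gaps above 1000 kb, average SNP density of at least
#' one SNP per 50 kb, and minimum run size of 100 SNPs and 1000 kb.
#'
#' @param window_snp SNPs per scanning window
#' @param window_het maximum heterozygous calls for a window to count as
#'   homozygous
#' @param window_missing maximum missing calls per window
#' @param gap_kb split a run where adjacent SNPs are further apart than this
#' @param density_kb_per_snp maximum average kb per SNP within a run
#' @param min_snp minimum SNPs per reported run
#' @param min_kb minimum run length in kb
#' @param window_threshold minimum fraction of overlapping windows that are
#'   homozygous for a SNP to be part of a run
#' @return list of class \code{roh_params}
#' @export
roh_params <- function(window_snp = 50L, window_het = 1L,
                       window_missing = 5L, gap_kb = 1000,
                       density_kb_per_snp = 50, min_snp = 100L,
                       min_kb = 1000, window_threshold = 0.05) {
  p <- list(window_snp = as.integer(window_snp),
            window_het = as.integer(window_het),
            window_missing = as.integer(window_missing),
            gap_kb = gap_kb, density_kb_per_snp = density_kb_per_snp,
            min_snp = as.integer(min_snp), min_kb = min_kb,
            window_threshold = window_threshold)
  stopifnot(all(vapply(p, function(v) v >= 0, logical(1))))
  structure(p, class = "roh_params")
}

#' Detect runs of homozygosity
#'
#' The scanning-window algorithm of PLINK \code{--homozyg}: for each sample
#' and chromosome, slide a window of \code{window_snp} SNPs; a window is
#' "homozygous" if it contains at most \code{window_het} heterozygous and at
#' most \code{window_missing} missing calls; each SNP's hit rate is the
#' fraction of windows overlapping it that are homozygous, and SNPs with
#' hit rate >= \code{window_threshold} seed candidate runs.  Maximal
#' stretches of consecutive qualifying SNPs are split wherever adjacent
#' SNPs are more than \code{gap_kb} apart, checked for average density
#' (run length in kb per SNP must not exceed \code{density_kb_per_snp}),
#' and reported when they contain at least \code{min_snp} SNPs and span at
#' least \code{min_kb} kb.  Run coordinates are the first and last SNP
#' positions.  Chromosomes with fewer than \code{window_snp} SNPs yield no
#' calls and are listed in the \code{skipped_chroms} attribute.
#'
#' @param gm a \code{\link{genotype_matrix}}
#' @param params a \code{\link{roh_params}}
#' @return data.frame with columns sample_id, chrom, start_bp, end_bp,
#'   n_snps, length_kb; attribute \code{skipped_chroms}
#' @export
detect_roh <- function(gm, params = roh_params()) {
  chroms <- unique(gm$sites$chrom)
  skipped <- character(0)
  out <- list()
  for (ch in chroms) {
    idx <- which(gm$sites$chrom == ch)
    if (length(idx) < params$window_snp) {
      skipped <- c(skipped, ch)
      next
    }
    pos <- gm$sites$pos[idx]
    for (s in seq_along(gm$sample_ids)) {
      g <- gm$calls[s, idx]
      segs <- roh_scan_sample(g, pos, params)
      if (nrow(segs)) {
        segs$sample_id <- gm$sample_ids[s]
        segs$chrom <- ch
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  res <- if (length(out)) {
    do.call(rbind, out)[, c("sample_id", "chrom", "start_bp", "end_bp",
                            "n_snps", "length_kb")]
  } else {
    data.frame(sample_id = character(0), chrom = character(0),
               start_bp = integer(0), end_bp = integer(0),
               n_snps = integer(0), length_kb = numeric(0),
               stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  attr(res, "skipped_chroms") <- skipped
  res
}

# one sample, one chromosome; g: dosage vector, pos: sorted positions
roh_scan_sample <- function(g, pos, params) {
  m <- length(g)
  w <- params$window_snp
  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  ch <- c(0L, cumsum(het))
  cm <- c(0L, cumsum(mis))
  nwin <- m - w + 1L
  starts <- seq_len(nwin)
  hom_win <- (ch[starts + w] - ch[starts]) <= params$window_het &
    (cm[starts + w] - cm[starts]) <= params$window_missing
  chw <- c(0L, cumsum(as.integer(hom_win)))

  i <- seq_len(m)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, nwin)
  rate <- (chw[hi + 1L] - chw[lo]) / (hi - lo + 1L)
  eligible <- rate >= params$window_threshold

  empty <- data.frame(start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), length_kb = numeric(0))
  if (!any(eligible)) return(empty)

  r <- rle(eligible)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    span <- run_start[k]:run_end[k]
    # split at large physical gaps between adjacent SNPs
    gaps <- which(diff(pos[span]) > params$gap_kb * 1000)
    cut <- c(0L, gaps, length(span))
    for (j in seq_len(length(cut) - 1L)) {
      sub <- span[(cut[j] + 1L):cut[j + 1L]]
      n <- length(sub)
      len_kb <- (pos[sub[n]] - pos[sub[1]] + 1L) / 1000
      if (n >= params$min_snp && len_kb >= params$min_kb &&
          len_kb / n <= params$density_kb_per_snp) {
        segs[[length(segs) + 1L]] <- data.frame(
          start_bp = pos[sub[1]], end_bp = pos[sub[n]],
          n_snps = n, length_kb = len_kb)
      }
    }
  }
  if (!length(segs)) return(empty)
  do.call(rbind, segs)
}

#' Summarise runs of homozygosity by group
#'
#' Per-group totals, the percentage of runs falling in 0.5-Mb length bins
#' (1-1.5 Mb, 1.5-2 Mb, ...), each chromosome's share of the group's runs,
#' and the longest run per group.
#'
#' @param segments output of \code{\link{detect_roh}}
#' @param pm a \code{population_map} assigning the segments' samples
#' @return list with \code{counts} (named integer vector per group),
#'   \code{length_bins}, \code{by_chrom} and \code{longest} data.frames
#' @export
summarize_roh <- function(segments, pm) {
  if (!nrow(segments)) {
    return(list(
      counts = integer(0),
      length_bins = data.frame(group = character(0), bin = character(0),
                               n = integer(0), pct = numeric(0)),
      by_chrom = data.frame(group = character(0), chrom = character(0),
                            n = integer(0), pct = numeric(0)),
      longest = data.frame(group = character(0), sample_id = character(0),
                           chrom = character(0), start_bp = integer(0),
                           end_bp = integer(0), length_kb = numeric(0))
    ))
  }
  group <- unname(unclass(pm))[match(segments$sample_id, names(pm))]
  if (anyNA(group))
    stop("segments contain samples absent from the population map")
  counts <- table(group)

  mb <- segments$length_kb / 1000
  top <- max(2, ceiling(max(mb) * 2) / 2)
  breaks <- seq(1, top, by = 0.5)
  if (max(mb) >= top) breaks <- c(breaks, max(mb) + 0.5)
  bin <- cut(mb, breaks, right = FALSE,
             labels = sprintf("%.1f-%.1f", utils::head(breaks, -1),
                              utils::tail(breaks, -1)))
  bt <- as.data.frame(table(group = group, bin = bin),
                      stringsAsFactors = FALSE)
  bt$pct <- 100 * bt$Freq / as.integer(counts[bt$group])
  length_bins <- data.frame(group = bt$group, bin = bt$bin, n = bt$Freq,
                            pct = bt$pct, stringsAsFactors = FALSE)

  ct <- as.data.frame(table(group = group, chrom = segments$chrom),
                      stringsAsFactors = FALSE)
  ct$pct <- 100 * ct$Freq / as.integer(counts[ct$group])
  by_chrom <- data.frame(group = ct$group, chrom = ct$chrom, n = ct$Freq,
                         pct = ct$pct, stringsAsFactors = FALSE)

  longest <- do.call(rbind, lapply(split(segments, group), function(s) {
    s[which.max(s$length_kb), , drop = FALSE]
  }))
  longest <- data.frame(group = rownames(longest),
                        longest[, c("sample_id", "chrom", "start_bp",
                                    "end_bp", "length_kb")],
                        stringsAsFactors = FALSE)
  rownames(longest) <- NULL

  list(counts = stats::setNames(as.integer(counts), names(counts)),
       length_bins = length_bins, by_chrom = by_chrom, longest = longest)
}
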