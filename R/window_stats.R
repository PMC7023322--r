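#' Build a sliding-window grid
#'
#' Windows are defined by genomic coordinates (not SNP indices): on each
#' chromosome they start at 1, 1 + step, 1 + 2*step, ... for every start not
#' exceeding the chromosome's maximum position, and each spans
#' \code{window_size_bp} bases (the last windows may extend past the end of
#' the chromosome; their SNP content simply ends there).  The defaults give
#' the classic 100-kb windows sliding by 50 kb.
#'
#' @param chrom_extents named numeric vector: chromosome -> maximum position
#'   (e.g. position of the last SNP, or chromosome length)
#' @param window_size_bp window span in bp
#' @param step_bp distance between consecutive window starts in bp
#' @return data.frame of class \code{window_grid} with columns chrom, start,
#'   end (1-based inclusive) and attributes \code{window_size_bp},
#'   \code{step_bp}
#' @export
make_windows <- function(chrom_extents, window_size_bp = 100000L,
                         step_bp = 50000L) {
  if (!length(chrom_extents)) stop("empty chromosome extents")
  if (is.null(names(chrom_extents)) || any(!nzchar(names(chrom_extents))))
    stop("chrom_extents must be a named vector")
  window_size_bp <- as.integer(window_size_bp)
  step_bp <- as.integer(step_bp)
  stopifnot(step_bp >= 1L, window_size_bp >= step_bp)
  chroms <- names(chrom_extents)
  pieces <- lapply(chroms, function(ch) {
    maxpos <- chrom_extents[[ch]]
    if (maxpos < 1) stop("chromosome extent must be >= 1: ", ch)
    starts <- seq.int(1L, as.integer(maxpos), by = step_bp)
    data.frame(chrom = ch, start = starts,
               end = starts + window_size_bp - 1L,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  attr(grid, "window_size_bp") <- window_size_bp
  attr(grid, "step_bp") <- step_bp
  class(grid) <- c("window_grid", "data.frame")
  grid
}

# site -> window membership as a Hits-like data.frame (window, site index)
window_site_hits <- function(grid, sites) {
  win_gr <- GenomicRanges::GRanges(
    grid$chrom, IRanges::IRanges(grid$start, grid$end))
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  hits <- GenomicRanges::findOverlaps(site_gr, win_gr)
  data.frame(win = S4Vectors::subjectHits(hits),
             site = S4Vectors::queryHits(hits))
}

# per-site mean pairwise difference (expected heterozygosity among observed
# alleles): 2 * c_alt * c_ref / (c * (c - 1)); 0 when fewer than 2 alleles
site_pairwise_diversity <- function(calls) {
  cnt <- site_allele_counts(calls)
  c_obs <- cnt$c_obs
  c_alt <- cnt$c_alt
  d <- numeric(length(c_obs))
  ok <- c_obs >= 2L
  d[ok] <- 2 * c_alt[ok] * (c_obs[ok] - c_alt[ok]) /
    (c_obs[ok] * (c_obs[ok] - 1))
  d
}

#' Windowed nucleotide diversity
#'
#' Pairwise nucleotide diversity per window and per bp for one group of
#' samples: each site contributes its mean pairwise difference among the
#' group's observed alleles, the window value is the sum of site
#' contributions divided by the full window span in bp (the convention of
#' windowed-diversity tools, so windows with no SNPs are 0, not undefined).
#'
#' @param gm a \code{\link{genotype_matrix}}
#' @param group_samples character vector of sample ids in the group
#' @param grid a \code{\link{make_windows}} grid
#' @return numeric vector of per-bp diversity, one value per grid window
#' @export
windowed_pi <- function(gm, group_samples, grid) {
  if (!length(group_samples)) stop("group must be non-empty")
  calls <- group_calls(gm, group_samples)
  d <- site_pairwise_diversity(calls)
  hits <- window_site_hits(grid, gm$sites)
  acc <- numeric(nrow(grid))
  if (nrow(hits)) {
    s <- rowsum(d[hits$site], hits$win)
    acc[as.integer(rownames(s))] <- s[, 1]
  }
  acc / attr(grid, "window_size_bp")
}

#' Tajima's D normalising constants
#'
#' The harmonic-number and variance constants of Tajima's neutrality test
#' for a sample of \code{n} haplotypes: a1, a2, b1, b2, c1, c2, e1, e2.
#'
#' @param n number of haplotypes (>= 4 for a usable variance)
#' @return named list of constants
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Windowed Tajima's D
#'
#' For each window, computes Tajima's D within one group:
#' \code{D = (Pi - S/a1) / sqrt(e1*S + e2*S*(S-1))}, where S is the number
#' of segregating sites among the group's observed alleles, Pi the window's
#' mean pairwise difference count (sum of per-site mean pairwise
#' differences, not per bp), and the constants are those of
#' \code{\link{tajima_constants}} evaluated at the group's full haplotype
#' count n = 2 x (number of diploids).  Windows with S = 0 are undefined
#' (\code{NA}), as is everything when n < 4.  With missing data, per-site
#' contributions use the observed alleles while the constants keep the full
#' n; the approximation is bounded by the upstream missingness QC.
#'
#' @inheritParams windowed_pi
#' @return data.frame with one row per window: \code{d}, \code{s}
#'   (segregating sites), \code{pi} (mean pairwise difference count)
#' @export
tajima_d <- function(gm, group_samples, grid) {
  if (length(group_samples) < 2L)
    stop("Tajima's D needs at least 2 diploids")
  n <- 2L * length(group_samples)
  calls <- group_calls(gm, group_samples)
  cnt <- site_allele_counts(calls)
  seg <- as.integer(cnt$c_obs >= 2L & cnt$c_alt > 0L &
                      cnt$c_alt < cnt$c_obs)
  d_site <- site_pairwise_diversity(calls)

  hits <- window_site_hits(grid, gm$sites)
  s_win <- integer(nrow(grid))
  pi_win <- numeric(nrow(grid))
  if (nrow(hits)) {
    s_acc <- rowsum(seg[hits$site], hits$win)
    s_win[as.integer(rownames(s_acc))] <- s_acc[, 1]
    p_acc <- rowsum(d_site[hits$site], hits$win)
    pi_win[as.integer(rownames(p_acc))] <- p_acc[, 1]
  }

  d <- rep(NA_real_, nrow(grid))
  if (n >= 4L) {
    k <- tajima_constants(n)
    ok <- s_win > 0L
    d[ok] <- (pi_win[ok] - s_win[ok] / k$a1) /
      sqrt(k$e1 * s_win[ok] + k$e2 * s_win[ok] * (s_win[ok] - 1))
  }
  data.frame(d = d, s = s_win, pi = pi_win)
}

# per-site Weir-Cockerham variance components for two populations.
# calls1/calls2: samples x sites matrices.  Returns a, b, c vectors with NA
# at unusable sites (monomorphic across both groups, or insufficient data).
wc_site_components <- function(calls1, calls2) {
  n1 <- colSums(!is.na(calls1))
  n2 <- colSums(!is.na(calls2))
  p1 <- ifelse(n1 > 0, colSums(calls1, na.rm = TRUE) / (2 * n1), NA)
  p2 <- ifelse(n2 > 0, colSums(calls2, na.rm = TRUE) / (2 * n2), NA)
  h1 <- ifelse(n1 > 0, colSums(calls1 == 1L, na.rm = TRUE) / n1, NA)
  h2 <- ifelse(n2 > 0, colSums(calls2 == 1L, na.rm = TRUE) / n2, NA)

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2))  # /(r-1) with r = 2
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)

  usable <- n1 >= 1 & n2 >= 1 & nbar > 1 & nc > 0 &
    !is.na(pbar) & pbar > 0 & pbar < 1
  a <- b <- cc <- rep(NA_real_, length(n1))
  i <- which(usable)
  if (length(i)) {
    pq <- pbar[i] * (1 - pbar[i])
    inner <- pq - (r - 1) / r * s2[i] - hbar[i] / 4
    a[i] <- (nbar[i] / nc[i]) * (s2[i] - inner / (nbar[i] - 1))
    b[i] <- (nbar[i] / (nbar[i] - 1)) *
      (pq - (r - 1) / r * s2[i] - (2 * nbar[i] - 1) / (4 * nbar[i]) * hbar[i])
    cc[i] <- hbar[i] / 2
  }
  list(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham fixation index
#'
#' Per-site variance components a (among populations), b (among individuals
#' within populations) and c (within individuals) are computed for the two
#' groups from their sample sizes, ALT allele frequencies and observed
#' heterozygosities, then aggregated per window as the ratio of sums
#' \code{sum(a) / sum(a + b + c)} (the "weighted" estimator).  Sites
#' monomorphic across both groups contribute nothing; windows with no usable
#' sites are \code{NA}.  Negative estimates are not clamped.
#'
#' @param gm a \code{\link{genotype_matrix}}
#' @param pm a two-group \code{population_map}
#' @param grid a \code{\link{make_windows}} grid
#' @return numeric vector of per-window weighted F_st estimates
#' @export
windowed_wc_fst <- function(gm, pm, grid) {
  unassigned <- setdiff(gm$sample_ids, names(pm))
  if (length(unassigned))
    stop("samples missing from population map: ",
         paste(unassigned, collapse = ", "))
  grp <- pop_groups(pm[names(pm) %in% gm$sample_ids])
  if (length(grp) != 2L) stop("exactly two population groups required")
  if (any(lengths(grp) < 2L)) stop("each group needs at least 2 diploids")
  comp <- wc_site_components(group_calls(gm, grp[[1]]),
                             group_calls(gm, grp[[2]]))
  hits <- window_site_hits(grid, gm$sites)
  num <- den <- numeric(nrow(grid))
  if (nrow(hits)) {
    a <- comp$a[hits$site]
    tot <- a + comp$b[hits$site] + comp$c[hits$site]
    ok <- !is.na(tot)
    s_num <- rowsum(a[ok], hits$win[ok])
    s_den <- rowsum(tot[ok], hits$win[ok])
    num[as.integer(rownames(s_num))] <- s_num[, 1]
    den[as.integer(rownames(s_den))] <- s_den[, 1]
  }
  ifelse(den != 0, num / den, NA_real_)
}

#' Z-transformation
#'
#' Standardises the defined (non-\code{NA}, finite) values to zero mean and
#' unit sample standard deviation; undefined entries stay undefined.
#'
#' @param values numeric vector, possibly with \code{NA}
#' @return numeric vector of the same length
#' @export
z_transform <- function(values) {
  def <- which(is.finite(values))
  if (length(def) < 2L) stop("z_transform needs at least 2 defined values")
  m <- mean(values[def])
  s <- stats::sd(values[def])
  if (s == 0) stop("z_transform undefined for zero-variance input")
  out <- rep(NA_real_, length(values))
  out[def] <- (values[def] - m) / s
  nonfin <- which(!is.na(values) & !is.finite(values))
  out[nonfin] <- values[nonfin]
  out
}

#' Log2 nucleotide-diversity ratio
#'
#' \code{log2(pi_background / pi_focal)} per window: large positive values
#' flag windows where the focal (candidate-selection) group has lost
#' diversity relative to the background group.  A window with zero focal
#' diversity but positive background diversity maps to \code{+Inf} (it ranks
#' above any finite threshold); windows with zero diversity in both groups
#' are undefined and excluded from ranking.
#'
#' @param pi_background per-window diversity of the background group
#' @param pi_focal per-window diversity of the focal group
#' @return numeric vector (may contain \code{Inf}, \code{-Inf}, \code{NA})
#' @export
log2_pi_ratio <- function(pi_background, pi_focal) {
  if (length(pi_background) != length(pi_focal))
    stop("window lists must be aligned")
  out <- rep(NA_real_, length(pi_focal))
  both <- !is.na(pi_background) & !is.na(pi_focal)
  pos <- both & (pi_background > 0 | pi_focal > 0)
  out[pos] <- log2(pi_background[pos] / pi_focal[pos])
  out
}

#' Full per-window statistics table
#'
#' Runs every windowed statistic of the scan over one grid and assembles the
#' per-window table: SNP counts, per-group diversity, weighted
#' Weir-Cockerham F_st and its Z-transform, the log2 diversity ratio
#' (background over focal) and Tajima's D within the focal group.
#'
#' @param gm a post-QC \code{\link{genotype_matrix}}
#' @param pm a two-group \code{population_map} covering the samples
#' @param grid a \code{\link{make_windows}} grid
#' @param focal_group label of the group scanned for sweeps (diversity loss,
#'   negative Tajima's D); the other group is the background
#' @return data.frame with columns chrom, start, end, n_snps, pi_focal,
#'   pi_background, fst, z_fst, log2_ratio, tajima_d_focal, s_focal
#' @export
compute_window_stats <- function(gm, pm, grid, focal_group) {
  groups <- two_groups(pm)
  if (!focal_group %in% groups)
    stop("focal_group '", focal_group, "' not in population map")
  background_group <- setdiff(groups, focal_group)
  grp <- pop_groups(pm[names(pm) %in% gm$sample_ids])

  hits <- window_site_hits(grid, gm$sites)
  n_snps <- integer(nrow(grid))
  tab <- table(hits$win)
  n_snps[as.integer(names(tab))] <- as.integer(tab)

  pi_f <- windowed_pi(gm, grp[[focal_group]], grid)
  pi_b <- windowed_pi(gm, grp[[background_group]], grid)
  fst <- windowed_wc_fst(gm, pm, grid)
  taj <- tajima_d(gm, grp[[focal_group]], grid)

  out <- data.frame(
    chrom = grid$chrom, start = grid$start, end = grid$end,
    n_snps = n_snps,
    pi_focal = pi_f, pi_background = pi_b,
    fst = fst,
    z_fst = NA_real_,
    log2_ratio = log2_pi_ratio(pi_b, pi_f),
    tajima_d_focal = taj$d, s_focal = taj$s,
    stringsAsFactors = FALSE
  )
  out$z_fst <- z_transform(out$fst)
  attr(out, "focal_group") <- focal_group
  attr(out, "background_group") <- background_group
  out
}
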