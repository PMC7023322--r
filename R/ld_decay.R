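#' Linkage-disequilibrium decay curve
#'
#' Composite LD from unphased data: for every same-chromosome SNP pair
#' separated by at most \code{max_dist_bp}, r^2 is the squared sample
#' correlation of the two diploid dosage vectors over pairwise-complete
#' samples.  Pairs where either site is monomorphic among the group's
#' complete observations are skipped.  Pair r^2 values are averaged within
#' contiguous distance bins of width \code{bin_bp}.
#'
#' When a chromosome holds more than \code{max_pairs_per_chrom} eligible
#' pairs, a seeded uniform subsample of pairs is used so that dense inputs
#' stay tractable; the curve is otherwise deterministic.
#'
#' @param gm a \code{\link{genotype_matrix}}
#' @param group_samples character vector of >= 3 sample ids
#' @param max_dist_bp maximum pair separation in bp (default 300 kb)
#' @param bin_bp distance-bin width in bp (default 10 kb)
#' @param max_pairs_per_chrom cap on evaluated pairs per chromosome
#' @param seed seed for the pair subsample (only used above the cap)
#' @return data.frame: bin_start, bin_end, distance_bin_bp (midpoint),
#'   mean_r2, n_pairs; bins without pairs are omitted.  Empty (with a
#'   warning) when no eligible pairs exist.
#' @export
ld_decay_curve <- function(gm, group_samples, max_dist_bp = 300000L,
                           bin_bp = 10000L, max_pairs_per_chrom = 1e6,
                           seed = 1L) {
  if (length(group_samples) < 3L) stop("LD needs at least 3 samples")
  calls <- group_calls(gm, group_samples)
  storage.mode(calls) <- "double"
  dist_all <- numeric(0)
  r2_all <- numeric(0)
  for (ch in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == ch)
    if (length(idx) < 2L) next
    pos <- gm$sites$pos[idx]
    pairs <- eligible_pairs(pos, max_dist_bp)
    if (!nrow(pairs)) next
    if (nrow(pairs) > max_pairs_per_chrom) {
      old <- .Random.seed_save()
      set.seed(seed)
      pairs <- pairs[sample.int(nrow(pairs), max_pairs_per_chrom), ,
                     drop = FALSE]
      .Random.seed_restore(old)
    }
    r2 <- pair_r2(calls[, idx, drop = FALSE], pairs)
    keep <- !is.na(r2)
    dist_all <- c(dist_all, (pos[pairs[, 2]] - pos[pairs[, 1]])[keep])
    r2_all <- c(r2_all, r2[keep])
  }
  if (!length(r2_all)) {
    warning("no eligible SNP pairs for LD computation")
    return(data.frame(bin_start = integer(0), bin_end = integer(0),
                      distance_bin_bp = integer(0), mean_r2 = numeric(0),
                      n_pairs = integer(0)))
  }
  bin <- pmin(floor((dist_all - 1) / bin_bp), max_dist_bp %/% bin_bp - 1L)
  agg_n <- tapply(r2_all, bin, length)
  agg_m <- tapply(r2_all, bin, mean)
  b <- as.integer(names(agg_n))
  data.frame(
    bin_start = b * bin_bp + 1L,
    bin_end = (b + 1L) * bin_bp,
    distance_bin_bp = as.integer(b * bin_bp + bin_bp / 2),
    mean_r2 = as.numeric(agg_m),
    n_pairs = as.integer(agg_n),
    row.names = NULL
  )
}

# index pairs (i, j), i < j, with pos[j] - pos[i] <= max_dist
eligible_pairs <- function(pos, max_dist) {
  n <- length(pos)
  hi <- findInterval(pos + max_dist, pos)
  cnt <- hi - seq_len(n)
  i <- rep.int(seq_len(n), pmax(cnt, 0L))
  j <- unlist(lapply(which(cnt > 0L), function(k) (k + 1L):hi[k]),
              use.names = FALSE)
  if (!length(i))
    return(matrix(integer(0), ncol = 2))
  cbind(i, j)
}

# squared pairwise-complete correlation for given column pairs, chunked
pair_r2 <- function(calls, pairs, chunk = 100000L) {
  out <- numeric(nrow(pairs))
  for (off in seq(1L, nrow(pairs), by = chunk)) {
    rows <- off:min(off + chunk - 1L, nrow(pairs))
    A <- calls[, pairs[rows, 1], drop = FALSE]
    B <- calls[, pairs[rows, 2], drop = FALSE]
    ok <- !is.na(A) & !is.na(B)
    A[!ok] <- NA; B[!ok] <- NA
    n <- colSums(ok)
    sa <- colSums(A, na.rm = TRUE); sb <- colSums(B, na.rm = TRUE)
    saa <- colSums(A * A, na.rm = TRUE); sbb <- colSums(B * B, na.rm = TRUE)
    sab <- colSums(A * B, na.rm = TRUE)
    va <- saa - sa^2 / n
    vb <- sbb - sb^2 / n
    cov <- sab - sa * sb / n
    r2 <- ifelse(n >= 3 & va > 1e-12 & vb > 1e-12,
                 cov^2 / (va * vb), NA_real_)
    out[rows] <- r2
  }
  out
}

# save/restore the global RNG state around an internally seeded step
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
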