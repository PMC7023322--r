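#' Top-percentile selection of windows
#'
#' Selects the windows in the upper tail of a statistic.  The threshold is
#' the empirical (1 - q) quantile (linear-interpolation convention, R type 7)
#' of the defined (finite) values; every window with value >= threshold is
#' selected, so ties at the threshold are all included and the set may
#' slightly exceed q * N.  \code{+Inf} values are always selected and never
#' enter the quantile computation.  With \code{fixed_count = TRUE} the
#' threshold is instead the \code{ceiling(q * N)}-th largest defined value.
#'
#' @param values numeric vector of per-window statistics (\code{NA}
#'   undefined)
#' @param q upper-tail fraction, in (0, 1); default 0.01 (top 1 percent)
#' @param fixed_count select a fixed count of windows rather than cutting at
#'   a quantile
#' @return list with \code{selected} (integer indices into \code{values})
#'   and \code{threshold}
#' @export
top_percentile <- function(values, q = 0.01, fixed_count = FALSE) {
  stopifnot(q > 0, q < 1)
  def <- which(is.finite(values))
  if (length(def) < 2L) stop("need at least 2 defined values")
  x <- values[def]
  if (fixed_count) {
    n_top <- max(1L, ceiling(q * length(x)))
    threshold <- sort(x, decreasing = TRUE)[n_top]
  } else {
    threshold <- stats::quantile(x, probs = 1 - q, names = FALSE, type = 7)
  }
  selected <- which((!is.na(values) & values >= threshold) |
                      (!is.na(values) & values == Inf))
  list(selected = selected, threshold = threshold)
}

#' Candidate selective-sweep windows
#'
#' The scan's decision rule: take the top fraction \code{q} of windows by
#' Z(F_st) and, independently, by the log2 diversity ratio; intersect the
#' two sets by exact window identity (both statistics live on the same
#' grid); then validate with Tajima's D in the focal group, keeping only
#' shared windows with D <= 0 (windows with undefined D are excluded).
#'
#' @param ws per-window statistics from \code{\link{compute_window_stats}}
#' @param q upper-tail fraction for both statistics (default 0.01)
#' @param absolute rank windows by |Z(F_st)| instead of signed Z(F_st);
#'   the default keeps the signed, high-differentiation tail
#' @param fixed_count passed to \code{\link{top_percentile}}
#' @return list of class \code{candidate_set}: \code{stats} (the input
#'   table), integer index vectors \code{top_fst}, \code{top_ratio},
#'   \code{shared}, \code{final}, and \code{thresholds} (named list with
#'   \code{z_fst_cut}, \code{ratio_cut})
#' @export
candidate_windows <- function(ws, q = 0.01, absolute = FALSE,
                              fixed_count = FALSE) {
  fst_values <- if (absolute) abs(ws$z_fst) else ws$z_fst
  sel_fst <- top_percentile(fst_values, q, fixed_count)
  sel_ratio <- top_percentile(ws$log2_ratio, q, fixed_count)
  shared <- intersect(sel_fst$selected, sel_ratio$selected)
  d <- ws$tajima_d_focal[shared]
  final <- shared[!is.na(d) & d <= 0]
  out <- list(
    stats = ws,
    top_fst = sel_fst$selected,
    top_ratio = sel_ratio$selected,
    shared = sort(shared),
    final = sort(final),
    thresholds = list(z_fst_cut = sel_fst$threshold,
                      ratio_cut = sel_ratio$threshold)
  )
  class(out) <- "candidate_set"
  stopifnot(all(out$final %in% out$shared),
            all(out$shared %in% out$top_fst),
            all(out$shared %in% out$top_ratio))
  out
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf(
    paste0("candidate_set: |top_fst| = %d, |top_ratio| = %d, ",
           "|shared| = %d, |final| = %d\n"),
    length(x$top_fst), length(x$top_ratio), length(x$shared),
    length(x$final)))
  cat(sprintf("thresholds: Z(F_st) >= %.4g, log2 ratio >= %.4g\n",
              x$thresholds$z_fst_cut, x$thresholds$ratio_cut))
  invisible(x)
}

# "chrom:start-end" keys for window tables
window_keys <- function(windows) {
  paste0(windows$chrom, ":", windows$start, "-", windows$end)
}

#' Assign genes to candidate windows
#'
#' A gene is assigned to a window iff their 1-based inclusive intervals
#' overlap by at least 1 bp.  Gene lists are deduplicated per window; the
#' number of distinct genes across all windows is attached as attribute
#' \code{n_distinct_genes}.
#'
#' @param windows data.frame with columns chrom, start, end
#' @param ann gene annotation from \code{\link{read_gene_annotation}}
#' @return named list (window key -> character vector of gene ids) with
#'   attribute \code{n_distinct_genes}
#' @export
annotate_genes <- function(windows, ann) {
  keys <- window_keys(windows)
  genes <- stats::setNames(rep(list(character(0)), nrow(windows)), keys)
  if (nrow(windows) && nrow(ann)) {
    win_gr <- GenomicRanges::GRanges(
      windows$chrom, IRanges::IRanges(windows$start, windows$end))
    gene_gr <- GenomicRanges::GRanges(
      ann$chrom, IRanges::IRanges(ann$start, ann$end))
    hits <- GenomicRanges::findOverlaps(win_gr, gene_gr)
    for (w in unique(S4Vectors::queryHits(hits))) {
      g <- ann$gene_id[S4Vectors::subjectHits(hits)[
        S4Vectors::queryHits(hits) == w]]
      genes[[w]] <- unique(g)
    }
  }
  attr(genes, "n_distinct_genes") <- length(unique(unlist(genes)))
  genes
}

#' Intersect two interval sets
#'
#' Maximal intersection intervals between two sets of 1-based inclusive
#' genomic intervals (e.g. selective-signal regions vs runs of
#' homozygosity).  An empty result is valid and simply means no overlap.
#'
#' @param a,b data.frames with columns chrom, start, end
#' @return data.frame with columns chrom, start, end (possibly 0 rows)
#' @export
overlap_regions <- function(a, b) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (!nrow(a) || !nrow(b)) return(empty)
  gr_a <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start, a$end))
  gr_b <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start, b$end))
  ov <- suppressWarnings(GenomicRanges::intersect(gr_a, gr_b,
                                                  ignore.strand = TRUE))
  if (!length(ov)) return(empty)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ov)),
    start = BiocGenerics::start(ov),
    end = BiocGenerics::end(ov),
    stringsAsFactors = FALSE
  )
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Gene-set over-representation test
#'
#' One-sided Fisher exact test per gene set for over-representation of the
#' candidate genes against a background universe, with Benjamini-Hochberg
#' FDR across tested terms.  Gene sets are intersected with the background
#' before testing; terms with zero candidate overlap get p = 1.
#'
#' @param candidate_genes character vector, must be a subset of
#'   \code{background_genes}
#' @param background_genes character vector, the gene universe
#' @param gene_sets named list (term -> character vector of genes), e.g.
#'   from \code{\link{read_gmt}}
#' @return data.frame: term, n_set, n_overlap, overlap_genes
#'   (comma-separated), p, fdr; sorted by p
#' @export
enrichment_test <- function(candidate_genes, background_genes, gene_sets) {
  candidate_genes <- unique(candidate_genes)
  background_genes <- unique(background_genes)
  if (!length(candidate_genes)) stop("empty candidate gene set")
  extra <- setdiff(candidate_genes, background_genes)
  if (length(extra))
    stop("candidate genes missing from background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  n_bg <- length(background_genes)
  n_cand <- length(candidate_genes)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(unique(gene_sets[[term]]), background_genes)
    hit <- intersect(candidate_genes, set)
    k <- length(hit)
    tab <- matrix(c(k, length(set) - k,
                    n_cand - k, n_bg - length(set) - n_cand + k),
                  nrow = 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(term = term, n_set = length(set), n_overlap = k,
               overlap_genes = paste(sort(hit), collapse = ","),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$term), , drop = FALSE]
}

#' Read gene sets in GMT format
#'
#' Tab-delimited: term, description, then one gene per field.
#'
#' @param path GMT file
#' @return named list of character vectors
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("GMT lines need term, description and at least one gene")
  stats::setNames(
    lapply(fields, function(f) unique(f[-(1:2)])),
    vapply(fields, `[`, character(1), 1L)
  )
}
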