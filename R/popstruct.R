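#' Identity-by-state (allele-sharing) distance matrix
#'
#' Pairwise genetic distance between samples from genotype dosages:
#' \code{d(i, j)} is the mean over sites called in both samples of
#' \code{|dosage_i - dosage_j| / 2}, i.e. an allele-sharing distance in
#' [0, 1] (0 for identical genotypes, 1 for opposite homozygotes at every
#' co-called site).
#'
#' @param gm a \code{\link{genotype_matrix}} with >= 3 samples
#' @return a symmetric \code{dist}-compatible matrix with zero diagonal,
#'   labelled by sample id
#' @export
ibs_distance <- function(gm) {
  n <- n_samples(gm)
  if (n < 3L) stop("distance matrix needs at least 3 samples")
  calls <- gm$calls
  storage.mode(calls) <- "double"
  d <- matrix(0, n, n, dimnames = list(gm$sample_ids, gm$sample_ids))
  for (i in seq_len(n - 1L)) {
    gi <- calls[i, ]
    for (j in (i + 1L):n) {
      gj <- calls[j, ]
      ok <- !is.na(gi) & !is.na(gj)
      m <- sum(ok)
      if (m == 0L)
        stop("samples ", gm$sample_ids[i], " and ", gm$sample_ids[j],
             " share no called sites")
      d[i, j] <- d[j, i] <- sum(abs(gi[ok] - gj[ok])) / (2 * m)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Builds the unrooted neighbor-joining tree (Saitou-Nei agglomeration on
#' the Q-criterion) from a distance matrix.  For tree-additive distances NJ
#' reconstructs the generating tree exactly, which is the main correctness
#' property used in this package's tests.  Negative branch lengths, which
#' NJ can produce on noisy non-additive input, are clamped to zero with a
#' warning and flagged via \code{attr(, "clamped_edges")}.
#'
#' @param dm symmetric distance matrix with >= 3 labelled rows
#' @return an \code{ape} \code{phylo} tree with tip labels and branch
#'   lengths
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(dm))) stop("distances must be finite")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix must be symmetric")
  if (is.null(rownames(dm))) stop("distance matrix must be labelled")
  tree <- ape::nj(stats::as.dist(dm))
  n_neg <- sum(tree$edge.length < 0)
  if (n_neg > 0) {
    warning(n_neg, " negative NJ branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  attr(tree, "clamped_edges") <- n_neg
  tree
}

#' Distance matrix as square TSV
#' @param dm labelled square matrix
#' @param path output path
#' @return invisibly, the path
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(sample_id = rownames(dm), as.data.frame(dm),
                   check.names = FALSE)
  write_tsv(df, path)
}
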