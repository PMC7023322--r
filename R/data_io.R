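#' Read a multi-sample VCF into a genotype matrix
#'
#' Ingests a VCF 4.x file (plain or bgzipped) and returns the biallelic-SNP
#' genotype matrix the scan operates on.  Multiallelic records, indels and
#' records on chromosomes outside \code{region_filter} are dropped, with
#' counts reported via \code{attr(, "dropped")}.  Genotype codes count ALT
#' alleles from the GT field; phase separators are ignored and half-calls
#' (e.g. \code{./1}) are treated as missing.
#'
#' Per-site quality annotations are carried along when present: the INFO
#' fields \code{QD}, \code{MQ}, \code{FS}, \code{MQRankSum} and the per-site
#' mean of the FORMAT \code{GQ} field (column \code{GQ_mean}).
#'
#' @param path path to a VCF file (".vcf" or ".vcf.gz")
#' @param region_filter optional character vector of chromosome names to
#'   keep (e.g. autosomes); \code{NULL} keeps all.
#' @return a \code{\link{genotype_matrix}} with attribute \code{dropped}, a
#'   named integer vector of removed record counts.
#' @export
read_vcf <- function(path, region_filter = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(vcf@gt) < 2L) stop("VCF contains no sample columns")
  fix <- vcf@fix

  n_in <- nrow(fix)
  is_snp <- !is.na(fix[, "REF"]) & !is.na(fix[, "ALT"]) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  is_multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  keep <- is_snp & !is_multi
  n_region <- 0L
  if (!is.null(region_filter)) {
    in_region <- fix[, "CHROM"] %in% region_filter
    n_region <- sum(keep & !in_region)
    keep <- keep & in_region
  }
  dropped <- c(
    multiallelic = sum(is_multi),
    non_snp = sum(!is_snp & !is_multi),
    off_region = n_region
  )
  if (!any(keep)) stop("no biallelic SNP records retained from ", path)

  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  codes <- gt_to_dosage(gt)

  sites <- data.frame(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = fix[keep, "REF"],
    alt = fix[keep, "ALT"],
    stringsAsFactors = FALSE
  )
  for (fld in c("QD", "MQ", "FS", "MQRankSum")) {
    if (grepl(paste0("ID=", fld, ","), paste(vcf@meta, collapse = "\n"))) {
      v <- suppressWarnings(
        vcfR::extract.info(vcf, element = fld, as.numeric = TRUE)
      )
      sites[[fld]] <- v[keep]
    }
  }
  if (any(grepl("ID=GQ,", vcf@meta))) {
    gq <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE)
    )[keep, , drop = FALSE]
    sites$GQ_mean <- rowMeans(gq, na.rm = TRUE)
  }

  gm <- genotype_matrix(t(codes), colnames(gt), sites)
  attr(gm, "dropped") <- dropped
  gm
}

# GT strings (sites x samples) -> integer dosage matrix; half-calls -> NA
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  code <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)[[1]]
    if (length(alleles) != 2L || any(alleles == ".") || any(is.na(alleles)))
      return(NA_integer_)
    a <- suppressWarnings(as.integer(alleles))
    if (anyNA(a) || any(a > 1L)) return(NA_integer_)
    sum(a)
  }, integer(1))
  m <- matrix(code[match(as.vector(gt), u)], nrow = nrow(gt))
  dimnames(m) <- dimnames(gt)
  m
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits a minimal GT-only VCF that round-trips through
#' \code{\link{read_vcf}} losslessly (genotype codes, positions, sample
#' order).  Homozygous/heterozygous codes are written unphased
#' (\code{0/0}, \code{0/1}, \code{1/1}); missing as \code{./.}.
#'
#' @param gm a \code{\link{genotype_matrix}}
#' @param path output file path (".vcf")
#' @return invisibly, the path
#' @export
write_vcf <- function(gm, path) {
  chroms <- unique(gm$sites$chrom)
  extents <- vapply(chroms, function(ch)
    max(gm$sites$pos[gm$sites$chrom == ch]), integer(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    sprintf("##contig=<ID=%s,length=%d>", chroms, extents),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")
  )
  gtmap <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = n_sites(gm), ncol = n_samples(gm))
  ok <- !is.na(t(gm$calls))
  gt[ok] <- gtmap[t(gm$calls)[ok] + 1L]
  body <- paste(
    gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
    ".", "PASS", ".", "GT",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Two-column delimited text (whitespace or tab), optionally with a header
#' row; column 1 is the sample id, column 2 the group label.  Any duplicated
#' sample id is an error.
#'
#' @param path path to the map file
#' @return a named character vector (sample id -> group label) of class
#'   \code{population_map}
#' @export
read_population_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("empty population map: ", path)
  fields <- strsplit(trimws(lines), "[\t ]+")
  if (any(lengths(fields) < 2L))
    stop("population map must have two columns (sample, group)")
  first <- tolower(fields[[1]])
  if (first[1] %in% c("sample", "sample_id", "id") ||
      first[2] %in% c("group", "pop", "population"))
    fields <- fields[-1]
  if (!length(fields)) stop("population map has a header but no rows")
  samples <- vapply(fields, `[`, character(1), 1L)
  groups <- vapply(fields, `[`, character(1), 2L)
  if (anyDuplicated(samples)) {
    dup <- unique(samples[duplicated(samples)])
    stop("duplicated sample id(s) in population map: ",
         paste(dup, collapse = ", "))
  }
  structure(stats::setNames(groups, samples), class = "population_map")
}

#' Samples belonging to each group of a population map
#' @param pm a \code{population_map}
#' @return named list of character vectors, one per group label
#' @export
pop_groups <- function(pm) split(names(pm), unname(unclass(pm)))

# the two group labels of a strictly two-group map, in sorted order
two_groups <- function(pm) {
  g <- sort(unique(unname(unclass(pm))))
  if (length(g) != 2L)
    stop("exactly two population groups required, found ", length(g))
  g
}

#' Read gene annotation from BED or GFF3
#'
#' BED input (0-based half-open) is converted to the package's internal
#' 1-based inclusive convention; GFF3 input keeps its native 1-based
#' coordinates and only \code{gene} features are retained.  Records are
#' sorted by (chrom, start).
#'
#' @param path annotation file
#' @param fmt \code{"bed"} (BED3+1: the 4th column is the gene id/name) or
#'   \code{"gff3"} (gene id from the \code{ID} attribute, name from
#'   \code{Name} when present)
#' @return data.frame with columns chrom, start, end, gene_id, gene_name
#' @export
read_gene_annotation <- function(path, fmt = c("bed", "gff3")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = toupper(fmt)),
    error = function(e) stop("failed to parse ", fmt, " annotation: ",
                             conditionMessage(e))
  )
  if (fmt == "gff3") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    if (!length(gr)) stop("no gene features in GFF3: ", path)
    gene_id <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
    gene_name <- if (!is.null(gr$Name)) as.character(gr$Name) else gene_id
    gene_name[is.na(gene_name)] <- gene_id[is.na(gene_name)]
  } else {
    if (is.null(gr$name) || anyNA(gr$name))
      stop("BED annotation requires a 4th (name) column")
    gene_id <- as.character(gr$name)
    gene_name <- gene_id
  }
  if (any(BiocGenerics::width(gr) < 1L))
    stop("annotation contains empty or inverted intervals")
  if (any(BiocGenerics::start(gr) < 1L))
    stop("annotation contains non-positive coordinates")
  if (any(is.na(gene_id)) || any(!nzchar(gene_id)))
    stop("every gene record needs a non-empty id")
  ann <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    gene_id = gene_id,
    gene_name = gene_name,
    stringsAsFactors = FALSE
  )
  ann[order(ann$chrom, ann$start), , drop = FALSE]
}

#' Write gene annotation as BED (0-based half-open)
#' @param ann data.frame as returned by \code{\link{read_gene_annotation}}
#' @param path output path
#' @return invisibly, the path
#' @export
write_gene_annotation_bed <- function(ann, path) {
  utils::write.table(
    data.frame(ann$chrom, ann$start - 1L, ann$end, ann$gene_id),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Write a tree in Newick format
#'
#' @param tree an \code{ape} \code{phylo} object with >= 3 uniquely-labelled
#'   tips and branch lengths
#' @param path output file
#' @return invisibly, the path
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (length(tree$tip.label) < 3L) stop("a tree needs at least 3 leaves")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

# tab-delimited results table with "." for undefined values
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]][is.nan(out[[j]])] <- NA
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}
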