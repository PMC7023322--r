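#' Pipeline configuration
#'
#' Assembles all inputs and tuning parameters of the full selection scan.
#' The defaults are the package's "standard scan": 100-kb windows sliding
#' by 50 kb, top 1 percent of both ranking statistics, Tajima's D <= 0
#' validation, MAF >= 0.01 / HWE p >= 0.001 / 10 percent missingness QC,
#' and PLINK-default ROH parameters.
#'
#' @param vcf path to the input VCF
#' @param popmap path to the two-column population map
#' @param outdir output directory (created if needed)
#' @param focal_group group label scanned for sweeps
#' @param annotation optional gene-annotation path
#' @param annotation_format \code{"bed"} or \code{"gff3"}
#' @param gene_sets optional GMT file for enrichment
#' @param window_size_bp,step_bp sliding-window geometry
#' @param q upper-tail fraction for candidate selection
#' @param absolute rank by |Z(F_st)| instead of signed Z(F_st)
#' @param fixed_count select a fixed window count instead of a quantile cut
#' @param qc a \code{\link{qc_config}}
#' @param roh a \code{\link{roh_params}}
#' @param seed integer seed (reserved for seeded stages)
#' @return list of class \code{pipeline_config}
#' @export
pipeline_config <- function(vcf, popmap, outdir, focal_group = "sport",
                            annotation = NULL, annotation_format = "bed",
                            gene_sets = NULL,
                            window_size_bp = 100000L, step_bp = 50000L,
                            q = 0.01, absolute = FALSE, fixed_count = FALSE,
                            qc = qc_config(), roh = roh_params(),
                            seed = 1L) {
  structure(list(
    vcf = vcf, popmap = popmap, outdir = outdir,
    focal_group = focal_group,
    annotation = annotation, annotation_format = annotation_format,
    gene_sets = gene_sets,
    window_size_bp = as.integer(window_size_bp),
    step_bp = as.integer(step_bp),
    q = q, absolute = absolute, fixed_count = fixed_count,
    qc = qc, roh = roh, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{pipeline_config}}; the nested
#' \code{qc} and \code{roh} maps mirror \code{\link{qc_config}} and
#' \code{\link{roh_params}}.
#'
#' @param path YAML file
#' @return a \code{pipeline_config}
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("qc", "roh"))]
  if (!is.null(y$qc)) args$qc <- do.call(qc_config, y$qc)
  if (!is.null(y$roh)) args$roh <- do.call(roh_params, y$roh)
  do.call(pipeline_config, args)
}

#' Run the full selection-signature scan
#'
#' Executes the whole pipeline from a configuration: site and sample QC,
#' window grid, per-window diversity / F_st / Tajima's D, Z-transformation
#' and log2 diversity ratio, top-percentile intersection with Tajima's D
#' validation, optional gene annotation of the final windows, ROH detection
#' and the overlap between ROHs and the final candidate regions, and an
#' optional gene-set enrichment test.  Every output table is written under
#' \code{cfg$outdir} together with a key=value run log recording input
#' counts, removal counts, thresholds and set sizes; any stage failure
#' aborts with the stage named.
#'
#' @param cfg a \code{\link{pipeline_config}}
#' @return (invisibly) list with \code{gm}, \code{stats}, \code{candidates},
#'   \code{genes}, \code{roh}, \code{roh_overlap}, \code{enrichment},
#'   \code{log} (named character vector) and \code{files}
#' @export
run_full_scan <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  say <- function(key, value) {
    log[[key]] <<- paste0(key, "=", paste(format(value, trim = TRUE),
                                          collapse = ","))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  gm <- stage("read_vcf", read_vcf(cfg$vcf))
  pm <- stage("read_popmap", read_population_map(cfg$popmap))
  say("n_samples_in", n_samples(gm))
  say("n_sites_in", n_sites(gm))

  qc <- cfg$qc
  say("qc_maf_min", qc$maf_min)
  say("qc_hwe_p_min", qc$hwe_p_min)
  say("qc_site_call_rate_min", qc$site_call_rate_min)
  say("qc_sample_call_rate_min", qc$sample_call_rate_min)
  sq <- stage("site_qc", apply_site_qc(gm, qc))
  for (nm in names(sq$removed)) say(paste0("removed_", nm), sq$removed[[nm]])
  if (length(sq$skipped_annotations))
    say("skipped_annotation_filters",
        paste(sq$skipped_annotations, collapse = ","))
  smq <- stage("sample_qc", apply_sample_qc(sq$gm, qc))
  gm <- smq$gm
  say("removed_samples", length(smq$removed_samples))
  say("n_sites_qc", n_sites(gm))
  say("n_samples_qc", n_samples(gm))

  extents <- tapply(gm$sites$pos, gm$sites$chrom, max)
  grid <- stage("window_grid",
                make_windows(extents, cfg$window_size_bp, cfg$step_bp))
  say("window_size_bp", cfg$window_size_bp)
  say("step_bp", cfg$step_bp)
  say("n_windows", nrow(grid))

  ws <- stage("window_stats",
              compute_window_stats(gm, pm, grid, cfg$focal_group))
  say("n_windows_ranked", sum(is.finite(ws$z_fst)))

  say("top_fraction_q", cfg$q)
  say("tajima_filter", "D<=0")
  cand <- stage("candidate_windows",
                candidate_windows(ws, cfg$q, cfg$absolute, cfg$fixed_count))
  say("z_fst_cut", cand$thresholds$z_fst_cut)
  say("ratio_cut", cand$thresholds$ratio_cut)
  say("n_top_fst", length(cand$top_fst))
  say("n_top_ratio", length(cand$top_ratio))
  say("n_shared", length(cand$shared))
  say("n_final", length(cand$final))

  genes <- NULL
  ann <- NULL
  if (!is.null(cfg$annotation)) {
    ann <- stage("read_annotation",
                 read_gene_annotation(cfg$annotation, cfg$annotation_format))
    genes <- stage("annotate_genes",
                   annotate_genes(ws[cand$final, c("chrom", "start", "end")],
                                  ann))
    say("n_genes_final", attr(genes, "n_distinct_genes"))
  }

  for (nm in names(unclass(cfg$roh)))
    say(paste0("roh_", nm), cfg$roh[[nm]])
  roh <- stage("detect_roh", detect_roh(gm, cfg$roh))
  say("n_roh_segments", nrow(roh))
  final_windows <- ws[cand$final, c("chrom", "start", "end")]
  roh_iv <- data.frame(chrom = roh$chrom, start = roh$start_bp,
                       end = roh$end_bp, stringsAsFactors = FALSE)
  ovl <- stage("roh_overlap", overlap_regions(final_windows, roh_iv))
  say("n_roh_overlap_regions", nrow(ovl))

  enr <- NULL
  if (!is.null(cfg$gene_sets) && !is.null(genes) && !is.null(ann)) {
    sets <- stage("read_gene_sets", read_gmt(cfg$gene_sets))
    cand_genes <- unique(unlist(genes))
    if (length(cand_genes)) {
      enr <- stage("enrichment",
                   enrichment_test(cand_genes, unique(ann$gene_id), sets))
      say("n_enrichment_terms", nrow(enr))
    } else {
      say("n_enrichment_terms", 0L)
    }
  }

  files <- c(
    windows = file.path(cfg$outdir, "windows.tsv"),
    candidates = file.path(cfg$outdir, "candidates.tsv"),
    thresholds = file.path(cfg$outdir, "thresholds.txt"),
    roh_segments = file.path(cfg$outdir, "roh_segments.tsv"),
    roh_overlap = file.path(cfg$outdir, "roh_overlap.tsv"),
    run_log = file.path(cfg$outdir, "run_log.txt")
  )
  write_tsv(ws, files["windows"])

  cand_tab <- ws
  cand_tab$in_top_fst <- seq_len(nrow(ws)) %in% cand$top_fst
  cand_tab$in_top_ratio <- seq_len(nrow(ws)) %in% cand$top_ratio
  cand_tab$in_shared <- seq_len(nrow(ws)) %in% cand$shared
  cand_tab$in_final <- seq_len(nrow(ws)) %in% cand$final
  cand_tab <- cand_tab[cand_tab$in_top_fst | cand_tab$in_top_ratio, ,
                       drop = FALSE]
  if (!is.null(genes)) {
    key <- window_keys(cand_tab)
    cand_tab$genes <- vapply(key, function(k) {
      g <- genes[[k]]
      if (is.null(g) || !length(g)) "." else paste(g, collapse = ",")
    }, character(1))
  }
  write_tsv(cand_tab, files["candidates"])

  writeLines(c(
    paste0("z_fst_cut=", format(cand$thresholds$z_fst_cut, digits = 15)),
    paste0("ratio_cut=", format(cand$thresholds$ratio_cut, digits = 15))
  ), files["thresholds"])

  write_tsv(roh, files["roh_segments"])
  write_tsv(ovl, files["roh_overlap"])
  if (!is.null(enr))
    write_tsv(enr, files["enrichment"] <- file.path(cfg$outdir,
                                                    "enrichment.tsv"))
  writeLines(unlist(log), files["run_log"])

  invisible(list(gm = gm, stats = ws, candidates = cand, genes = genes,
                 roh = roh, roh_overlap = ovl, enrichment = enr,
                 log = unlist(log), files = files))
}
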