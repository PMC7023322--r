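test_that("top-percentile threshold uses the interpolated quantile", {
  sel <- top_percentile(1:100, 0.01)
  expect_equal(sel$threshold, 99.01)
  expect_equal(sel$selected, 100L)

  # ties at the threshold are all selected
  vals <- c(rep(1, 90), rep(10, 10))
  sel2 <- top_percentile(vals, 0.05)
  expect_equal(sel2$selected, 91:100)

  # NA windows are ignored, not selected
  vals3 <- c(NA, 1:99)
  sel3 <- top_percentile(vals3, 0.02)
  expect_false(1L %in% sel3$selected)

  expect_error(top_percentile(c(1, NA, NA), 0.01), "defined")

  # fixed-count variant picks ceiling(q * N) values
  sel4 <- top_percentile(1:200, 0.01, fixed_count = TRUE)
  expect_equal(length(sel4$selected), 2L)
})

test_that("candidate sets respect the nesting and the Tajima filter", {
  set.seed(77)
  n <- 300
  ws <- data.frame(
    chrom = "chr1", start = seq(1, by = 50000, length.out = n),
    end = seq(100000, by = 50000, length.out = n),
    n_snps = 100L,
    pi_focal = runif(n, 0.001, 0.01), pi_background = runif(n, 0.001, 0.01),
    fst = runif(n), z_fst = NA_real_, log2_ratio = NA_real_,
    tajima_d_focal = rnorm(n), s_focal = 50L
  )
  ws$z_fst <- z_transform(ws$fst)
  ws$log2_ratio <- log2_pi_ratio(ws$pi_background, ws$pi_focal)
  cand <- candidate_windows(ws, q = 0.1)
  expect_true(all(cand$final %in% cand$shared))
  expect_true(all(cand$shared %in% cand$top_fst))
  expect_true(all(cand$shared %in% cand$top_ratio))
  expect_true(all(ws$tajima_d_focal[cand$final] <= 0))
  # windows with D > 0 or undefined D are excluded from final
  dropped <- setdiff(cand$shared, cand$final)
  expect_true(all(is.na(ws$tajima_d_focal[dropped]) |
                    ws$tajima_d_focal[dropped] > 0))

  # lowering q never grows any selected set
  cand_small <- candidate_windows(ws, q = 0.05)
  expect_true(all(cand_small$top_fst %in% cand$top_fst))
  expect_true(all(cand_small$top_ratio %in% cand$top_ratio))
  expect_true(all(cand_small$shared %in% cand$shared))
  expect_true(all(cand_small$final %in% cand$final))
})

test_that("negative Tajima's D windows survive the validation filter", {
  ws <- data.frame(
    chrom = "chr1", start = c(1, 50001, 100001), end = c(1e5, 15e4, 2e5),
    n_snps = 10L, pi_focal = c(0.001, 0.001, 0.005),
    pi_background = c(0.01, 0.01, 0.005),
    fst = c(0.8, 0.7, 0.05), z_fst = NA_real_, log2_ratio = NA_real_,
    tajima_d_focal = c(-2.8, 0.1, -1), s_focal = 5L
  )
  ws$z_fst <- z_transform(ws$fst)
  ws$log2_ratio <- log2_pi_ratio(ws$pi_background, ws$pi_focal)
  cand <- candidate_windows(ws, q = 0.5)
  expect_true(1L %in% cand$final)       # D = -2.8 retained
  expect_false(2L %in% cand$final)      # D = +0.1 excluded
  expect_true(2L %in% cand$shared)
})

test_that("genes map to windows by 1-bp interval overlap, deduplicated", {
  windows <- data.frame(chrom = "chr1", start = c(200L, 1000L),
                        end = c(300L, 1100L))
  ann <- data.frame(
    chrom = "chr1", start = c(150L, 301L, 250L, 1050L),
    end = c(250L, 400L, 1050L, 1080L),
    gene_id = c("gA", "gB", "gC", "gD"),
    gene_name = c("gA", "gB", "gC", "gD"), stringsAsFactors = FALSE)
  genes <- annotate_genes(windows, ann)
  expect_setequal(genes[["chr1:200-300"]], c("gA", "gC"))   # gB abuts only
  expect_setequal(genes[["chr1:1000-1100"]], c("gC", "gD"))
  # gC spans both windows but counts once in the distinct total
  expect_equal(attr(genes, "n_distinct_genes"), 3L)
  expect_lte(attr(genes, "n_distinct_genes"), sum(lengths(genes)))
})

test_that("interval intersection returns maximal overlaps or empty", {
  a <- data.frame(chrom = "chr1", start = 1L, end = 100L)
  b <- data.frame(chrom = "chr1", start = 50L, end = 150L)
  got <- overlap_regions(a, b)
  expect_equal(got$start, 50L); expect_equal(got$end, 100L)

  disjoint <- overlap_regions(a, data.frame(chrom = "chr1", start = 200L,
                                            end = 300L))
  expect_equal(nrow(disjoint), 0L)

  inner <- data.frame(chrom = "chr1", start = 20L, end = 30L)
  expect_equal(overlap_regions(a, inner), inner)
})

test_that("enrichment p-values match the hypergeometric tail oracle", {
  bg <- sprintf("g%03d", 1:100)
  cand <- bg[1:10]
  sets <- list(self = cand, disjoint = bg[51:60],
               partial = bg[6:25], all = bg)
  res <- enrichment_test(cand, bg, sets)
  expect_equal(res$term[1], "self")  # minimal p among terms
  expect_equal(res$p[res$term == "disjoint"], 1)
  for (term in names(sets)) {
    k <- length(intersect(cand, sets[[term]]))
    expect_equal(res$p[res$term == term],
                 oracle_fisher_greater(k, length(sets[[term]]), 10, 100),
                 tolerance = 1e-12)
  }
  expect_equal(res$fdr, p.adjust(res$p, "BH"))

  set.seed(88)
  for (rep in 1:30) {
    n_bg <- sample(20:80, 1)
    bgr <- sprintf("r%03d", seq_len(n_bg))
    cnd <- sample(bgr, sample(3:10, 1))
    st <- list(t1 = sample(bgr, sample(2:15, 1)))
    res <- enrichment_test(cnd, bgr, st)
    expect_equal(res$p,
                 oracle_fisher_greater(length(intersect(cnd, st$t1)),
                                       length(st$t1), length(cnd), n_bg),
                 tolerance = 1e-12)
  }
  expect_error(enrichment_test(character(0), bg, sets), "empty")
  expect_error(enrichment_test(c(cand, "novel"), bg, sets), "missing")
})

test_that("GMT gene sets parse into named lists", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("term1\tdesc\tg1\tg2\tg3", "term2\tdesc\tg2"), path)
  sets <- read_gmt(path)
  expect_equal(names(sets), c("term1", "term2"))
  expect_equal(sets$term1, c("g1", "g2", "g3"))
})
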