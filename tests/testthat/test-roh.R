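test_that("an ideal homozygous stretch yields exactly one run", {
  # 200 consecutive homozygous SNPs spanning ~2 Mb at 10 kb/SNP
  pos <- seq(10000L, by = 10000L, length.out = 200L)
  gm <- make_gm(matrix(0L, nrow = 1, ncol = 200), pos = pos)
  segs <- detect_roh(gm, roh_params())
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_snps, 200L)
  expect_equal(segs$start_bp, pos[1])
  expect_equal(segs$end_bp, pos[200])

  # all-heterozygous sample: no runs
  gm_het <- make_gm(matrix(1L, nrow = 1, ncol = 200), pos = pos)
  expect_equal(nrow(detect_roh(gm_het, roh_params())), 0L)

  # chromosome with fewer SNPs than the window yields no calls, logged
  gm_small <- make_gm(matrix(0L, nrow = 1, ncol = 10))
  out <- detect_roh(gm_small, roh_params())
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "skipped_chroms"), "chr1")
})

test_that("runs split at large gaps and honour size constraints", {
  pos <- c(seq(10000L, by = 10000L, length.out = 150L),
           seq(3000000L, by = 10000L, length.out = 150L))  # 1.5 Mb gap
  gm <- make_gm(matrix(0L, nrow = 1, ncol = 300), pos = pos)
  segs <- detect_roh(gm, roh_params())
  expect_equal(nrow(segs), 2L)
  expect_true(all(segs$n_snps >= 100L))
  expect_true(all(segs$length_kb >= 1000))

  # sparse SNPs fail the density check: 150 SNPs over 15 Mb = 100 kb/SNP
  pos_sparse <- seq(100000L, by = 100000L, length.out = 150L)
  gm_sparse <- make_gm(matrix(0L, nrow = 1, ncol = 150), pos = pos_sparse)
  # gaps are each 100 kb < 1000-kb gap limit, so only density can reject
  expect_equal(nrow(detect_roh(gm_sparse, roh_params())), 0L)
})

test_that("detection agrees with a naive reimplementation on random input", {
  set.seed(99)
  params <- roh_params(window_snp = 20L, min_snp = 25L, min_kb = 100,
                       density_kb_per_snp = 50, gap_kb = 200)
  for (rep in 1:12) {
    m <- sample(500:3000, 1)
    pos <- sort(sample.int(m * 8000L, m))
    # mosaic of homozygous stretches and noisy regions
    g <- integer(m)
    i <- 1L
    while (i <= m) {
      len <- sample(50:400, 1)
      block <- if (runif(1) < 0.5) {
        sample(0:2, len, replace = TRUE, prob = c(0.48, 0.04, 0.48))
      } else {
        sample(0:2, len, replace = TRUE, prob = c(0.3, 0.4, 0.3))
      }
      g[i:min(m, i + len - 1L)] <- block[seq_len(min(len, m - i + 1L))]
      i <- i + len
    }
    g[sample.int(m, round(0.02 * m))] <- NA
    gm <- make_gm(matrix(g, nrow = 1), pos = pos)
    got <- detect_roh(gm, params)
    want <- oracle_roh(g, pos, params)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start_bp, want$start_bp)
      expect_equal(got$end_bp, want$end_bp)
      expect_equal(got$n_snps, want$n_snps)
    }
  }
})

test_that("adding a heterozygous call never lengthens a run", {
  set.seed(111)
  pos <- seq(5000L, by = 5000L, length.out = 400L)
  g <- sample(c(0L, 2L), 400, replace = TRUE)
  gm <- make_gm(matrix(g, nrow = 1), pos = pos)
  params <- roh_params(min_snp = 50L, min_kb = 200)
  base <- detect_roh(gm, params)
  expect_gte(nrow(base), 1L)
  span_of <- function(segs) sum(segs$end_bp - segs$start_bp + 1)
  for (k in c(100L, 200L, 300L)) {
    g2 <- g; g2[k] <- 1L
    got <- detect_roh(make_gm(matrix(g2, nrow = 1), pos = pos), params)
    expect_lte(span_of(got), span_of(base))
  }
})

test_that("detection is independent across samples", {
  set.seed(122)
  pos <- seq(4000L, by = 4000L, length.out = 600L)
  g1 <- sample(c(0L, 2L), 600, replace = TRUE)
  g2 <- sample(0:2, 600, replace = TRUE)
  params <- roh_params(min_snp = 50L, min_kb = 200)
  both <- detect_roh(make_gm(rbind(g1, g2), pos = pos,
                             ids = c("a", "b")), params)
  alone <- detect_roh(make_gm(matrix(g1, nrow = 1), pos = pos,
                              ids = "a"), params)
  got_a <- both[both$sample_id == "a", c("start_bp", "end_bp", "n_snps")]
  rownames(got_a) <- NULL
  expect_equal(got_a, alone[, c("start_bp", "end_bp", "n_snps")])
})

test_that("ROH summary tabulates counts, length bins and chromosome share", {
  segs <- data.frame(
    sample_id = c("a", "a", "a", "b", "b", "b", "b", "b", "b", "b"),
    chrom = c("chr1", "chr1", "chr2", rep("chr1", 5), "chr2", "chr2"),
    start_bp = 1L, end_bp = 2L,
    n_snps = 120L,
    length_kb = c(1200, 1200, 1400, 1100, 1600, 2100, 1200, 1300,
                  1250, 3200),
    stringsAsFactors = FALSE)
  pm <- structure(c(a = "sport", b = "non_sport"),
                  class = "population_map")
  s <- summarize_roh(segs, pm)
  expect_equal(s$counts[["sport"]], 3L)
  expect_equal(s$counts[["non_sport"]], 7L)
  # all sport runs are 1-1.5 Mb: 100% in the modal bin
  sport_bins <- s$length_bins[s$length_bins$group == "sport", ]
  expect_equal(sport_bins$pct[sport_bins$bin == "1.0-1.5"], 100)
  ch <- s$by_chrom
  expect_equal(ch$pct[ch$group == "non_sport" & ch$chrom == "chr1"],
               100 * 5 / 7)
  expect_equal(s$longest$length_kb[s$longest$group == "non_sport"], 3200)

  empty <- summarize_roh(segs[0, ], pm)
  expect_equal(length(empty$counts), 0L)
})
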