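test_that("window grid arithmetic follows the coordinate convention", {
  g <- make_windows(c(chr1 = 250000))
  expect_equal(g$start, c(1L, 50001L, 100001L, 150001L, 200001L))
  expect_equal(g$end[1], 100000L)

  # step = size gives non-overlapping tiling windows
  g2 <- make_windows(c(chr1 = 300000), 100000, 100000)
  expect_equal(g2$start, c(1L, 100001L, 200001L))
  expect_true(all(g2$end - g2$start + 1L == 100000L))

  # every start <= the chromosome extent; consecutive starts differ by step
  g3 <- make_windows(c(chr1 = 99999))
  expect_true(all(g3$start <= 99999))
  expect_equal(unique(diff(g3$start)), 50000L)

  expect_error(make_windows(numeric(0)), "empty")
})

test_that("windowed diversity matches the closed form and brute force", {
  # one site, 2 diploids both het: c_ref = c_alt = 2 -> 2*2*2/(4*3) = 2/3
  gm <- make_gm(matrix(c(1L, 1L), nrow = 2), pos = 50L)
  grid <- make_windows(c(chr1 = 100), 100000, 100000)
  expect_equal(windowed_pi(gm, gm$sample_ids, grid), (2 / 3) / 100000)

  # monomorphic window -> 0
  gm0 <- make_gm(matrix(2L, nrow = 3, ncol = 4))
  expect_equal(windowed_pi(gm0, gm0$sample_ids, whole_grid(gm0)), 0)

  set.seed(11)
  for (rep in 1:8) {
    gm <- random_gm(10, 50, miss = 0.1)
    grid <- whole_grid(gm)
    got <- windowed_pi(gm, gm$sample_ids, grid)
    want <- oracle_window_pi(gm$calls, attr(grid, "window_size_bp"))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("Tajima's D agrees with an independent computation", {
  # n = 4 haplotypes (2 diploids), hand-built window with S = 3
  calls <- rbind(c(0L, 1L, 2L), c(1L, 1L, 0L))
  gm <- make_gm(calls)
  got <- tajima_d(gm, gm$sample_ids, whole_grid(gm))
  expect_equal(got$s, 3L)
  expect_equal(got$d, oracle_tajima_d(calls), tolerance = 1e-12)

  # S = 0 -> undefined
  gm0 <- make_gm(matrix(0L, nrow = 3, ncol = 5))
  expect_true(is.na(tajima_d(gm0, gm0$sample_ids, whole_grid(gm0))$d))

  set.seed(21)
  for (rep in 1:8) {
    gm <- random_gm(sample(2:8, 1), 30, miss = 0.05)
    got <- tajima_d(gm, gm$sample_ids, whole_grid(gm))
    expect_equal(got$d, oracle_tajima_d(gm$calls), tolerance = 1e-10)
  }
})

test_that("Weir-Cockerham F_st: fixed difference gives 1, panmixia <= 0", {
  calls <- rbind(matrix(2L, 4, 10), matrix(0L, 6, 10))
  gm <- make_gm(calls)
  pm <- make_popmap(gm, 4)
  expect_equal(windowed_wc_fst(gm, pm, whole_grid(gm)), 1)

  one <- matrix(sample(0:2, 30, replace = TRUE), nrow = 5,
                ncol = 6, byrow = FALSE)
  gm2 <- make_gm(rbind(one, one))
  pm2 <- make_popmap(gm2, 5)
  est <- windowed_wc_fst(gm2, pm2, whole_grid(gm2))
  expect_lte(est, 0)  # no among-population variance; no clamping
})

test_that("Weir-Cockerham F_st matches the brute-force oracle", {
  set.seed(33)
  for (rep in 1:10) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    gm <- random_gm(n1 + n2, 50, miss = 0.1)
    pm <- make_popmap(gm, n1)
    got <- windowed_wc_fst(gm, pm, whole_grid(gm))
    grp <- pop_groups(pm)
    want <- oracle_wc_fst(t(sapply(grp[["sport"]],
                                   function(s) gm$calls[s, ])),
                          t(sapply(grp[["non_sport"]],
                                   function(s) gm$calls[s, ])))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("statistics are invariant to sample order and allele relabeling", {
  set.seed(44)
  gm <- random_gm(12, 60, miss = 0.05)
  pm <- make_popmap(gm, 5)
  grid <- whole_grid(gm)

  perm <- sample(n_samples(gm))
  gmp <- subset_genotypes(gm, samples = perm)
  expect_equal(windowed_wc_fst(gmp, pm, grid),
               windowed_wc_fst(gm, pm, grid), tolerance = 1e-12)
  expect_equal(windowed_pi(gmp, gm$sample_ids, grid),
               windowed_pi(gm, gm$sample_ids, grid), tolerance = 1e-12)

  flip <- gm
  flip$calls <- 2L - gm$calls
  expect_equal(windowed_pi(flip, gm$sample_ids, grid),
               windowed_pi(gm, gm$sample_ids, grid), tolerance = 1e-12)
  expect_equal(windowed_wc_fst(flip, pm, grid),
               windowed_wc_fst(gm, pm, grid), tolerance = 1e-12)
  expect_equal(tajima_d(flip, gm$sample_ids, grid)$d,
               tajima_d(gm, gm$sample_ids, grid)$d, tolerance = 1e-12)
})

test_that("window values depend only on the sites inside the window", {
  set.seed(55)
  calls <- matrix(sample(0:2, 8 * 20, replace = TRUE), nrow = 8)
  pos_a <- sort(sample(1:200000, 20))
  pos_a[10] <- 99999L                       # inside window 1 only
  gm_a <- make_gm(calls, pos = sort(pos_a))
  pos_b <- pos_a; pos_b[10] <- 100002L      # crosses into windows 2 and 3
  gm_b <- make_gm(calls, pos = sort(pos_b))
  grid <- make_windows(c(chr1 = 200000), 100000, 50000)
  pa <- windowed_pi(gm_a, gm_a$sample_ids, grid)
  pb <- windowed_pi(gm_b, gm_b$sample_ids, grid)
  # window 2 ([50001,150000]) contains the SNP both times; only 1 and 3 move
  expect_equal(pa[2], pb[2], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(pa[1], pb[1])))
  expect_false(isTRUE(all.equal(pa[3], pb[3])))
})

test_that("z-transform standardises defined values and keeps NA/Inf", {
  expect_equal(z_transform(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(66)
  x <- rnorm(50)
  x[c(3, 17)] <- NA
  z <- z_transform(x)
  expect_true(all(is.na(z[c(3, 17)])))
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_error(z_transform(rep(2, 5)), "zero-variance")
})

test_that("log2 diversity ratio handles zeros and undefined windows", {
  expect_equal(log2_pi_ratio(0.02, 0.02), 0)
  expect_equal(log2_pi_ratio(0.04, 0.02), 1)
  expect_equal(log2_pi_ratio(0.01, 0), Inf)
  expect_equal(log2_pi_ratio(0, 0.01), -Inf)
  expect_true(is.na(log2_pi_ratio(0, 0)))

  # +Inf windows are always in the selected top set
  vals <- c(rnorm(99), Inf)
  sel <- top_percentile(vals, 0.01)
  expect_true(100 %in% sel$selected)
})
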