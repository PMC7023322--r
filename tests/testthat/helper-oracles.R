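# independent brute-force oracles; deliberately naive, no shared code with
# the implementation

# window diversity by explicit enumeration of all observed allele pairs
oracle_window_pi <- function(calls, window_bp) {
  total <- 0
  for (j in seq_len(ncol(calls))) {
    g <- calls[, j]
    alleles <- integer(0)
    for (gi in g[!is.na(g)]) {
      alleles <- c(alleles, switch(gi + 1L, c(0L, 0L), c(0L, 1L),
                                   c(1L, 1L)))
    }
    c_tot <- length(alleles)
    if (c_tot < 2) next
    diffs <- 0
    for (a in seq_len(c_tot - 1))
      for (b in (a + 1):c_tot)
        diffs <- diffs + (alleles[a] != alleles[b])
    total <- total + diffs / choose(c_tot, 2)
  }
  total / window_bp
}

# Weir-Cockerham (1984) variance components for one site, two populations,
# written scalar-by-scalar from the published formulas
oracle_wc_site <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 1 || n2 < 1) return(NULL)
  r <- 2
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
  nbar <- mean(c(n1, n2))
  if (nbar <= 1) return(NULL)
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  if (nc <= 0) return(NULL)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  if (pbar <= 0 || pbar >= 1) return(NULL)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

oracle_wc_fst <- function(calls1, calls2) {
  num <- den <- 0
  for (j in seq_len(ncol(calls1))) {
    comp <- oracle_wc_site(calls1[, j], calls2[, j])
    if (is.null(comp)) next
    num <- num + comp$a
    den <- den + comp$a + comp$b + comp$c
  }
  if (den == 0) NA_real_ else num / den
}

# Tajima's D from first principles: explicit harmonic sums and the
# published variance constants, pairwise differences by allele enumeration
oracle_tajima_d <- function(calls, window_bp = NULL) {
  n <- 2 * nrow(calls)
  if (n < 4) return(NA_real_)
  s <- 0; ppi <- 0
  for (j in seq_len(ncol(calls))) {
    g <- unname(calls[, j][!is.na(calls[, j])])
    alleles <- unlist(lapply(g, function(x)
      switch(x + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))))
    if (length(alleles) < 2) next
    if (length(unique(alleles)) > 1) s <- s + 1
    d <- 0
    for (a in seq_len(length(alleles) - 1))
      for (b in (a + 1):length(alleles))
        d <- d + (alleles[a] != alleles[b])
    ppi <- ppi + d / choose(length(alleles), 2)
  }
  if (s == 0) return(NA_real_)
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (ppi - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
}

# exact HWE p by exhaustive enumeration of ref-allele placements: all
# choose(2n, nA) subsets of allele slots, pairing consecutive slots into
# individuals (feasible for n <= 8)
oracle_hwe_subsets <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  na <- 2 * n_hom_ref + n_het
  if (na == 0 || na == 2 * n) return(1)
  slots <- 2 * n
  combs <- utils::combn(slots, na)
  het_counts <- apply(combs, 2, function(ref_pos) {
    is_ref <- rep(FALSE, slots)
    is_ref[ref_pos] <- TRUE
    sum(is_ref[seq(1, slots, 2)] != is_ref[seq(2, slots, 2)])
  })
  tab <- table(het_counts)
  probs <- as.numeric(tab) / ncol(combs)
  p_obs <- probs[match(n_het, as.integer(names(tab)))]
  sum(probs[probs <= p_obs + 1e-12])
}

# exact HWE p via the Wigginton et al. recurrence (independent route for
# larger n): P(h + 2) / P(h) = (na - h)(nb - h) / ((h + 2)(h + 1) / ... )
oracle_hwe_recurrence <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  na <- 2 * n_hom_ref + n_het
  nb <- 2 * n - na
  if (na == 0 || nb == 0) return(1)
  n_minor <- min(na, nb)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  w <- numeric(length(hets))
  w[1] <- 1
  if (length(hets) > 1) {
    for (k in 2:length(hets)) {
      h <- hets[k - 1]
      # hom pairs split into one extra het pair each
      w[k] <- w[k - 1] * ((na - h) * (nb - h)) / ((h + 2) * (h + 1))
    }
  }
  probs <- w / sum(w)
  p_obs <- probs[match(n_het, hets)]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# naive ROH scan: literal loops over windows and SNPs
oracle_roh <- function(g, pos, params) {
  m <- length(g)
  w <- params$window_snp
  if (m < w) return(data.frame(start_bp = integer(0), end_bp = integer(0),
                               n_snps = integer(0)))
  hom_win <- logical(m - w + 1)
  for (s in seq_along(hom_win)) {
    win <- g[s:(s + w - 1)]
    hom_win[s] <- sum(win == 1, na.rm = TRUE) <= params$window_het &&
      sum(is.na(win)) <= params$window_missing
  }
  eligible <- logical(m)
  for (i in seq_len(m)) {
    ss <- max(1, i - w + 1):min(i, m - w + 1)
    eligible[i] <- mean(hom_win[ss]) >= params$window_threshold
  }
  segs <- list()
  i <- 1
  while (i <= m) {
    if (!eligible[i]) { i <- i + 1; next }
    j <- i
    while (j < m && eligible[j + 1] &&
           (pos[j + 1] - pos[j]) <= params$gap_kb * 1000) j <- j + 1
    n <- j - i + 1
    len_kb <- (pos[j] - pos[i] + 1) / 1000
    if (n >= params$min_snp && len_kb >= params$min_kb &&
        len_kb / n <= params$density_kb_per_snp)
      segs[[length(segs) + 1]] <- data.frame(start_bp = pos[i],
                                             end_bp = pos[j], n_snps = n)
    i <- j + 1
  }
  if (!length(segs)) return(data.frame(start_bp = integer(0),
                                       end_bp = integer(0),
                                       n_snps = integer(0)))
  do.call(rbind, segs)
}

# one-sided over-representation p by explicit hypergeometric tail summation
oracle_fisher_greater <- function(k, n_set, n_cand, n_bg) {
  kk <- k:min(n_set, n_cand)
  sum(stats::dhyper(kk, n_set, n_bg - n_set, n_cand))
}

# random additive tree: unrooted binary topology with positive lengths
random_additive_tree <- function(n_taxa, min_len = 0.1, max_len = 1) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(n) stats::runif(n, min_len, max_len))
  tr$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  tr
}
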