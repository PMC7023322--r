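# run code under a local RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Parameters of the two-population genotype simulator.  The defaults
#' emulate a 16-vs-35 diploid resequencing design: 20 chromosomes of 5 Mb,
#' one SNP per kb, Balding-Nichols background differentiation F = 0.05, and
#' 10 planted 100-kb selective-sweep windows in which the focal ("sport")
#' group's diversity is depressed about \code{sweep_pi_reduction}-fold, its
#' allele frequencies are pushed toward fixation (displaced toward ALT by
#' about \code{sweep_freq_shift}) and residual polymorphism is skewed to
#' rare variants, driving Tajima's D negative.
#'
#' @param n_sport,n_nonsport diploid sample counts for the focal and
#'   background groups
#' @param n_chrom number of chromosomes
#' @param chrom_len_bp chromosome length in bp
#' @param snp_density_per_kb expected SNPs per kb
#' @param background_F Balding-Nichols differentiation parameter, in (0, 1)
#' @param theta_per_window coalescent theta used by
#'   \code{\link{simulate_coalescent_window}}
#' @param n_sweeps number of planted sweep windows
#' @param sweep_pi_reduction target fold-reduction of focal-group diversity
#'   inside sweep windows
#' @param sweep_freq_shift target ALT-frequency displacement of the focal
#'   group inside sweep windows
#' @param sweep_window_bp sweep window span (aligned to the analysis grid)
#' @param seed integer seed; all randomness derives from it (one stream per
#'   chromosome)
#' @return list of class \code{sim_config}
#' @export
sim_config <- function(n_sport = 16L, n_nonsport = 35L, n_chrom = 20L,
                       chrom_len_bp = 5000000L, snp_density_per_kb = 1,
                       background_F = 0.05, theta_per_window = 10,
                       n_sweeps = 10L, sweep_pi_reduction = 5,
                       sweep_freq_shift = 0.6, sweep_window_bp = 100000L,
                       seed = 42L) {
  stopifnot(n_sport >= 2L, n_nonsport >= 2L, n_chrom >= 1L,
            chrom_len_bp >= 1L, snp_density_per_kb > 0,
            background_F > 0, background_F < 1,
            theta_per_window > 0, n_sweeps >= 0L,
            sweep_pi_reduction >= 1, sweep_freq_shift >= 0,
            sweep_freq_shift <= 1)
  structure(list(
    n_sport = as.integer(n_sport), n_nonsport = as.integer(n_nonsport),
    n_chrom = as.integer(n_chrom), chrom_len_bp = as.integer(chrom_len_bp),
    snp_density_per_kb = snp_density_per_kb, background_F = background_F,
    theta_per_window = theta_per_window, n_sweeps = as.integer(n_sweeps),
    sweep_pi_reduction = sweep_pi_reduction,
    sweep_freq_shift = sweep_freq_shift,
    sweep_window_bp = as.integer(sweep_window_bp),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Neutral coalescent window
#'
#' Samples one window under the standard neutral coalescent without
#' recombination: exponential coalescence times with rate choose(k, 2)
#' while k lineages remain, Poisson(theta/2 x branch length) mutations on
#' the genealogy under the infinite-sites model.  Used as the neutral
#' oracle for Tajima's D (expected D near 0, E[S] = theta x a1,
#' E[pi] = theta).
#'
#' @param n_haplotypes number of sampled haplotypes (>= 2)
#' @param theta population-scaled mutation rate for the window
#' @param seed optional integer seed (local to this call)
#' @param length_bp span over which site positions are placed uniformly
#' @return list with \code{haplotypes} (n x S 0/1 matrix) and
#'   \code{positions} (sorted unique integers in 1..length_bp)
#' @export
simulate_coalescent_window <- function(n_haplotypes, theta, seed = NULL,
                                       length_bp = 100000L) {
  stopifnot(n_haplotypes >= 2L, theta > 0)
  run <- function() {
    n <- n_haplotypes
    lineages <- as.list(seq_len(n))
    seg_members <- list()
    seg_len <- numeric(0)
    for (k in n:2) {
      t_k <- stats::rexp(1, rate = k * (k - 1) / 2)
      seg_members <- c(seg_members, lineages)
      seg_len <- c(seg_len, rep(t_k, k))
      pair <- sample.int(k, 2L)
      merged <- c(lineages[[pair[1]]], lineages[[pair[2]]])
      lineages <- c(lineages[-pair], list(merged))
    }
    total_len <- sum(seg_len)
    s <- stats::rpois(1, theta / 2 * total_len)
    hap <- matrix(0L, nrow = n, ncol = s)
    if (s > 0) {
      seg <- sample.int(length(seg_len), s, replace = TRUE, prob = seg_len)
      for (j in seq_len(s)) hap[seg_members[[seg[j]]], j] <- 1L
    }
    pos <- sort(sample.int(length_bp, min(s, length_bp)))
    # infinite sites: collisions impossible by sampling without replacement
    list(haplotypes = hap[, seq_along(pos), drop = FALSE], positions = pos)
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Two-locus genotype sample with controlled linkage
#'
#' Draws diploid dosages at two loci whose haplotype alleles have
#' correlation \code{rho} (both marginal allele frequencies \code{p}),
#' so the dosage correlation is \code{rho} and composite r^2 estimates
#' \code{rho^2}.  Used to calibrate the LD-decay estimator.
#'
#' @param n_ind number of diploid individuals
#' @param p allele frequency at both loci
#' @param rho haplotype allele correlation, in [0, 1]
#' @param seed optional integer seed (local to this call)
#' @return integer matrix with \code{n_ind} rows and 2 dosage columns
#' @export
simulate_linked_pair <- function(n_ind, p, rho, seed = NULL) {
  stopifnot(n_ind >= 1, p > 0, p < 1, rho >= 0, rho <= 1)
  run <- function() {
    a <- matrix(stats::rbinom(2L * n_ind, 1L, p), ncol = 2L)
    copy <- matrix(stats::runif(2L * n_ind) < rho, ncol = 2L)
    bnew <- matrix(stats::rbinom(2L * n_ind, 1L, p), ncol = 2L)
    b <- ifelse(copy, a, bnew)
    cbind(rowSums(a), rowSums(b))
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

# expected per-site pairwise diversity of the Balding-Nichols background,
# with ancestral frequency ~ U(lo, hi):  2 (1 - F) E[p (1 - p)]
bn_expected_site_pi <- function(F, lo = 0.05, hi = 0.95) {
  m <- (lo + hi) / 2
  v <- (hi - lo)^2 / 12
  2 * (1 - F) * (m * (1 - m) - v)
}

# pick n_sweeps non-overlapping grid-aligned sweep windows, >= 2 window
# spans apart on a chromosome, away from chromosome ends
choose_sweep_windows <- function(cfg, step_bp = 50000L) {
  if (cfg$n_sweeps == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  w <- cfg$sweep_window_bp
  cand <- do.call(rbind, lapply(seq_len(cfg$n_chrom), function(i) {
    lo <- 1L + w                      # keep one window span off each end
    hi <- cfg$chrom_len_bp - 2L * w
    if (hi < lo) return(NULL)
    starts <- seq.int(lo, hi, by = step_bp)
    data.frame(chrom = paste0("chr", i), start = starts,
               end = starts + w - 1L, stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || nrow(cand) < cfg$n_sweeps)
    stop("sweep windows exceed genome capacity")
  picked <- cand[0, ]
  pool <- cand
  for (k in seq_len(cfg$n_sweeps)) {
    if (!nrow(pool)) stop("sweep windows exceed genome capacity")
    i <- sample.int(nrow(pool), 1L)
    win <- pool[i, , drop = FALSE]
    picked <- rbind(picked, win)
    far <- pool$chrom != win$chrom |
      abs(pool$start - win$start) >= 2L * w
    pool <- pool[far, , drop = FALSE]
  }
  picked <- picked[order(picked$chrom, picked$start), , drop = FALSE]
  rownames(picked) <- NULL
  picked
}

#' Simulate a two-population genotype dataset with planted sweeps
#'
#' Background sites: ancestral ALT frequency p ~ U(0.05, 0.95); each
#' population's frequency is Balding-Nichols,
#' Beta(p (1 - F) / F, (1 - p) (1 - F) / F) with F the background
#' differentiation; diploid genotypes are Binomial(2, population frequency),
#' independent across sites.  Inside each planted sweep window the focal
#' group's frequencies are replaced: most sites are fixed (pushed toward ALT
#' with probability \code{min(1, p + sweep_freq_shift)}), and a calibrated
#' fraction stays polymorphic at rare-variant frequencies (minor allele
#' count 1 or 2), so that the focal group's expected diversity is reduced
#' about \code{sweep_pi_reduction}-fold and its site-frequency spectrum is
#' skewed toward singletons (negative Tajima's D).  The background group is
#' untouched.  All randomness derives from \code{cfg$seed}, with one RNG
#' stream per chromosome; the caller's RNG state is preserved.
#'
#' @param cfg a \code{\link{sim_config}}
#' @param out_prefix optional path prefix; when given, writes
#'   \code{<prefix>.vcf}, \code{<prefix>.popmap.tsv} and
#'   \code{<prefix>.truth.tsv}
#' @return list with \code{gm} (\code{\link{genotype_matrix}}),
#'   \code{popmap} (\code{population_map}), \code{truth} (data.frame of
#'   sweep windows), \code{config}, and (if written) \code{paths}
#' @export
simulate_two_pop_dataset <- function(cfg = sim_config(), out_prefix = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  truth <- with_local_seed(cfg$seed, choose_sweep_windows(cfg))

  sport_ids <- sprintf("sport_%02d", seq_len(cfg$n_sport))
  nonsport_ids <- sprintf("nonsport_%02d", seq_len(cfg$n_nonsport))
  F <- cfg$background_F

  # calibrated share of sweep sites left polymorphic at rare frequencies
  c_sport <- 2L * cfg$n_sport
  f1 <- 1 / c_sport
  f2 <- 2 / c_sport
  e_poly <- 0.7 * 2 * f1 * (1 - f1) + 0.3 * 2 * f2 * (1 - f2)
  p_poly <- min(1, bn_expected_site_pi(F) /
                  (cfg$sweep_pi_reduction * e_poly))

  chrom_parts <- lapply(seq_len(cfg$n_chrom), function(i) {
    ch <- paste0("chr", i)
    with_local_seed(cfg$seed + i, {
      n_sites <- round(cfg$snp_density_per_kb * cfg$chrom_len_bp / 1000)
      pos <- sort(sample.int(cfg$chrom_len_bp, n_sites))
      p_anc <- stats::runif(n_sites, 0.05, 0.95)
      q_sport <- stats::rbeta(n_sites, p_anc * (1 - F) / F,
                              (1 - p_anc) * (1 - F) / F)
      q_non <- stats::rbeta(n_sites, p_anc * (1 - F) / F,
                            (1 - p_anc) * (1 - F) / F)

      tw <- truth[truth$chrom == ch, , drop = FALSE]
      if (nrow(tw)) {
        in_sweep <- rep(FALSE, n_sites)
        for (r in seq_len(nrow(tw)))
          in_sweep <- in_sweep | (pos >= tw$start[r] & pos <= tw$end[r])
        ii <- which(in_sweep)
        if (length(ii)) {
          poly <- stats::runif(length(ii)) < p_poly
          fix_alt <- stats::runif(length(ii)) <
            pmin(1, p_anc[ii] + cfg$sweep_freq_shift)
          rare <- ifelse(stats::runif(length(ii)) < 0.7, f1, f2)
          q_new <- ifelse(poly, rare, ifelse(fix_alt, 1, 0))
          q_sport[ii] <- q_new
        }
      }

      g_sport <- matrix(stats::rbinom(cfg$n_sport * n_sites, 2L,
                                      rep(q_sport, each = cfg$n_sport)),
                        nrow = cfg$n_sport)
      g_non <- matrix(stats::rbinom(cfg$n_nonsport * n_sites, 2L,
                                    rep(q_non, each = cfg$n_nonsport)),
                      nrow = cfg$n_nonsport)
      ref_alt <- matrix(replicate(n_sites,
                                  sample(c("A", "C", "G", "T"), 2L)),
                        nrow = 2L)
      list(
        sites = data.frame(chrom = ch, pos = pos,
                           ref = ref_alt[1, ], alt = ref_alt[2, ],
                           stringsAsFactors = FALSE),
        calls = rbind(g_sport, g_non)
      )
    })
  })

  sites <- do.call(rbind, lapply(chrom_parts, `[[`, "sites"))
  calls <- do.call(cbind, lapply(chrom_parts, `[[`, "calls"))
  gm <- genotype_matrix(calls, c(sport_ids, nonsport_ids), sites)
  popmap <- structure(
    stats::setNames(c(rep("sport", cfg$n_sport),
                      rep("non_sport", cfg$n_nonsport)),
                    c(sport_ids, nonsport_ids)),
    class = "population_map")

  out <- list(gm = gm, popmap = popmap, truth = truth, config = cfg)
  if (!is.null(out_prefix)) {
    paths <- c(vcf = paste0(out_prefix, ".vcf"),
               popmap = paste0(out_prefix, ".popmap.tsv"),
               truth = paste0(out_prefix, ".truth.tsv"))
    write_vcf(gm, paths["vcf"])
    write_tsv(data.frame(sample_id = names(popmap),
                         group = unname(unclass(popmap))),
              paths["popmap"])
    write_tsv(truth, paths["truth"])
    out$paths <- paths
  }
  out
}
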