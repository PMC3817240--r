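# EHH/iHH/iHS and the gene-window selection caller.

test_that("EHH hand examples: core, paired split, all-distinct", {
  # 4 derived carriers split into two identical pairs one SNP to the right:
  # 2 concordant pairs of the 6 -> EHH = 1/3
  H <- rbind(c(1L, 0L, 0L),
             c(1L, 0L, 1L),
             c(1L, 1L, 0L),
             c(1L, 1L, 1L),
             c(0L, 0L, 0L),
             c(0L, 1L, 0L))
  p <- toy_panel(H)
  cu <- ehh(p, 1, "derived")
  expect_equal(cu$right$ehh[1], 1)                 # distance 0
  expect_equal(cu$right$ehh[2], 1 / 3)             # two pairs of 4 carriers
  expect_equal(cu$right$ehh[3], 0)                 # both pairs then split
  # all carriers distinct on the left of column 2 is impossible here, build
  # a direct all-distinct case
  H2 <- rbind(c(1L, 0L, 0L), c(1L, 0L, 1L), c(1L, 1L, 0L), c(0L, 0L, 0L))
  cu2 <- ehh(toy_panel(H2), 1, "derived")
  expect_equal(cu2$right$ehh[3], 0)
  expect_error(ehh(toy_panel(H2), 1, "ancestral"), "fewer than 2")
})

test_that("partition refinement equals the all-pairs brute-force oracle", {
  set.seed(20)
  for (r in 1:10) {
    H <- matrix(rbinom(30 * 15, 1, runif(1, 0.2, 0.8)), nrow = 30)
    core <- sample(2:14, 1)
    p <- toy_panel(H)
    for (al in c(1L, 0L)) {
      if (sum(H[, core] == al) < 2) next
      cu <- ehh(p, core, if (al == 1L) "derived" else "ancestral")
      for (k in seq_len(nrow(cu$right))[-1])
        expect_equal(cu$right$ehh[k],
                     brute_ehh(H, core, al, cu$right$index[k]))
      for (k in seq_len(nrow(cu$left))[-1])
        expect_equal(cu$left$ehh[k],
                     brute_ehh(H, core, al, cu$left$index[k]))
    }
  }
})

test_that("iHH is the floor-truncated trapezoid integral over cM", {
  mk_curve <- function(right, left) {
    structure(list(core_index = 1L, allele = "derived", n_carriers = 4L,
                   right = right, left = left,
                   reached_floor_right = TRUE, reached_floor_left = TRUE,
                   floor = 0.05), class = "ehh_curve")
  }
  # piecewise-linear toy: hand trapezoid sum
  cu <- mk_curve(data.frame(index = 1:3, dist_cM = c(0, 0.1, 0.3),
                            ehh = c(1, 0.6, 0.2)),
                 data.frame(index = 1, dist_cM = 0, ehh = 1))
  hand <- 0.1 * (1 + 0.6) / 2 + 0.2 * (0.6 + 0.2) / 2
  expect_equal(ihh(cu)$value, hand)
  # rectangle: EHH 1 over 2 cM then instant drop below the floor on one side
  cu2 <- mk_curve(data.frame(index = 1:3, dist_cM = c(0, 2, 2.0001),
                             ehh = c(1, 1, 0)),
                  data.frame(index = 1:2, dist_cM = c(0, -1e-4),
                             ehh = c(1, 0)))
  expect_equal(ihh(cu2)$value, 2, tolerance = 1e-3)
  # integration stops after the first sub-floor point
  cu3 <- mk_curve(data.frame(index = 1:3, dist_cM = c(0, 0.1, 0.5),
                             ehh = c(1, 0.02, 0.01)),
                  data.frame(index = 1, dist_cM = 0, ehh = 1))
  expect_equal(ihh(cu3)$value, 0.1 * (1 + 0.02) / 2)
  # zero genetic-map span
  cu4 <- mk_curve(data.frame(index = 1, dist_cM = 0, ehh = 1),
                  data.frame(index = 1, dist_cM = 0, ehh = 1))
  expect_error(ihh(cu4), "zero genetic-map span")
})

test_that("swapping ancestral/derived labels negates uiHS exactly", {
  spec <- simulation_spec(n_haplotypes = 100, n_snps = 200, rng_seed = 23)
  p <- simulate_neutral_panel(spec)
  j <- 100
  a <- ihh(ehh(p, j, "ancestral", floor = 0.05))
  d <- ihh(ehh(p, j, "derived", floor = 0.05))
  # flip the polarity of the core column only
  p2 <- p
  p2$H[, j] <- 1L - p2$H[, j]
  a2 <- ihh(ehh(p2, j, "ancestral", floor = 0.05))
  d2 <- ihh(ehh(p2, j, "derived", floor = 0.05))
  expect_equal(log(a$value / d$value), -log(a2$value / d2$value))
})

test_that("iHS scan output is invariant to haplotype row order and allele
           label swaps that preserve ancestral/derived identity", {
  spec <- simulation_spec(n_haplotypes = 150, n_snps = 250, rng_seed = 24)
  p <- simulate_neutral_panel(spec)
  base <- suppressWarnings(ihs_scan(p))
  set.seed(1)
  p2 <- p
  p2$H <- p2$H[sample(nrow(p2$H)), ]
  expect_equal(suppressWarnings(ihs_scan(p2))$ihs, base$ihs)
  p3 <- p     # strand relabel: ref/alt characters swap, identity unchanged
  p3$variants$ref <- p$variants$alt
  p3$variants$alt <- p$variants$ref
  expect_equal(suppressWarnings(ihs_scan(p3))$ihs, base$ihs)
})

test_that("scan excludes SNPs by MAF (strict), truncation and carrier count", {
  spec <- simulation_spec(n_haplotypes = 100, n_snps = 160, rng_seed = 25)
  p <- simulate_neutral_panel(spec)
  p$H[, 1] <- c(rep(1L, 5), rep(0L, 95))    # maf exactly 0.05: excluded
  sc <- suppressWarnings(ihs_scan(p, maf_min = 0.05))
  expect_equal(sc$reason[1], "maf")
  expect_true(all(is.na(sc$ihs) == !is.na(sc$reason)))
  # per-bin standardisation: mean 0, sd 1 within each bin
  ok <- !is.na(sc$ihs)
  for (b in unique(sc$bin[ok])) {
    i <- ok & sc$bin == b & !is.na(sc$bin)
    if (sum(i) > 2) {
      expect_equal(mean(sc$ihs[i]), 0, tolerance = 1e-10)
      expect_equal(sd(sc$ihs[i]), 1, tolerance = 1e-10)
    }
  }
})

test_that("reference standardisation reproduces own-panel scores and maps
           unseen frequencies to the nearest bin", {
  spec <- simulation_spec(n_haplotypes = 150, n_snps = 300, rng_seed = 26)
  p <- simulate_neutral_panel(spec)
  ref <- suppressWarnings(ihs_scan(p))
  again <- suppressWarnings(ihs_scan(p, standardize = ref))
  expect_equal(again$ihs, ref$ihs)
  expect_error(ihs_scan(p, standardize = data.frame()), "bin statistics")
})

test_that("candidate-locus join applies both thresholds and sorts by |iHS|", {
  fx <- load_snp_evidence_fixture()
  assoc <- data.frame(id = fx$snp, or_ = fx$or_, l95 = fx$l95, u95 = fx$u95,
                      p = fx$p)
  ihs <- data.frame(id = fx$snp, ihs = fx$ihs_asn)
  sel <- select_candidate_loci(ihs, assoc, ihs_threshold = 1.65, alpha = 0.05)
  # 26 of the 27 published rows exceed 1.65 strictly; rs6958497 sits at 1.647
  expect_equal(nrow(sel), 26)
  expect_false("rs6958497" %in% sel$id)
  sel2 <- select_candidate_loci(ihs, assoc, ihs_threshold = 2.0, alpha = 0.05)
  expect_true("rs17172432" %in% sel2$id)
  expect_equal(sel2$id[1], "rs17172432")        # maximum |iHS| first
  expect_equal(abs(sel2$ihs[1]), 2.967)
  none <- select_candidate_loci(ihs, assoc, ihs_threshold = 10, alpha = 0.05)
  expect_equal(nrow(none), 0)
})

test_that("gene-window caller flags only the extreme window on a hand toy", {
  # five chromosomes of 10 scored SNPs each -> window counts {0, 0, 1, 2, 7}
  n_sig <- c(0, 0, 1, 2, 7)
  rows <- do.call(rbind, lapply(1:5, function(ch) {
    ihs <- rep(0.5, 10)
    if (n_sig[ch] > 0) ihs[seq_len(n_sig[ch])] <- 3
    data.frame(id = sprintf("c%d_%d", ch, 1:10), chrom = as.character(ch),
               pos_bp = (1:10) * 1000, ihs = ihs)
  }))
  genes <- data.frame(name = paste0("G", 1:5), chrom = as.character(1:5),
                      start_bp = 4000, end_bp = 6000)
  gw <- gene_window_scan(rows, genes, window_snps = 10, sig_threshold = 2,
                         upper_fraction = 0.10)
  expect_equal(attr(gw, "window_counts")[order(attr(gw, "window_counts"))],
               c(0, 0, 1, 2, 7))
  expect_equal(gw$candidate, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(gw$n_sig, n_sig)
  expect_equal(gw$fraction[5], 0.2)     # 1 of 5 windows reaches count 7
  expect_false(any(gw$short_window))
})

test_that("without any significant SNP no gene is called a candidate", {
  rows <- data.frame(id = sprintf("s%d", 1:100), chrom = "1",
                     pos_bp = (1:100) * 1000, ihs = rnorm(100, 0, 0.5))
  rows$ihs <- pmin(pmax(rows$ihs, -1.9), 1.9)
  genes <- data.frame(name = "G", chrom = "1", start_bp = 40000,
                      end_bp = 60000)
  gw <- gene_window_scan(rows, genes, window_snps = 50, sig_threshold = 2)
  expect_equal(gw$n_sig, 0L)
  expect_false(gw$candidate)
})

test_that("chromosomes shorter than the window are used whole and flagged", {
  rows <- data.frame(id = sprintf("s%d", 1:20), chrom = "1",
                     pos_bp = (1:20) * 1000, ihs = c(rep(3, 5), rep(0, 15)))
  genes <- data.frame(name = "G", chrom = "1", start_bp = 9000,
                      end_bp = 11000)
  gw <- gene_window_scan(rows, genes, window_snps = 50, sig_threshold = 2)
  expect_true(gw$short_window)
  expect_equal(gw$n_window, 20L)
  expect_equal(gw$n_sig, 5L)
})

test_that("stronger sweeps never become less detectable (20 seeds)", {
  core_z <- function(panel, co, ref) {
    ia <- ihh(ehh(panel, co, "ancestral", floor = 0.05))
    id <- ihh(ehh(panel, co, "derived", floor = 0.05))
    if (ia$truncated || id$truncated) return(c(NA, NA))
    bs <- attr(ref, "bin_stats")
    b <- findInterval(mean(panel$H[, co]),
                      seq(0, 1, by = attr(ref, "bin_width")),
                      rightmost.closed = TRUE)
    k <- which.min(abs(bs$bin - b))
    c(abs((log(ia$value / id$value) - bs$mean[k]) / bs$sd[k]), id$value)
  }
  freqs <- c(0.3, 0.6, 0.8)
  res <- vapply(1:20, function(s) {
    sp <- simulation_spec(n_haplotypes = 300, n_snps = 1500, rng_seed = 100 + s)
    pp <- simulate_neutral_panel(sp)
    ref <- suppressWarnings(ihs_scan(pp))
    d <- colMeans(pp$H)
    co <- which(d > 0.12 & d < 0.18 &
                  seq_along(d) > 400 & seq_along(d) < 1100)[5]
    vapply(freqs, function(f)
      core_z(simulate_sweep(pp, co, f, seed = 100 + s), co, ref),
      numeric(2))
  }, matrix(0, 2, 3))
  z <- t(res[1, , ])            # 20 x 3 standardised scores
  ihh_d <- t(res[2, , ])        # 20 x 3 raw derived-class iHH
  med <- apply(z, 2, median, na.rm = TRUE)
  expect_gt(med[2], med[1])                        # 0.3 -> 0.6: strict rise
  expect_gte(med[3], med[2] * 0.98)                # 0.6 -> 0.8: no real drop
  # the raw haplotype-length signal grows with final frequency per seed
  expect_gte(mean(ihh_d[, 2] >= ihh_d[, 1], na.rm = TRUE), 0.9)
  expect_gte(mean(ihh_d[, 3] >= ihh_d[, 2], na.rm = TRUE), 0.9)
})
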