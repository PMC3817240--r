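# Ground-truth generator: determinism, LD structure, sweep construction,
# disease-model calibration and expression effects.

test_that("every generator operation is deterministic under rng_seed", {
  spec <- simulation_spec(n_haplotypes = 60, n_snps = 80,
                          causal_snps = data.frame(index = 3, log_odds = 0.4),
                          cis_pairs = data.frame(snp = 3, probe = 1, beta = 1,
                                                 noise_sd = 0.5),
                          n_probes = 3, rng_seed = 9)
  a <- simulate_neutral_panel(spec)
  b <- simulate_neutral_panel(spec)
  expect_identical(a$H, b$H)
  sa <- simulate_phenotype(a, spec)
  sb <- simulate_phenotype(b, spec)
  expect_identical(sa$phenotype, sb$phenotype)
  expect_identical(sa$covariates$age, sb$covariates$age)
  ea <- simulate_expression(sa, spec)
  eb <- simulate_expression(sb, spec)
  expect_identical(ea$E, eb$E)
  expect_identical(simulate_sweep(a, 40, 0.8, seed = 9)$H,
                   simulate_sweep(b, 40, 0.8, seed = 9)$H)
})

test_that("one founder and no mutation yields identical haplotypes", {
  spec <- simulation_spec(n_haplotypes = 30, n_snps = 50, n_founders = 1,
                          mutation_flip_prob = 0, rng_seed = 2)
  p <- simulate_neutral_panel(spec)
  expect_true(all(apply(p$H, 2, function(col) length(unique(col)) == 1L)))
})

test_that("descendant allele frequencies track founder frequencies (2000 x 2000)", {
  spec <- simulation_spec(n_haplotypes = 2000, n_snps = 2000, rng_seed = 12)
  p <- simulate_neutral_panel(spec)
  expect_true(max(abs(colMeans(p$H) - attr(p, "founder_freq"))) < 0.05)
})

test_that("sweep construction: frequency contract, degenerate EHH, errors", {
  spec <- simulation_spec(n_haplotypes = 200, n_snps = 120, rng_seed = 4)
  p <- simulate_neutral_panel(spec)
  core <- which(colMeans(p$H) > 0.2 & colMeans(p$H) < 0.5)[1]
  f0 <- mean(p$H[, core])
  # target equal to current frequency: unchanged
  expect_identical(simulate_sweep(p, core, f0, seed = 4)$H, p$H)
  # below current frequency: error
  expect_error(simulate_sweep(p, core, f0 / 2, seed = 4), "below")
  # frequency calibration
  sw <- simulate_sweep(p, core, 0.7, seed = 4)
  expect_equal(mean(sw$H[, core]), 0.7, tolerance = 0.01)
  # degenerate hard sweep: no escape, no mutation -> derived class is one
  # haplotype, so EHH_D = 1 at every distance in both directions
  sw0 <- simulate_sweep(p, core, 0.7, flip_prob = 0, escape_cM = 0, seed = 4)
  cu <- ehh(sw0, core, "derived")
  expect_true(all(cu$left$ehh == 1) && all(cu$right$ehh == 1))
  expect_equal(nrow(cu$right), ncol(p$H) - core + 1L)
})

test_that("disease-model intercept calibrates the marginal prevalence", {
  spec <- simulation_spec(n_haplotypes = 10000, n_snps = 20,
                          causal_snps = data.frame(index = 1:2,
                                                   log_odds = c(0.5, -0.4)),
                          baseline_prevalence = 0.5, rng_seed = 21)
  p <- simulate_neutral_panel(spec)
  st <- simulate_phenotype(p, spec)
  gt <- attr(st, "ground_truth")
  # deterministic part of the contract: the solved linear predictor's mean
  eta <- gt$intercept + 0.03 * (st$covariates$age - 65) +
    0.5 * st$G[, 1] - 0.4 * st$G[, 2]
  expect_lt(abs(mean(plogis(eta)) - 0.5), 0.01)
  # realised case fraction at n = 5000
  expect_lt(abs(mean(st$phenotype) - 0.5), 0.02)
})

test_that("null generator gives uniform association p over replicates", {
  # no causal SNPs: chi-square/Wald p at one SNP across replicates ~ U(0,1)
  ps <- vapply(1:200, function(r) {
    set.seed(r)
    g <- rbinom(300, 2, 0.3)
    age <- rnorm(300, 65, 8)
    spec <- simulation_spec(n_haplotypes = 600, n_snps = 1, rng_seed = r)
    st <- simulate_phenotype(list(G = matrix(as.integer(g)),
                                  variants = variant_table("s1", "1", 1000),
                                  sample_ids = sprintf("S%03d", 1:300)), spec)
    fit_snp_logistic(st, 1)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.10)
})

test_that("fitted OR covers the generating OR at the nominal rate", {
  # log-odds ln(0.673) at one SNP, n = 5000: the fitted 95% CI should
  # contain the true OR in >= 93% of 200 replicates
  lo <- log(0.673)
  covered <- vapply(1:200, function(r) {
    set.seed(1000 + r)
    g <- rbinom(5000, 2, 0.25)
    spec <- simulation_spec(n_haplotypes = 10000, n_snps = 1,
                            causal_snps = data.frame(index = 1, log_odds = lo),
                            rng_seed = 1000 + r)
    st <- simulate_phenotype(list(G = matrix(as.integer(g)),
                                  variants = variant_table("s1", "1", 1000),
                                  sample_ids = sprintf("S%04d", 1:5000)), spec)
    rec <- fit_snp_logistic(st, 1)
    rec$l95 <= 0.673 && 0.673 <= rec$u95
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("expression generator places cis pairs inside 1 Mb and others beyond", {
  spec <- simulation_spec(n_haplotypes = 200, n_snps = 50, n_probes = 6,
                          cis_pairs = data.frame(snp = c(10, 20),
                                                 probe = c(1, 2),
                                                 beta = c(1, 0.5),
                                                 noise_sd = c(0.5, 0.5)),
                          rng_seed = 31)
  p <- simulate_neutral_panel(spec)
  st <- simulate_phenotype(p, spec)
  ex <- simulate_expression(st, spec)
  lab <- classify_cis_trans(st$variants$chrom[c(10, 20)],
                            st$variants$pos_bp[c(10, 20)],
                            ex$probes$chrom[1:2], ex$probes$pos_bp[1:2])
  expect_equal(lab, c("cis", "cis"))
  # unpaired probes are beyond 1 Mb of every SNP
  for (pr in 3:6)
    expect_true(all(classify_cis_trans(st$variants$chrom,
                                       st$variants$pos_bp,
                                       ex$probes$chrom[pr],
                                       ex$probes$pos_bp[pr]) == "trans"))
})

test_that("a designated strong cis effect dominates its SNP's associations", {
  spec <- simulation_spec(n_haplotypes = 200, n_snps = 50, n_probes = 8,
                          cis_pairs = data.frame(snp = 25, probe = 1, beta = 1,
                                                 noise_sd = 0.1),
                          rng_seed = 34)
  p <- simulate_neutral_panel(spec)
  st <- simulate_phenotype(p, spec)
  ex <- simulate_expression(st, spec)
  ps <- vapply(1:8, function(pr) eqtl_test(st$G[, 25], ex$E[pr, ])$p,
               numeric(1))
  expect_equal(which.min(ps), 1L)
  expect_lt(ps[1], 1e-20)
})

test_that("with beta = 0 everywhere the eQTL hit rate is near alpha", {
  spec <- simulation_spec(n_haplotypes = 200, n_snps = 100, n_probes = 2,
                          rng_seed = 35)
  p <- simulate_neutral_panel(spec)
  st <- simulate_phenotype(p, spec)
  ex <- simulate_expression(st, spec)   # all probes pure noise
  tab <- eqtl_scan(st, ex)
  hits <- mean(tab$p_nominal < 0.05, na.rm = TRUE)
  # 200 tests at alpha .05: binomial 95% band around .05
  expect_lt(abs(hits - 0.05), 1.96 * sqrt(0.05 * 0.95 / nrow(tab)) + 1e-9)
})

test_that("write_simulation emits a consistent file set", {
  dir <- withr::local_tempdir()
  spec <- simulation_spec(n_haplotypes = 40, n_snps = 60,
                          sweep_core_index = 30, sweep_final_freq = 0.7,
                          causal_snps = data.frame(index = 30, log_odds = 0.5),
                          cis_pairs = data.frame(snp = 30, probe = 1, beta = 1,
                                                 noise_sd = 0.5),
                          n_probes = 2, rng_seed = 77)
  out <- write_simulation(spec, dir)
  panel2 <- add_genetic_map(read_vcf(file.path(dir, "panel.vcf")),
                            read_genetic_map(file.path(dir, "map.txt")))
  expect_identical(panel2$H, out$panel$H)
  ph <- read_phenotype_tsv(file.path(dir, "phenotype.tsv"))
  expect_equal(ph$status, out$study$phenotype)
  ex <- read_expression_tsv(file.path(dir, "expression.tsv"))
  expect_equal(ex$E[1, ], out$expression$E[1, ], tolerance = 1e-5,
               ignore_attr = TRUE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$sweep_core_index, 30)
})
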