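# Simulator with known ground truth: mosaic-LD haplotype panels, imposed
# selective sweeps, a logistic disease model with an age covariate, and
# additive cis effects on probe expression.
#
# All operations are deterministic given spec$rng_seed. Each operation uses
# its own derived seed (seed + a fixed offset) so e.g. regenerating the
# phenotype does not depend on whether a sweep was imposed first.

.seed_offsets <- c(panel = 0L, sweep = 11L, phenotype = 23L, expression = 37L)

.derived_seed <- function(seed, what) {
  (as.integer(seed) + .seed_offsets[[what]]) %% 2147483647L
}

#' Simulation specification
#'
#' Bundles every knob of the ground-truth generator. Defaults describe the
#' emulated study: a panel of unrelated chromosomes with block LD
#' (25 founders copied in 25-SNP mosaic blocks, per-site copy-flip
#' probability 0.005), SNPs every 2 kb under a constant 1 cM/Mb map, ages
#' N(65, 8) entering the disease model with the fixed coefficient 0.03 per
#' year, and a 50% baseline case fraction (the calibration contract's worked
#' value; the emulated cohort itself is ~58% cases).
#'
#' @param n_haplotypes even number of haplotypes (2 per sample).
#' @param n_snps SNPs on the single simulated chromosome.
#' @param n_founders founder haplotypes for the mosaic copying model.
#' @param mosaic_block_len SNPs per copying block.
#' @param mutation_flip_prob per-site allele flip probability when copying.
#' @param founder_freq_range derived-allele frequency range for founders.
#' @param bp_spacing physical spacing between adjacent SNPs (bp).
#' @param cm_per_mb constant genetic-map rate.
#' @param chrom chromosome label.
#' @param sweep_core_index,sweep_final_freq optional imposed sweep: core SNP
#'   column and target derived-allele frequency.
#' @param sweep_flip_prob per-site, per-SNP-step mutation rate on sweep
#'   copies. The sweep is recent relative to the standing variation, so this
#'   is an order of magnitude below `mutation_flip_prob`: the sweep lineage
#'   keeps long shared haplotypes against the neutral background.
#' @param causal_snps data.frame with columns `index`, `log_odds` (per-copy
#'   log odds ratios of the derived allele), or NULL for a null model.
#' @param baseline_prevalence target marginal case fraction.
#' @param age_mean,age_sd age distribution; `age_coef` is the fixed log-odds
#'   per year of age.
#' @param n_probes expression probes; `cis_pairs` is a data.frame with
#'   columns `snp`, `probe`, `beta`, `noise_sd` designating additive cis
#'   effects (other probes are pure noise).
#' @param rng_seed integer seed governing all four generator operations.
#' @return a list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_haplotypes, n_snps, n_founders = 25L,
                            mosaic_block_len = 25L,
                            mutation_flip_prob = 0.005,
                            founder_freq_range = c(0.05, 0.95),
                            bp_spacing = 2000L, cm_per_mb = 1,
                            chrom = "1",
                            sweep_core_index = NULL, sweep_final_freq = NULL,
                            sweep_flip_prob = 5e-4,
                            causal_snps = NULL, baseline_prevalence = 0.5,
                            age_mean = 65, age_sd = 8, age_coef = 0.03,
                            n_probes = NULL, cis_pairs = NULL,
                            rng_seed = 1L) {
  stopifnot(n_haplotypes %% 2 == 0, n_haplotypes >= 2, n_snps >= 1,
            n_founders >= 1, mosaic_block_len >= 1,
            mutation_flip_prob >= 0, mutation_flip_prob < 1,
            length(founder_freq_range) == 2,
            founder_freq_range[1] > 0, founder_freq_range[2] < 1,
            baseline_prevalence > 0, baseline_prevalence < 1,
            age_sd > 0, bp_spacing >= 1, cm_per_mb > 0)
  if (!is.null(sweep_core_index))
    stopifnot(sweep_core_index >= 1, sweep_core_index <= n_snps,
              !is.null(sweep_final_freq),
              sweep_final_freq > 0, sweep_final_freq < 1)
  if (!is.null(causal_snps))
    stopifnot(all(c("index", "log_odds") %in% names(causal_snps)),
              all(causal_snps$index >= 1), all(causal_snps$index <= n_snps))
  if (!is.null(cis_pairs)) {
    stopifnot(all(c("snp", "probe", "beta", "noise_sd") %in% names(cis_pairs)),
              all(cis_pairs$snp >= 1), all(cis_pairs$snp <= n_snps))
    if (is.null(n_probes)) n_probes <- max(cis_pairs$probe)
    stopifnot(all(cis_pairs$probe >= 1), all(cis_pairs$probe <= n_probes))
  }
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 n_snps = as.integer(n_snps),
                 n_founders = as.integer(n_founders),
                 mosaic_block_len = as.integer(mosaic_block_len),
                 mutation_flip_prob = mutation_flip_prob,
                 founder_freq_range = founder_freq_range,
                 bp_spacing = as.integer(bp_spacing), cm_per_mb = cm_per_mb,
                 chrom = as.character(chrom),
                 sweep_core_index = sweep_core_index,
                 sweep_final_freq = sweep_final_freq,
                 sweep_flip_prob = sweep_flip_prob,
                 causal_snps = causal_snps,
                 baseline_prevalence = baseline_prevalence,
                 age_mean = age_mean, age_sd = age_sd, age_coef = age_coef,
                 n_probes = n_probes, cis_pairs = cis_pairs,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_spec")
}

#' Simulate a neutral haplotype panel with block LD
#'
#' Founder haplotypes are drawn with per-SNP derived-allele frequencies
#' uniform on `founder_freq_range`; each descendant haplotype is a mosaic of
#' founder blocks (`mosaic_block_len` SNPs each, founder chosen uniformly per
#' block) with per-site flips at `mutation_flip_prob`. The realised founder
#' allele frequencies are stored in the attribute `founder_freq`.
#'
#' @param spec a [simulation_spec()].
#' @return a [haplotype_panel()] with the genetic map attached at
#'   `cm_per_mb`.
#' @export
simulate_neutral_panel <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(.derived_seed(spec$rng_seed, "panel"))
  M <- spec$n_snps
  n <- spec$n_haplotypes
  p <- runif(M, spec$founder_freq_range[1], spec$founder_freq_range[2])
  founders <- matrix(rbinom(spec$n_founders * M, 1L, rep(p, each = spec$n_founders)),
                     nrow = spec$n_founders, ncol = M)
  n_blocks <- ceiling(M / spec$mosaic_block_len)
  choice <- matrix(sample.int(spec$n_founders, n * n_blocks, replace = TRUE),
                   nrow = n)
  H <- matrix(0L, nrow = n, ncol = M)
  for (b in seq_len(n_blocks)) {
    cols <- ((b - 1L) * spec$mosaic_block_len + 1L):min(b * spec$mosaic_block_len, M)
    H[, cols] <- founders[choice[, b], cols, drop = FALSE]
  }
  if (spec$mutation_flip_prob > 0) {
    flips <- matrix(runif(n * M) < spec$mutation_flip_prob, nrow = n)
    H[flips] <- 1L - H[flips]
  }
  pos <- seq_len(M) * spec$bp_spacing
  v <- variant_table(id = sprintf("snp%05d", seq_len(M)), chrom = spec$chrom,
                     pos_bp = pos, map_cM = pos * spec$cm_per_mb / 1e6)
  out <- haplotype_panel(H, v)
  attr(out, "founder_freq") <- colMeans(founders)
  out
}

#' Impose a selective sweep on a haplotype panel
#'
#' Emulates a hard sweep by haplotype replication with recombination escape:
#' one derived-allele-carrying haplotype at the core SNP is chosen as the
#' sweep lineage. Every other derived carrier, and enough randomly chosen
#' ancestral carriers to bring the derived frequency at the core up to
#' `final_freq`, are overwritten by a copy of that lineage -- but only
#' between two recombination breakpoints drawn per copy at exponentially
#' distributed genetic distances from the core (mean `escape_cM`); outside
#' its breakpoints each recipient keeps its own background haplotype.
#' Copied segments additionally receive fresh point mutations at rate
#' `flip_prob` per site (never at the core). Haplotype homozygosity of the
#' derived class therefore decays with genetic distance, as after a real
#' sweep, while distant regions are untouched.
#'
#' By default `escape_cM` scales with the logistic growth rate implied by
#' `final_freq`: a sweep observed at higher frequency (same age) was
#' stronger, so its copies carry longer unbroken haplotypes. With
#' `escape_cM = 0` and `flip_prob = 0` all derived carriers at the core end
#' up sharing one haplotype chromosome-wide (EHH of the derived class is 1
#' at all distances). With `final_freq` equal to the current frequency the
#' panel is returned unchanged.
#'
#' @param panel a [haplotype_panel()] with genetic map attached.
#' @param core_index column index of the (polymorphic) core SNP.
#' @param final_freq target derived-allele frequency at the core; must be at
#'   least the current frequency.
#' @param flip_prob per-site mutation rate on copied segments.
#' @param escape_cM mean recombination-escape distance (cM) each side of the
#'   core; `NULL` = 0.25 cM at `final_freq` 0.5, scaled by the implied
#'   growth rate.
#' @param seed optional seed (defaults to the current RNG state).
#' @return the modified panel.
#' @export
simulate_sweep <- function(panel, core_index, final_freq, flip_prob = 5e-4,
                           escape_cM = NULL, seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!is.null(seed)) set.seed(.derived_seed(seed, "sweep"))
  H <- panel$H
  n <- nrow(H)
  M <- ncol(H)
  cm <- panel$variants$map_cM
  if (anyNA(cm)) stop("genetic map not attached")
  carriers <- which(H[, core_index] == 1L)
  f0 <- length(carriers) / n
  if (f0 == 0 || f0 == 1) stop("core SNP is monomorphic")
  n_target <- round(final_freq * n)
  if (n_target < length(carriers))
    stop("final_freq ", final_freq, " is below the current core frequency ",
         signif(f0, 4))
  if (n_target == length(carriers)) return(panel)
  if (is.null(escape_cM)) {
    # stronger sweeps reach higher frequency in the same time and carry
    # disproportionately longer unbroken haplotypes; the quadratic scaling
    # reproduces the qualitative rise of sweep detectability with derived
    # frequency seen in real scans
    growth <- log(final_freq / (1 - final_freq)) + log(n)
    escape_cM <- 0.25 * (max(growth, log(2)) / log(n))^2
  }
  donor_row <- sample(carriers, 1L)
  donor <- H[donor_row, ]
  recipients <- c(setdiff(carriers, donor_row),
                  sample(setdiff(seq_len(n), carriers),
                         n_target - length(carriers)))
  for (i in recipients) {
    if (escape_cM > 0) {
      lo <- cm[core_index] - rexp(1L, 1 / escape_cM)
      hi <- cm[core_index] + rexp(1L, 1 / escape_cM)
      seg <- which(cm >= lo & cm <= hi)
    } else {
      seg <- seq_len(M)
    }
    hap <- H[i, ]
    hap[seg] <- donor[seg]
    if (flip_prob > 0) {
      fl <- seg[runif(length(seg)) < flip_prob]
      fl <- fl[fl != core_index]
      hap[fl] <- 1L - hap[fl]
    }
    hap[core_index] <- 1L
    H[i, ] <- hap
  }
  panel$H <- H
  panel
}

#' Simulate a case/control phenotype over a panel or dosage substrate
#'
#' Linear predictor: `intercept + sum(log_odds * derived dosage) +
#' age_coef * (age - age_mean)`; status drawn Bernoulli(logistic(.)). The
#' intercept is solved numerically so the marginal prevalence matches
#' `baseline_prevalence` to within 0.01.
#'
#' @param x a [haplotype_panel()] or a list with elements `G`, `variants`,
#'   `sample_ids` (as from `read_vcf(..., require_phased = FALSE)`).
#' @param spec a [simulation_spec()] supplying causal SNPs, the age model and
#'   the seed.
#' @return a [genotype_study()]; the attribute `ground_truth` records the
#'   causal indices, log odds and solved intercept.
#' @export
simulate_phenotype <- function(x, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(.derived_seed(spec$rng_seed, "phenotype"))
  if (inherits(x, "haplotype_panel")) {
    n <- length(x$sample_ids)
    G <- x$H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
      x$H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
    v <- x$variants
    v$effect <- ifelse(v$ancestral == "ref", "alt", "ref")
    ids <- x$sample_ids
  } else {
    G <- x$G
    v <- x$variants
    if (is.null(v$effect)) v$effect <- "alt"
    ids <- x$sample_ids
  }
  n <- nrow(G)
  age <- rnorm(n, spec$age_mean, spec$age_sd)
  eta <- spec$age_coef * (age - spec$age_mean)
  if (!is.null(spec$causal_snps))
    for (k in seq_len(nrow(spec$causal_snps)))
      eta <- eta + spec$causal_snps$log_odds[k] * G[, spec$causal_snps$index[k]]
  f <- function(c0) mean(plogis(c0 + eta)) - spec$baseline_prevalence
  sol <- tryCatch(uniroot(f, c(-30, 30), tol = 1e-10),
                  error = function(e) stop("prevalence ",
                                           spec$baseline_prevalence,
                                           " unattainable: ", conditionMessage(e)))
  status <- rbinom(n, 1L, plogis(sol$root + eta))
  out <- genotype_study(G, v, status, data.frame(age = age), ids)
  attr(out, "ground_truth") <- list(causal_snps = spec$causal_snps,
                                    intercept = sol$root,
                                    target_prevalence = spec$baseline_prevalence)
  out
}

#' Simulate probe expression with designated additive cis effects
#'
#' For each designated pair, `E[probe, ] = beta * dosage + N(0, noise_sd)`;
#' all other probes are standard-normal noise. Paired probes are placed on
#' the SNP's chromosome within 1 Mb of it; unpaired probes are placed beyond
#' 1 Mb of every SNP, so the designated pairs (and only they) are labelled
#' cis downstream.
#'
#' @param study a [genotype_study()].
#' @param spec a [simulation_spec()] with `cis_pairs` / `n_probes`.
#' @return an [expression_matrix()]; attribute `ground_truth` records the
#'   pairs.
#' @export
simulate_expression <- function(study, spec) {
  stopifnot(inherits(study, "genotype_study"), inherits(spec, "simulation_spec"))
  set.seed(.derived_seed(spec$rng_seed, "expression"))
  P <- if (is.null(spec$n_probes)) 10L else as.integer(spec$n_probes)
  n <- nrow(study$G)
  E <- matrix(rnorm(P * n), nrow = P)
  pos <- integer(P)
  chrom <- rep(study$variants$chrom[1], P)
  far <- max(study$variants$pos_bp) + 2e6
  pos <- as.integer(far + seq_len(P) * 1e4)   # default: trans to every SNP
  if (!is.null(spec$cis_pairs)) {
    for (k in seq_len(nrow(spec$cis_pairs))) {
      pr <- spec$cis_pairs$probe[k]
      sn <- spec$cis_pairs$snp[k]
      g <- study$G[, sn]
      E[pr, ] <- spec$cis_pairs$beta[k] * g +
        rnorm(n, 0, spec$cis_pairs$noise_sd[k])
      chrom[pr] <- study$variants$chrom[sn]
      pos[pr] <- as.integer(study$variants$pos_bp[sn] +
                              sample(-9e5:9e5, 1L))
      if (pos[pr] < 1L) pos[pr] <- 1L
    }
  }
  out <- expression_matrix(E,
                           probes = data.frame(probe = sprintf("probe%04d", seq_len(P)),
                                               chrom = chrom, pos_bp = pos,
                                               stringsAsFactors = FALSE),
                           sample_ids = study$sample_ids)
  attr(out, "ground_truth") <- spec$cis_pairs
  out
}

#' Generate a full synthetic study and write it to disk
#'
#' Runs the generator end to end (panel, optional sweep, phenotype,
#' expression) and writes `panel.vcf`, `map.txt`, `phenotype.tsv`,
#' `expression.tsv`, `genes.bed` (one gene spanning the sweep neighbourhood
#' plus one distal gene) and `truth.json` into `dir`.
#'
#' @param spec a [simulation_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects.
#' @export
write_simulation <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  panel <- simulate_neutral_panel(spec)
  if (!is.null(spec$sweep_core_index))
    panel <- simulate_sweep(panel, spec$sweep_core_index,
                            spec$sweep_final_freq,
                            flip_prob = spec$sweep_flip_prob,
                            seed = spec$rng_seed)
  study <- simulate_phenotype(panel, spec)
  expr <- if (!is.null(spec$cis_pairs)) simulate_expression(study, spec) else NULL

  write_vcf(panel, file.path(dir, "panel.vcf"))
  v <- panel$variants
  write.table(data.frame(chrom = v$chrom, id = v$id, cM = v$map_cM,
                         bp = v$pos_bp),
              file.path(dir, "map.txt"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = study$sample_ids, status = study$phenotype,
                         age = round(study$covariates$age, 2)),
              file.path(dir, "phenotype.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(expr)) {
    tab <- data.frame(probe = expr$probes$probe, chrom = expr$probes$chrom,
                      pos = expr$probes$pos_bp, round(expr$E, 6),
                      check.names = FALSE)
    names(tab)[-(1:3)] <- expr$sample_ids
    write.table(tab, file.path(dir, "expression.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(causal_snps = spec$causal_snps,
                            sweep_core_index = spec$sweep_core_index,
                            sweep_final_freq = spec$sweep_final_freq,
                            cis_pairs = spec$cis_pairs,
                            rng_seed = spec$rng_seed),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(list(panel = panel, study = study, expression = expr))
}
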