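# Domain containers, coordinate conventions and readers/writers.
#
# Conventions: all coordinates are 1-based inclusive except BED input (0-based
# half-open, converted on read); haplotype matrices are coded 0 = ancestral /
# 1 = derived; dosage matrices count copies of the designated effect allele.

## ---- containers -------------------------------------------------------

#' Variant table constructor/validator
#'
#' A variant table is a data.frame with one row per biallelic SNP and columns
#' `id`, `chrom`, `pos_bp` (1-based), `ref`, `alt`, `ancestral` (one of
#' `"ref"`, `"alt"`, `"unknown"`), `map_cM` (may be `NA` until a genetic map
#' is attached) and `ancestral_inferred` (TRUE when the ancestral state was
#' filled in as the major allele rather than read from annotation).
#'
#' @param id,chrom,pos_bp,ref,alt,ancestral,map_cM,ancestral_inferred column
#'   vectors, recycled where length 1.
#' @return a validated `data.frame`.
#' @export
variant_table <- function(id, chrom, pos_bp, ref = "A", alt = "G",
                          ancestral = "ref", map_cM = NA_real_,
                          ancestral_inferred = FALSE) {
  v <- data.frame(id = as.character(id), chrom = as.character(chrom),
                  pos_bp = as.integer(pos_bp), ref = ref, alt = alt,
                  ancestral = ancestral, map_cM = as.numeric(map_cM),
                  ancestral_inferred = ancestral_inferred,
                  stringsAsFactors = FALSE)
  validate_variants(v)
  v
}

validate_variants <- function(v) {
  stopifnot(is.data.frame(v),
            all(c("id", "chrom", "pos_bp", "ref", "alt", "ancestral",
                  "map_cM") %in% names(v)))
  if (any(v$pos_bp < 1L)) stop("pos_bp must be >= 1")
  if (!all(v$ancestral %in% c("ref", "alt", "unknown")))
    stop("ancestral must be 'ref', 'alt' or 'unknown'")
  for (ch in unique(v$chrom)) {
    i <- v$chrom == ch & !is.na(v$map_cM)
    o <- order(v$pos_bp[i])
    if (is.unsorted(v$map_cM[i][o]))
      stop("map_cM must be non-decreasing with pos_bp within chromosome ", ch)
  }
  invisible(v)
}

#' Phased haplotype panel
#'
#' @param H 2N x M binary matrix (rows = haplotypes, two consecutive rows per
#'   sample; columns = SNPs), entry 1 = derived allele.
#' @param variants variant table (see [variant_table()]), one row per column.
#' @param sample_ids length-N character vector.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(H, variants, sample_ids = NULL) {
  H <- as.matrix(H)
  storage.mode(H) <- "integer"
  if (nrow(H) %% 2L != 0L) stop("haplotype count must be even (phased pairs)")
  if (ncol(H) != nrow(variants))
    stop("column count must equal number of variants")
  if (!all(H %in% c(0L, 1L))) stop("haplotype entries must be 0/1")
  validate_variants(variants)
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%04d", seq_len(nrow(H) / 2L))
  if (length(sample_ids) != nrow(H) / 2L)
    stop("need one sample id per haplotype pair")
  structure(list(H = H, variants = variants,
                 sample_ids = as.character(sample_ids)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("Phased haplotype panel:", nrow(x$H), "haplotypes (",
      length(x$sample_ids), "samples ) x", ncol(x$H), "SNPs\n")
  cat("  chromosome(s):", paste(unique(x$variants$chrom), collapse = ", "),
      "; bp span:", min(x$variants$pos_bp), "-", max(x$variants$pos_bp), "\n")
  if (any(is.na(x$variants$map_cM)))
    cat("  genetic map: not attached\n")
  else
    cat("  genetic map:", round(diff(range(x$variants$map_cM)), 3), "cM\n")
  invisible(x)
}

#' Unphased case-control genotype study
#'
#' @param G N x M dosage matrix counting copies of the effect allele
#'   (0/1/2/NA).
#' @param variants variant table with an `effect` column naming the counted
#'   allele (`"ref"` or `"alt"`).
#' @param phenotype binary 0/1 vector (1 = case).
#' @param covariates data.frame of per-sample numeric covariates; must contain
#'   `age`.
#' @param sample_ids character ids aligned with rows of `G`.
#' @return an object of class `genotype_study`.
#' @export
genotype_study <- function(G, variants, phenotype, covariates,
                           sample_ids = NULL) {
  G <- as.matrix(G)
  storage.mode(G) <- "integer"
  if (!all(G %in% c(0L, 1L, 2L, NA))) stop("dosages must be 0/1/2 or NA")
  if (ncol(G) != nrow(variants)) stop("dimension mismatch: G vs variants")
  phenotype <- as.integer(phenotype)
  if (!all(phenotype %in% c(0L, 1L))) stop("phenotype must be 0/1")
  if (length(phenotype) != nrow(G)) stop("dimension mismatch: phenotype")
  covariates <- as.data.frame(covariates)
  if (!"age" %in% names(covariates)) stop("covariates must include 'age'")
  if (nrow(covariates) != nrow(G)) stop("dimension mismatch: covariates")
  validate_variants(variants)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(nrow(G)))
  structure(list(G = G, variants = variants, phenotype = phenotype,
                 covariates = covariates,
                 sample_ids = as.character(sample_ids),
                 missing_frac = colMeans(is.na(G))),
            class = "genotype_study")
}

#' @export
print.genotype_study <- function(x, ...) {
  cat("Case-control genotype study:", nrow(x$G), "samples x", ncol(x$G),
      "SNPs\n")
  cat("  cases:", sum(x$phenotype == 1L), " controls:",
      sum(x$phenotype == 0L), "\n")
  cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  cat("  max per-SNP missingness:", round(max(x$missing_frac), 4), "\n")
  invisible(x)
}

#' Expression matrix with probe coordinates
#'
#' @param E P x N matrix of normalised expression (rows = probes).
#' @param probes data.frame with columns `probe`, `chrom`, `pos_bp`.
#' @param sample_ids character ids aligned with columns of `E`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(E, probes, sample_ids) {
  E <- as.matrix(E)
  stopifnot(all(c("probe", "chrom", "pos_bp") %in% names(probes)),
            nrow(E) == nrow(probes), ncol(E) == length(sample_ids))
  if (any(rowSums(!is.na(E)) == 0L)) stop("all-missing probe row")
  structure(list(E = E, probes = as.data.frame(probes),
                 sample_ids = as.character(sample_ids)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$E), "probes x", ncol(x$E), "samples\n")
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles the thresholds and sizes used across the evidence chain. Defaults
#' are the study conventions: association alpha 0.05, iHS thresholds 1.65
#' (suggestive) and 2 (strong), 50-SNP gene windows called at the upper 10%
#' of the genome-wide empirical window distribution, a 1 Mb cis window,
#' 100 kb gene flanks, 10,000 permutations and a 5% MAF floor.
#'
#' @param assoc_alpha,ihs_suggestive,ihs_strong,window_snps,window_upper_fraction
#'   numeric thresholds (see Description).
#' @param cis_window_bp,gene_flank_bp,n_permutations,maf_min,rng_seed sizes,
#'   rates and the seed for all randomised stages.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(assoc_alpha = 0.05, ihs_suggestive = 1.65,
                            ihs_strong = 2, window_snps = 50,
                            window_upper_fraction = 0.10,
                            cis_window_bp = 1e6, gene_flank_bp = 1e5,
                            n_permutations = 10000, maf_min = 0.05,
                            rng_seed = 1L) {
  stopifnot(assoc_alpha > 0, assoc_alpha < 1,
            ihs_suggestive > 0, ihs_strong >= ihs_suggestive,
            window_snps >= 1, window_upper_fraction > 0,
            window_upper_fraction < 1, cis_window_bp > 0, gene_flank_bp >= 0,
            n_permutations >= 1, maf_min >= 0, maf_min < 0.5)
  structure(list(assoc_alpha = assoc_alpha, ihs_suggestive = ihs_suggestive,
                 ihs_strong = ihs_strong, window_snps = as.integer(window_snps),
                 window_upper_fraction = window_upper_fraction,
                 cis_window_bp = cis_window_bp, gene_flank_bp = gene_flank_bp,
                 n_permutations = as.integer(n_permutations),
                 maf_min = maf_min, rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

## ---- VCF --------------------------------------------------------------

#' Read a VCF into a haplotype panel or a genotype study substrate
#'
#' Biallelic SNP records only; anything else is skipped with a warning giving
#' the count. The ancestral allele is taken from the `AA` INFO tag when
#' present; otherwise the sample major allele is used and the variant is
#' flagged `ancestral_inferred`.
#'
#' In phased mode each sample contributes two consecutive haplotype rows in
#' genome order and the matrix is coded 1 = derived allele. In unphased mode
#' the dosage of the sample minor allele (recomputed for this data set) is
#' returned, with missing genotypes kept as `NA`.
#'
#' @param path VCF file (plain text or gzipped).
#' @param require_phased if TRUE return a [haplotype_panel()]; an unphased GT
#'   is an error naming the first offending record. If FALSE return a list
#'   with elements `G` (dosage matrix), `variants` and `sample_ids`, ready for
#'   [genotype_study()] once a phenotype is attached.
#' @return see `require_phased`.
#' @export
read_vcf <- function(path, require_phased = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0L) stop("empty VCF: ", path)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !is.na(fix$ALT) & !grepl(",", fix$ALT, fixed = TRUE)
  n_skipped <- sum(!keep)
  if (n_skipped > 0L)
    warning(n_skipped, " non-biallelic-SNP record(s) skipped")
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  vcf <- vcf[keep, ]
  fix <- fix[keep, , drop = FALSE]

  aa <- suppressWarnings(vcfR::extract.info(vcf, "AA"))
  ancestral <- rep("unknown", nrow(fix))
  if (!is.null(aa)) {
    ancestral[!is.na(aa) & toupper(aa) == toupper(fix$REF)] <- "ref"
    ancestral[!is.na(aa) & toupper(aa) == toupper(fix$ALT)] <- "alt"
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  variants <- data.frame(id = ids, chrom = fix$CHROM,
                         pos_bp = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, ancestral = ancestral,
                         map_cM = NA_real_,
                         ancestral_inferred = FALSE,
                         stringsAsFactors = FALSE)
  samples <- colnames(gt)

  if (require_phased) {
    unphased <- grepl("/", gt, fixed = TRUE) | is.na(gt)
    if (any(unphased)) {
      w <- which(unphased, arr.ind = TRUE)[1, ]
      stop("unphased or missing GT in phased mode at record ",
           variants$id[w[1]], ", sample ", samples[w[2]])
    }
    a1 <- substr(gt, 1L, 1L) == "1"
    a2 <- substr(gt, 3L, 3L) == "1"
    # gt is M x N; interleave the two haplotypes per sample, samples in order
    Halt <- matrix(0L, nrow = 2L * length(samples), ncol = nrow(variants))
    Halt[seq(1L, 2L * length(samples), by = 2L), ] <- t(a1) * 1L
    Halt[seq(2L, 2L * length(samples), by = 2L), ] <- t(a2) * 1L
    # derive ancestral coding; unknown AA -> major allele treated ancestral
    alt_freq <- colMeans(Halt)
    infer <- variants$ancestral == "unknown"
    variants$ancestral[infer] <- ifelse(alt_freq[infer] <= 0.5, "ref", "alt")
    variants$ancestral_inferred <- infer
    flip <- variants$ancestral == "alt"
    H <- Halt
    H[, flip] <- 1L - Halt[, flip]
    return(haplotype_panel(H, variants, samples))
  }

  d1 <- matrix(suppressWarnings(as.integer(substr(gt, 1L, 1L))),
               nrow = nrow(gt), dimnames = dimnames(gt))
  d2 <- matrix(suppressWarnings(as.integer(substr(gt, 3L, 3L))),
               nrow = nrow(gt), dimnames = dimnames(gt))
  Dalt <- t(d1 + d2)                       # N x M alt-allele dosage, NA kept
  alt_freq <- colMeans(Dalt, na.rm = TRUE) / 2
  effect <- ifelse(alt_freq <= 0.5, "alt", "ref")
  G <- Dalt
  G[, effect == "ref"] <- 2L - Dalt[, effect == "ref"]
  variants$effect <- effect
  list(G = G, variants = variants, sample_ids = samples)
}

#' Write a phased haplotype panel as a plain-text VCF
#'
#' The ancestral allele is recorded in the `AA` INFO field so a read/write
#' round trip reproduces the derived-allele coding exactly.
#'
#' @param panel a [haplotype_panel()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  v <- panel$variants
  aa_char <- ifelse(v$ancestral == "alt", v$alt, v$ref)
  n <- length(panel$sample_ids)
  # back to ref/alt coding
  A <- panel$H
  flip <- v$ancestral == "alt"
  A[, flip] <- 1L - A[, flip]
  h1 <- t(A[seq(1L, 2L * n, by = 2L), , drop = FALSE])
  h2 <- t(A[seq(2L, 2L * n, by = 2L), , drop = FALSE])
  gt <- matrix(paste0(h1, "|", h2), nrow = nrow(v))
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", panel$sample_ids), collapse = "\t"))
  body <- paste(v$chrom, v$pos_bp, v$id, v$ref, v$alt, ".", "PASS",
                paste0("AA=", aa_char), "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

## ---- genetic map ------------------------------------------------------

#' Read a 4-column genetic map and build a bp -> cM interpolator
#'
#' Expects whitespace/tab-separated columns `chrom`, `id`, `cM`, `bp` (a
#' header line is detected and skipped). Within each chromosome the map must
#' be non-decreasing in cM along bp. Queries interpolate linearly between
#' flanking points; queries outside the mapped range extrapolate at the
#' nearest interval's cM/bp rate. A single-point chromosome falls back to a
#' constant 1 cM/Mb rate (with a warning).
#'
#' @param path map file.
#' @return an object of class `genetic_map`; evaluate with
#'   [interpolate_cM()].
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), "[ \t]+")[[1]][3])))
  tab <- read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("genetic map needs 4 columns: chrom id cM bp")
  names(tab)[1:4] <- c("chrom", "id", "cM", "bp")
  tab$chrom <- as.character(tab$chrom)
  pts <- list()
  for (ch in unique(tab$chrom)) {
    sub <- tab[tab$chrom == ch, ]
    o <- order(sub$bp)
    sub <- sub[o, ]
    bad <- which(diff(sub$cM) < 0)
    if (length(bad))
      stop("non-monotone cM in genetic map, chromosome ", ch, " near line ",
           which(tab$chrom == ch)[o][bad[1] + 1L] + has_header)
    pts[[ch]] <- sub[, c("bp", "cM")]
  }
  structure(list(points = pts), class = "genetic_map")
}

#' Interpolate genetic-map position
#'
#' @param map a `genetic_map` from [read_genetic_map()].
#' @param chrom chromosome label (scalar).
#' @param bp physical positions to evaluate.
#' @return cM positions.
#' @export
interpolate_cM <- function(map, chrom, bp) {
  p <- map$points[[as.character(chrom)]]
  if (is.null(p)) stop("chromosome ", chrom, " not in genetic map")
  if (nrow(p) == 1L) {
    warning("single map point on chromosome ", chrom,
            "; constant 1 cM/Mb fallback")
    return(p$cM[1] + (bp - p$bp[1]) * 1e-6)
  }
  out <- approx(p$bp, p$cM, xout = bp, rule = 1)$y
  lo <- bp < p$bp[1]
  hi <- bp > p$bp[nrow(p)]
  if (any(lo)) {
    r <- (p$cM[2] - p$cM[1]) / (p$bp[2] - p$bp[1])
    out[lo] <- p$cM[1] + (bp[lo] - p$bp[1]) * r
  }
  if (any(hi)) {
    k <- nrow(p)
    r <- (p$cM[k] - p$cM[k - 1]) / (p$bp[k] - p$bp[k - 1])
    out[hi] <- p$cM[k] + (bp[hi] - p$bp[k]) * r
  }
  out
}

#' Attach genetic-map positions to a panel or variant table
#'
#' @param x a [haplotype_panel()] or variant table.
#' @param map a `genetic_map`.
#' @return `x` with `map_cM` filled in.
#' @export
add_genetic_map <- function(x, map) {
  v <- if (inherits(x, "haplotype_panel")) x$variants else x
  for (ch in unique(v$chrom)) {
    i <- v$chrom == ch
    v$map_cM[i] <- interpolate_cM(map, ch, v$pos_bp[i])
  }
  validate_variants(v)
  if (inherits(x, "haplotype_panel")) {
    x$variants <- v
    x
  } else v
}

## ---- genes, phenotype, expression -------------------------------------

#' Read gene annotations from BED
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention on read.
#'
#' @param path BED file (>= 4 columns: chrom, start, end, name).
#' @return data.frame with columns `name`, `chrom`, `start_bp`, `end_bp`.
#' @export
read_gene_bed <- function(path) {
  g <- rtracklayer::import(path, format = "BED")
  data.frame(name = if (!is.null(g$name)) as.character(g$name) else
               paste0("gene", seq_along(g)),
             chrom = as.character(GenomicRanges::seqnames(g)),
             start_bp = GenomicRanges::start(g),   # already 1-based inclusive
             end_bp = GenomicRanges::end(g),
             stringsAsFactors = FALSE)
}

#' Assign SNPs to (flank-extended) genes
#'
#' A SNP belongs to a gene iff `start_bp - flank_bp <= pos_bp <= end_bp +
#' flank_bp` on the same chromosome (1-based inclusive, boundary inclusive).
#' A SNP may belong to several genes.
#'
#' @param variants variant table.
#' @param genes data.frame with `name`, `chrom`, `start_bp`, `end_bp`.
#' @param flank_bp extension applied on both sides (default 100 kb, the
#'   convention used to capture regulatory flanks of pathway genes).
#' @return named list: gene name -> integer vector of SNP indices.
#' @export
assign_snps_to_genes <- function(variants, genes, flank_bp = 1e5) {
  stopifnot(flank_bp >= 0)
  out <- vector("list", nrow(genes))
  names(out) <- genes$name
  for (i in seq_len(nrow(genes))) {
    out[[i]] <- which(variants$chrom == genes$chrom[i] &
                        variants$pos_bp >= genes$start_bp[i] - flank_bp &
                        variants$pos_bp <= genes$end_bp[i] + flank_bp)
  }
  out
}

#' Read a phenotype/covariate TSV
#'
#' Columns: `sample`, `status` (0 control / 1 case), `age`, optional extras
#' (e.g. `psa`).
#'
#' @param path TSV file with header.
#' @return data.frame.
#' @export
read_phenotype_tsv <- function(path) {
  ph <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "status", "age") %in% names(ph)))
  if (!all(ph$status %in% 0:1)) stop("status must be 0/1")
  ph
}

#' Read an expression TSV into an [expression_matrix()]
#'
#' Columns: `probe`, `chrom`, `pos`, then one numeric column per sample.
#'
#' @param path TSV file with header.
#' @return an `expression_matrix`.
#' @export
read_expression_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  stopifnot(all(c("probe", "chrom", "pos") %in% names(tab)))
  samp <- setdiff(names(tab), c("probe", "chrom", "pos"))
  E <- as.matrix(tab[, samp, drop = FALSE])
  rownames(E) <- tab$probe
  expression_matrix(E,
                    probes = data.frame(probe = tab$probe,
                                        chrom = as.character(tab$chrom),
                                        pos_bp = as.integer(tab$pos),
                                        stringsAsFactors = FALSE),
                    sample_ids = samp)
}

#' Collapse a phased panel to a case/control study
#'
#' Sums the two haplotypes per sample into a derived-allele dosage and binds
#' a phenotype table (matched by sample id).
#'
#' @param panel a [haplotype_panel()].
#' @param phenotype data.frame as from [read_phenotype_tsv()].
#' @return a [genotype_study()]; the effect allele is the derived allele.
#' @export
panel_to_study <- function(panel, phenotype) {
  m <- match(panel$sample_ids, phenotype$sample)
  if (anyNA(m)) stop("phenotype table is missing sample(s): ",
                     paste(head(panel$sample_ids[is.na(m)]), collapse = ", "))
  ph <- phenotype[m, , drop = FALSE]
  n <- length(panel$sample_ids)
  G <- panel$H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    panel$H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  v <- panel$variants
  v$effect <- ifelse(v$ancestral == "ref", "alt", "ref")  # derived allele
  covs <- ph[, setdiff(names(ph), c("sample", "status")), drop = FALSE]
  genotype_study(G, v, ph$status, covs, panel$sample_ids)
}
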