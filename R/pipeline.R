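# Orchestration of the full evidence chain, published-table fixtures, and
# small report arithmetic.

## ---- packaged fixtures -------------------------------------------------

#' Load the packaged SNP evidence table fixture
#'
#' Transcription of the published table of SNPs significant in the
#' case-control association analysis (P < 0.05) and showing suggestive
#' haplotype-based selection signals: per SNP the odds ratio, 95% CI, Wald P,
#' and the iHS score in the ASN, CEU and YRI reference panels, plus the
#' per-population gene-level positive-selection flags.
#'
#' @return data.frame with columns `chrom`, `snp`, `gene`, `or_`, `l95`,
#'   `u95`, `p`, `ihs_asn`, `ihs_ceu`, `ihs_yri`, `sel_asn`, `sel_ceu`,
#'   `sel_yri`.
#' @export
load_snp_evidence_fixture <- function() {
  read.table(system.file("extdata", "snp_evidence.tsv", package = "pathsel"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = "NA")
}

#' Load the packaged cohort descriptive counts fixture
#'
#' Category counts (with missing counts) for the emulated case-control
#' cohort: PSA classes, Gleason score classes and clinical stages among 1417
#' cases and 1008 controls.
#'
#' @return data.frame with columns `group`, `variable`, `category`, `count`,
#'   `total`, `missing`.
#' @export
load_cohort_fixture <- function() {
  read.table(system.file("extdata", "cohort_counts.tsv", package = "pathsel"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Load the packaged positive-loci fixture
#'
#' The five SNPs carrying every layer of evidence in the published analysis
#' (association, selection, eQTL), with genotype counts (mm/Mm/MM; m = minor
#' allele), SNP- and gene-level iHS evidence, association P values and the
#' best cis-eQTL P.
#'
#' @return data.frame.
#' @export
load_positive_loci_fixture <- function() {
  read.table(system.file("extdata", "positive_loci.tsv", package = "pathsel"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = "NA")
}

## ---- report arithmetic -------------------------------------------------

#' Summarise the SNP evidence fixture
#'
#' Returns the SNP attaining the maximum |iHS| in the chosen population
#' column and the number of rows passing each threshold (strict `>`), among
#' rows with a non-missing score.
#'
#' @param fixture data.frame as from [load_snp_evidence_fixture()]; an empty
#'   table gives an error-free empty summary.
#' @param column iHS column to summarise (default `"ihs_asn"`).
#' @param thresholds |iHS| thresholds to count against.
#' @return list: `max_snp`, `max_abs_ihs`, `n_scored`, `counts` (named by
#'   threshold).
#' @export
summarize_fixture_table <- function(fixture, column = "ihs_asn",
                                    thresholds = c(1.65, 2)) {
  v <- fixture[[column]]
  scored <- which(!is.na(v))
  counts <- vapply(thresholds, function(th) sum(abs(v[scored]) > th), 1L)
  names(counts) <- as.character(thresholds)
  if (length(scored) == 0L)
    return(list(max_snp = NA_character_, max_abs_ihs = NA_real_,
                n_scored = 0L, counts = counts))
  i <- scored[which.max(abs(v[scored]))]
  list(max_snp = fixture$snp[i], max_abs_ihs = abs(v[i]),
       n_scored = length(scored), counts = counts)
}

#' Cohort descriptive percentages
#'
#' `percentage = 100 * count / (total - missing)`, rounded to one decimal:
#' the convention used for the published cohort table, where percentages are
#' taken among subjects with a non-missing value.
#'
#' @param count category count(s).
#' @param total group total(s).
#' @param missing count(s) with a missing value for the variable.
#' @return percentage(s), one decimal.
#' @export
cohort_descriptives <- function(count, total, missing = 0) {
  if (any(total <= missing)) stop("total must exceed missing")
  round(100 * count / (total - missing), 1)
}

## ---- orchestration -----------------------------------------------------

.write_stage <- function(x, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  write.table(as.data.frame(x), file.path(dir, paste0(name, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full evidence chain
#'
#' Stages: per-SNP association scan -> gene/pathway ARTP -> iHS scan ->
#' candidate-locus join (association p < `assoc_alpha` and |iHS| >
#' `ihs_suggestive`) -> gene-window selection scan -> eQTL on the surviving
#' loci -> multi-evidence summary. Every stage's table is persisted under
#' `out_dir` (when given) together with a JSON run manifest echoing the
#' configuration, and the run is fully reproducible from config + seed.
#'
#' @param config a [pipeline_config()].
#' @param panel a [haplotype_panel()] with genetic map attached.
#' @param study a [genotype_study()] over the same variants/samples.
#' @param genes data.frame with `name`, `chrom`, `start_bp`, `end_bp`.
#' @param expression an [expression_matrix()], or NULL to skip the eQTL
#'   stage.
#' @param out_dir directory for stage outputs (created; NULL = in-memory
#'   only).
#' @return object of class `evidence_summary`: all stage outputs, the final
#'   evidence table, funnel counts, and the config.
#' @export
run_pipeline <- function(config, panel, study, genes, expression = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  assoc <- stage("association", assoc_scan(study))
  .write_stage(assoc, out_dir, "assoc")

  gene_map <- stage("gene-assignment",
                    assign_snps_to_genes(study$variants, genes,
                                         config$gene_flank_bp))
  artp <- stage("artp", artp_test(study, gene_map, B = config$n_permutations,
                                  seed = (config$rng_seed + 101L) %% 2147483647L))
  .write_stage(artp$genes, out_dir, "artp_genes")

  ihs <- stage("ihs-scan", ihs_scan(panel, maf_min = config$maf_min))
  .write_stage(ihs, out_dir, "ihs")

  cand <- stage("candidate-join",
                select_candidate_loci(ihs, assoc,
                                      ihs_threshold = config$ihs_suggestive,
                                      alpha = config$assoc_alpha))
  .write_stage(cand, out_dir, "candidates")

  windows <- stage("gene-window-scan",
                   gene_window_scan(ihs, genes,
                                    window_snps = config$window_snps,
                                    sig_threshold = config$ihs_strong,
                                    upper_fraction = config$window_upper_fraction))
  .write_stage(windows, out_dir, "gene_windows")

  eqtl <- NULL
  if (!is.null(expression) && nrow(cand) > 0L) {
    idx <- match(cand$id, study$variants$id)
    eqtl <- stage("eqtl",
                  eqtl_scan(study, expression, snp_indices = idx,
                            B = config$n_permutations,
                            seed = (config$rng_seed + 202L) %% 2147483647L,
                            window_bp = config$cis_window_bp))
    .write_stage(eqtl, out_dir, "eqtl")
  }

  evidence <- stage("evidence-join",
                    build_evidence_table(cand, study, gene_map, artp, windows,
                                         eqtl))
  .write_stage(evidence, out_dir, "evidence")

  funnel <- c(n_snps = ncol(study$G),
              n_assoc_significant = length(significant_snps(assoc,
                                                            config$assoc_alpha)),
              n_ihs_scored = sum(!is.na(ihs$ihs)),
              n_candidates = nrow(cand),
              n_candidate_genes = sum(windows$candidate, na.rm = TRUE),
              n_eqtl_supported = if (is.null(eqtl)) NA_integer_ else
                length(unique(eqtl$snp[!is.na(eqtl$p_perm) &
                                         eqtl$p_perm < config$assoc_alpha])))
  if (!is.null(out_dir))
    jsonlite::write_json(list(config = unclass(config), funnel = as.list(funnel),
                              pathway_p = artp$pathway_p),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  structure(list(assoc = assoc, artp = artp, ihs = ihs, candidates = cand,
                 windows = windows, eqtl = eqtl, evidence = evidence,
                 funnel = funnel, config = config),
            class = "evidence_summary")
}

#' Assemble the final multi-evidence table
#'
#' One row per candidate SNP: genotype counts of the effect allele (mm/Mm/MM;
#' m = effect/minor allele), the SNP's iHS, its gene's window-scan empirical
#' fraction, the association P, the gene's ARTP P and the best cis and trans
#' eQTL permutation P. Built purely from persisted stage outputs, so
#' re-joining them reproduces it exactly.
#'
#' @param candidates output of [select_candidate_loci()].
#' @param study the [genotype_study()].
#' @param gene_map named list gene -> SNP indices.
#' @param artp an `artp_result`.
#' @param windows a `gene_selection` table.
#' @param eqtl an `eqtl_table` or NULL.
#' @return data.frame, one row per candidate SNP.
#' @export
build_evidence_table <- function(candidates, study, gene_map, artp, windows,
                                 eqtl = NULL) {
  if (nrow(candidates) == 0L)
    return(data.frame(snp = character(), gene = character(),
                      n_mm = integer(), n_Mm = integer(), n_MM = integer(),
                      loci_ihs = numeric(), gene_fraction = numeric(),
                      loci_p = numeric(), gene_artp_p = numeric(),
                      cis_eqtl_p = numeric(), trans_eqtl_p = numeric(),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    id <- candidates$id[i]
    j <- match(id, study$variants$id)
    g <- study$G[, j]
    in_genes <- names(gene_map)[vapply(gene_map, function(x) j %in% x, TRUE)]
    gene <- if (length(in_genes)) paste(in_genes, collapse = ",") else NA_character_
    g1 <- if (length(in_genes)) in_genes[1L] else NA_character_
    ge_p <- if (!is.na(g1) && g1 %in% artp$genes$gene)
      artp$genes$gene_p[artp$genes$gene == g1] else NA_real_
    frac <- if (!is.na(g1) && g1 %in% windows$gene)
      windows$fraction[windows$gene == g1] else NA_real_
    cis_p <- trans_p <- NA_real_
    if (!is.null(eqtl)) {
      sub <- eqtl[eqtl$snp == id & !is.na(eqtl$p_perm), , drop = FALSE]
      if (any(sub$label == "cis"))
        cis_p <- min(sub$p_perm[sub$label == "cis"])
      if (any(sub$label == "trans"))
        trans_p <- min(sub$p_perm[sub$label == "trans"])
    }
    data.frame(snp = id, gene = gene,
               n_mm = sum(g == 2L, na.rm = TRUE),
               n_Mm = sum(g == 1L, na.rm = TRUE),
               n_MM = sum(g == 0L, na.rm = TRUE),
               loci_ihs = candidates$ihs[i], gene_fraction = frac,
               loci_p = candidates$p[i], gene_artp_p = ge_p,
               cis_eqtl_p = cis_p, trans_eqtl_p = trans_p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.evidence_summary <- function(x, ...) {
  cat("Evidence-chain run\n")
  cat("  funnel:", paste(names(x$funnel), x$funnel, sep = "=",
                         collapse = ", "), "\n")
  cat("  ARTP pathway P =", format(x$artp$pathway_p, digits = 4), "\n")
  if (nrow(x$evidence)) {
    cat("  final evidence table:\n")
    print.data.frame(x$evidence, digits = 4, row.names = FALSE)
  } else cat("  final evidence table: empty\n")
  invisible(x)
}
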