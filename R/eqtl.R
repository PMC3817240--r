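# Additive linear-regression eQTL scan with permutation significance and
# cis/trans labelling by the 1 Mb rule.

# closed-form simple OLS slope test (two-sided t); returns NULL on skip
.ols_slope <- function(g, e) {
  ok <- !is.na(g) & !is.na(e)
  g <- g[ok]; e <- e[ok]
  n <- length(g)
  ug <- unique(g)
  if (length(ug) < 2L || var(e) == 0) return(NULL)
  if (length(ug) == 2L && n < 10L) return(NULL)
  if (n < 4L) return(NULL)
  gc <- g - mean(g)
  ec <- e - mean(e)
  sxx <- sum(gc^2)
  beta <- sum(gc * ec) / sxx
  rss <- sum((ec - beta * gc)^2)
  se <- sqrt(rss / (n - 2L) / sxx)
  t <- if (se == 0) sign(beta) * Inf else beta / se
  list(beta = beta, se = se, t = t, p = 2 * pt(-abs(t), df = n - 2L), n = n)
}

#' Single-pair eQTL test
#'
#' Ordinary least squares of expression on additive dosage with a two-sided
#' t-test on the slope. Requires at least 3 distinct dosage values, or 2
#' distinct values with n >= 10; constant dosage or constant expression is
#' skipped.
#'
#' @param g dosage vector (0/1/2, NA allowed; pairwise-complete).
#' @param e expression vector.
#' @return list `beta`, `se`, `t`, `p`, `n`, or `NULL` when skipped.
#' @export
eqtl_test <- function(g, e) {
  .ols_slope(g, e)
}

#' Permutation p-value for one eQTL pair
#'
#' The expression vector is permuted B times; the permutation p-value is
#' `(1 + #[|t_perm| >= |t_obs|]) / (B + 1)` (never zero). Deterministic under
#' `seed`.
#'
#' @param g dosage vector.
#' @param e expression vector.
#' @param B permutations (>= 1).
#' @param seed RNG seed.
#' @param perms optional explicit (B x n) matrix of row-permuted indices
#'   (e.g. the exhaustive set on a toy); overrides random permutation.
#' @return list: `p_perm`, `p_nominal`, `beta`, `t_obs`, `B`; or `NULL`
#'   when the observed test is skipped.
#' @export
eqtl_permutation_p <- function(g, e, B = 1000L, seed = 1L, perms = NULL) {
  obs <- eqtl_test(g, e)
  if (is.null(obs)) return(obs)
  ok <- !is.na(g) & !is.na(e)
  g <- g[ok]; e <- e[ok]
  n <- length(g)
  if (!is.null(perms)) {
    stopifnot(ncol(perms) == n)
    B <- nrow(perms)
  } else {
    set.seed(seed)
    perms <- t(replicate(B, sample.int(n)))
  }
  # |t| is a monotone function of |cor|, so compare correlations
  gc <- g - mean(g)
  E <- matrix(e[t(perms)], nrow = n)            # n x B, column = one permutation
  r <- abs(as.vector(crossprod(gc, scale(E, scale = FALSE)))) /
    sqrt(sum(gc^2) * colSums(scale(E, scale = FALSE)^2))
  r_obs <- abs(sum(gc * (e - mean(e)))) / sqrt(sum(gc^2) * sum((e - mean(e))^2))
  p_perm <- (1 + sum(r >= r_obs - 1e-12)) / (B + 1)
  list(p_perm = p_perm, p_nominal = obs$p, beta = obs$beta, t_obs = obs$t,
       B = B)
}

#' Label a SNP-probe pair cis or trans
#'
#' cis iff same chromosome and `|pos_snp - pos_probe| <= window_bp`
#' (boundary inclusive); different chromosomes are always trans.
#'
#' @param snp_chrom,snp_pos SNP coordinates (vectors recycle).
#' @param probe_chrom,probe_pos probe coordinates.
#' @param window_bp cis window (default 1 Mb).
#' @return character vector of `"cis"` / `"trans"`.
#' @export
classify_cis_trans <- function(snp_chrom, snp_pos, probe_chrom, probe_pos,
                               window_bp = 1e6) {
  ifelse(as.character(snp_chrom) == as.character(probe_chrom) &
           abs(as.numeric(snp_pos) - as.numeric(probe_pos)) <= window_bp,
         "cis", "trans")
}

#' eQTL scan over SNP-probe pairs
#'
#' Tests every combination of the requested SNPs and probes (samples aligned
#' by id), with optional permutation p-values and cis/trans labelling.
#'
#' @param study a [genotype_study()].
#' @param expr an [expression_matrix()] with the same samples.
#' @param snp_indices,probe_indices subsets; default all.
#' @param B permutations per pair (0 = nominal p only).
#' @param seed RNG seed; pair b gets seed `seed + pair rank` for
#'   reproducibility.
#' @param window_bp cis window.
#' @param cis_only test only pairs within the cis window.
#' @return data.frame of class `eqtl_table`: `snp`, `probe`, `beta`,
#'   `p_nominal`, `p_perm`, `distance_bp` (signed SNP - probe, NA across
#'   chromosomes), `label`, `reason`.
#' @export
eqtl_scan <- function(study, expr, snp_indices = NULL, probe_indices = NULL,
                      B = 0L, seed = 1L, window_bp = 1e6, cis_only = FALSE) {
  if (!identical(study$sample_ids, expr$sample_ids)) {
    m <- match(study$sample_ids, expr$sample_ids)
    if (anyNA(m)) stop("expression matrix is missing study sample(s)")
    expr$E <- expr$E[, m, drop = FALSE]
    expr$sample_ids <- expr$sample_ids[m]
  }
  if (is.null(snp_indices)) snp_indices <- seq_len(ncol(study$G))
  if (is.null(probe_indices)) probe_indices <- seq_len(nrow(expr$E))
  rows <- list()
  k <- 0L
  for (si in snp_indices) {
    for (pi in probe_indices) {
      same <- study$variants$chrom[si] == expr$probes$chrom[pi]
      dist <- if (same)
        study$variants$pos_bp[si] - expr$probes$pos_bp[pi] else NA_real_
      label <- classify_cis_trans(study$variants$chrom[si],
                                  study$variants$pos_bp[si],
                                  expr$probes$chrom[pi],
                                  expr$probes$pos_bp[pi], window_bp)
      if (cis_only && label != "cis") next
      k <- k + 1L
      g <- study$G[, si]
      e <- expr$E[pi, ]
      base <- data.frame(snp = study$variants$id[si],
                         probe = expr$probes$probe[pi],
                         beta = NA_real_, p_nominal = NA_real_,
                         p_perm = NA_real_, distance_bp = dist,
                         label = label, reason = NA_character_,
                         stringsAsFactors = FALSE)
      if (B > 0L) {
        res <- eqtl_permutation_p(g, e, B = B,
                                  seed = (seed + k) %% 2147483647L)
        if (is.null(res)) base$reason <- "constant or under-filled pair"
        else {
          base$beta <- res$beta
          base$p_nominal <- res$p_nominal
          base$p_perm <- res$p_perm
        }
      } else {
        res <- eqtl_test(g, e)
        if (is.null(res)) base$reason <- "constant or under-filled pair"
        else {
          base$beta <- res$beta
          base$p_nominal <- res$p
        }
      }
      rows[[k]] <- base
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp = character(), probe = character(), beta = numeric(),
               p_nominal = numeric(), p_perm = numeric(),
               distance_bp = numeric(), label = character(),
               reason = character(), stringsAsFactors = FALSE)
  class(out) <- c("eqtl_table", "data.frame")
  out
}

#' @export
print.eqtl_table <- function(x, ...) {
  cat("eQTL scan:", nrow(x), "pairs (", sum(x$label == "cis"), "cis /",
      sum(x$label == "trans"), "trans )\n")
  pcol <- if (any(!is.na(x$p_perm))) x$p_perm else x$p_nominal
  cat("  pairs with p < 0.05:", sum(pcol < 0.05, na.rm = TRUE), "\n")
  invisible(x)
}
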