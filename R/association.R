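# Per-SNP case-control logistic association with covariate adjustment,
# plus the odds-ratio/CI/Wald arithmetic used for published-table checks.

.z975 <- 1.959964

.skip_record <- function(id, reason) {
  data.frame(id = id, beta = NA_real_, se = NA_real_, or_ = NA_real_,
             l95 = NA_real_, u95 = NA_real_, p = NA_real_,
             n_used = NA_integer_, maf = NA_real_, reason = reason,
             stringsAsFactors = FALSE)
}

#' Fit one SNP's additive logistic association
#'
#' Additive dosage coding, covariate-adjusted logistic regression fitted by
#' iteratively reweighted least squares (relative deviance change < 1e-8,
#' at most 50 iterations), two-sided Wald test, and a 95% CI of the odds
#' ratio as `exp(beta +/- 1.959964 * se)`. Samples missing the genotype or a
#' covariate are dropped for this SNP only (pairwise-complete).
#'
#' Monomorphic SNPs, or SNPs leaving fewer than 10 cases or 10 controls with
#' complete data, are skipped with a reason; non-convergence or separation
#' (|beta| > 10) yields a flagged record with `p = NA`.
#'
#' @param study a [genotype_study()].
#' @param snp_index column index into the dosage matrix.
#' @param covariates names of covariate columns to adjust for.
#' @return one-row data.frame: `id`, `beta`, `se`, `or_`, `l95`, `u95`, `p`,
#'   `n_used`, `maf`, `reason` (NA when the fit is clean).
#' @export
fit_snp_logistic <- function(study, snp_index, covariates = "age") {
  id <- study$variants$id[snp_index]
  g <- study$G[, snp_index]
  X <- study$covariates[, covariates, drop = FALSE]
  y <- study$phenotype
  ok <- !is.na(g) & complete.cases(X)
  g <- g[ok]; y <- y[ok]; X <- X[ok, , drop = FALSE]
  if (length(unique(g)) < 2L) return(.skip_record(id, "monomorphic"))
  if (sum(y == 1L) < 10L || sum(y == 0L) < 10L)
    return(.skip_record(id, "fewer than 10 cases or 10 controls"))
  dat <- data.frame(y = y, g = g, X)
  fit <- glm(y ~ ., family = binomial(), data = dat,
             control = glm.control(epsilon = 1e-8, maxit = 50L))
  beta <- coef(fit)[["g"]]
  se <- sqrt(diag(vcov(fit)))[["g"]]
  f <- mean(g) / 2
  rec <- data.frame(id = id, beta = beta, se = se, or_ = exp(beta),
                    l95 = exp(beta - .z975 * se),
                    u95 = exp(beta + .z975 * se),
                    p = 2 * pnorm(-abs(beta / se)),
                    n_used = length(y), maf = min(f, 1 - f),
                    reason = NA_character_, stringsAsFactors = FALSE)
  if (!fit$converged || abs(beta) > 10) {
    rec$p <- NA_real_
    rec$reason <- if (!fit$converged) "non-convergence" else "separation"
  }
  rec
}

#' Per-SNP association scan over a study
#'
#' Applies [fit_snp_logistic()] to every SNP (or a subset) and returns a
#' table in the published layout (SNP, OR, L95, U95, P).
#'
#' @param study a [genotype_study()].
#' @param covariates covariate names (default age only).
#' @param snp_indices subset of columns; default all.
#' @return data.frame of class `assoc_table`, one row per SNP.
#' @export
assoc_scan <- function(study, covariates = "age", snp_indices = NULL) {
  if (is.null(snp_indices)) snp_indices <- seq_len(ncol(study$G))
  out <- do.call(rbind, lapply(snp_indices, fit_snp_logistic, study = study,
                               covariates = covariates))
  out$chrom <- study$variants$chrom[snp_indices]
  out$pos_bp <- study$variants$pos_bp[snp_indices]
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' @export
print.assoc_table <- function(x, ...) {
  cat("Association scan:", nrow(x), "SNPs;",
      sum(!is.na(x$p) & x$p < 0.05), "with Wald P < 0.05;",
      sum(!is.na(x$reason)), "skipped/flagged\n")
  print.data.frame(head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Recover a two-sided Wald P from a printed OR and 95% CI
#'
#' `se = (ln u95 - ln l95) / (2 * 1.959964)`; `p = 2 * pnorm(-|ln or_| / se)`.
#' Used to verify published association tables from their printed columns.
#'
#' @param or_ odds ratio(s).
#' @param l95,u95 bounds of the 95% confidence interval.
#' @return two-sided Wald p-value(s).
#' @export
wald_p_from_or_ci <- function(or_, l95, u95) {
  if (any(!(0 < l95 & l95 <= or_ & or_ <= u95)))
    stop("need 0 < l95 <= or_ <= u95")
  se <- (log(u95) - log(l95)) / (2 * .z975)
  2 * pnorm(-abs(log(or_)) / se)
}

#' Indices of significant association records
#'
#' Strict inequality (`p < alpha`); records with missing p are excluded.
#'
#' @param records an `assoc_table` or any data.frame with a `p` column.
#' @param alpha significance threshold (default 0.05).
#' @return integer indices into `records`.
#' @export
significant_snps <- function(records, alpha = 0.05) {
  which(!is.na(records$p) & records$p < alpha)
}
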