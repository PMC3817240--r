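# Gene- and pathway-level adaptive rank truncated product (ARTP) permutation
# test combining per-SNP association evidence.
#
# The machinery follows the single-permutation-layer construction: one
# phenotype-permutation ensemble supplies (i) per-SNP p-values per replicate,
# (ii) per-gene RTP statistics and their rank-based significance per
# truncation point, (iii) the gene-level MinP statistic and its adjusted p,
# and (iv) a second ARTP layer over genes for the pathway p. No nested
# resampling is used.

#' Rank truncated product statistic
#'
#' Product of the k smallest p-values; computed as a sum of logs to avoid
#' underflow.
#'
#' @param p p-values in (0, 1].
#' @param k truncation point, `1 <= k <= length(p)`.
#' @param log return the statistic on the log scale.
#' @return the RTP statistic (product scale unless `log = TRUE`).
#' @export
rtp_statistic <- function(p, k, log = FALSE) {
  if (k < 1 || k > length(p)) stop("k out of range")
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  w <- sum(base::log(sort(p, partial = k)[seq_len(k)]))
  if (log) w else exp(w)
}

# Vectorised score-test p-values for many SNPs against one phenotype vector,
# adjusting for covariates: one Newton evaluation at the covariate-only null
# fit (the classical efficient-score test). G must be complete; callers
# mean-impute sporadic missingness first.
.score_test_p <- function(G, y, Xd) {
  nf <- glm.fit(Xd, y, family = binomial())
  p0 <- nf$fitted.values
  w <- p0 * (1 - p0)
  r <- y - p0
  U <- crossprod(G, r)                          # M x 1
  A <- crossprod(G, w * Xd)                     # M x k
  Cinv <- solve(crossprod(Xd, w * Xd))          # k x k
  V <- colSums(w * G^2) - rowSums((A %*% Cinv) * A)
  stat <- as.vector(U)^2 / V
  p <- pchisq(stat, df = 1L, lower.tail = FALSE)
  p[!is.finite(stat) | V <= 0] <- 1
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Observed-plus-permuted per-SNP p-value matrix
#'
#' Row 1 holds the observed per-SNP association p-values; rows 2..B+1 hold
#' phenotype-permutation replicates. Covariates stay attached to samples and
#' only the phenotype labels are permuted. The per-SNP statistic is the
#' covariate-adjusted score test (one Newton step from the covariate-only
#' null fit); `method = "wald"` refits the full logistic model per SNP and
#' replicate instead (toy scale only). Sporadically missing genotypes are
#' mean-imputed for this permutation machinery.
#'
#' @param study a [genotype_study()].
#' @param snp_indices SNP columns to include.
#' @param B number of permutations (>= 1).
#' @param seed RNG seed making the replicate set reproducible.
#' @param covariates covariate names.
#' @param method `"score"` (default) or `"wald"`.
#' @param perms optional explicit (B x n) matrix of permuted phenotype
#'   vectors (rows), e.g. the exhaustive set on a toy; overrides random
#'   permutation.
#' @return (B+1) x length(snp_indices) matrix of p-values.
#' @export
permutation_p_matrix <- function(study, snp_indices, B, seed = 1L,
                                 covariates = "age",
                                 method = c("score", "wald"), perms = NULL) {
  method <- match.arg(method)
  y <- study$phenotype
  if (length(unique(y)) < 2L) stop("need both phenotype classes")
  if (!is.null(perms)) {
    stopifnot(ncol(perms) == length(y))
    B <- nrow(perms)
  }
  stopifnot(B >= 1)
  G <- study$G[, snp_indices, drop = FALSE]
  if (anyNA(G)) {
    for (j in seq_len(ncol(G))) {
      nas <- is.na(G[, j])
      if (any(nas)) G[nas, j] <- mean(G[, j], na.rm = TRUE)
    }
  }
  storage.mode(G) <- "double"
  Xd <- cbind(1, as.matrix(study$covariates[, covariates, drop = FALSE]))
  Y <- matrix(0L, nrow = B + 1L, ncol = length(y))
  Y[1L, ] <- y
  if (is.null(perms)) {
    set.seed(seed)
    for (b in seq_len(B)) Y[b + 1L, ] <- sample(y)
  } else {
    Y[-1L, ] <- perms
  }
  out <- matrix(NA_real_, nrow = B + 1L, ncol = ncol(G))
  for (b in seq_len(B + 1L)) {
    if (method == "score") {
      out[b, ] <- .score_test_p(G, Y[b, ], Xd)
    } else {
      out[b, ] <- vapply(seq_len(ncol(G)), function(j) {
        dat <- data.frame(y = Y[b, ], g = G[, j],
                          study$covariates[, covariates, drop = FALSE])
        fit <- glm(y ~ ., family = binomial(), data = dat,
                   control = glm.control(epsilon = 1e-8, maxit = 50L))
        z <- coef(fit)[["g"]] / sqrt(diag(vcov(fit)))[["g"]]
        2 * pnorm(-abs(z))
      }, numeric(1))
    }
  }
  colnames(out) <- study$variants$id[snp_indices]
  out
}

# rank-based significance of each row's statistic within its column:
# p_hat_b = (1 + #{b' != b : W_b' <= W_b}) / (B + 1)
# = rank with ties counted "<=" (conservative), over all B+1 rows.
.rank_p <- function(W) {
  apply(W, 2L, function(col) rank(col, ties.method = "max")) / nrow(W)
}

#' Convert a statistic matrix to rank-based p-values per replicate
#'
#' For each column (SNP or gene), each row's statistic is converted to
#' `(1 + #[other rows with a statistic at least as extreme]) / (B + 1)`.
#' Larger statistics count as more significant when `decreasing = TRUE`.
#'
#' @param S (B+1) x L statistic matrix, observed row first.
#' @param decreasing direction of significance.
#' @return matrix of the same shape with entries in `[1/(B+1), 1]`.
#' @export
rank_p_matrix <- function(S, decreasing = TRUE) {
  if (decreasing) S <- -S
  .rank_p(S)
}

#' Gene-level ARTP p-value from a permutation p matrix
#'
#' For every replicate b and truncation point k, the RTP statistic W_b(k) is
#' ranked within the ensemble to give an estimated significance
#' `p_hat_b(k)`; `MinP_b = min_k p_hat_b(k)` is the adaptive statistic, and
#' the gene p-value is `(1 + #[b >= 1 : MinP_b <= MinP_0]) / (B + 1)` — the
#' single-layer adjustment, no nested resampling.
#'
#' @param p_matrix (B+1) x L matrix from [permutation_p_matrix()] (columns =
#'   the gene's SNPs, observed row first).
#' @param truncation_grid truncation points; default `c(1,2,3,4,5,10,15,20)`
#'   capped at the SNP count.
#' @return list of class `artp_gene`: `gene_p`, `min_p` (per replicate),
#'   `w_obs` (log RTP per k, observed), `p_hat_obs`, `grid`, `B`.
#' @export
artp_gene_p <- function(p_matrix, truncation_grid = NULL) {
  L <- ncol(p_matrix)
  B <- nrow(p_matrix) - 1L
  if (B < 20L) warning("B < 20 permutations: p-value resolution is coarse")
  if (is.null(truncation_grid))
    truncation_grid <- c(1L, 2L, 3L, 4L, 5L, 10L, 15L, 20L)
  grid <- sort(unique(pmin(as.integer(truncation_grid), L)))
  if (length(grid) == 0L || any(grid < 1L)) stop("empty/invalid truncation grid")
  # log-RTP for all k in one sorted cumsum pass per replicate
  W <- t(apply(p_matrix, 1L, function(p) cumsum(base::log(sort(p)))[grid]))
  if (length(grid) == 1L) W <- matrix(W, ncol = 1L)
  p_hat <- .rank_p(W)
  min_p <- apply(p_hat, 1L, min)
  gene_p <- (1 + sum(min_p[-1L] <= min_p[1L])) / (B + 1L)
  structure(list(gene_p = gene_p, min_p = min_p, w_obs = W[1L, ],
                 p_hat_obs = p_hat[1L, ], grid = grid, B = B),
            class = "artp_gene")
}

#' Pathway-level ARTP p-value from per-gene MinP statistics
#'
#' Treats each gene's per-replicate MinP as a statistic, rank-transforms it
#' into a per-replicate gene p-value, and applies the identical ARTP layer
#' over genes (RTP across genes per replicate over `gene_grid`, rank, min,
#' single-layer adjustment). All genes must come from the same permutation
#' ensemble.
#'
#' @param minp_matrix (B+1) x n_genes matrix; column g holds gene g's MinP
#'   per replicate, observed row first.
#' @param gene_grid truncation points over genes; same default family as
#'   [artp_gene_p()], capped at the gene count.
#' @return list of class `artp_pathway`: `pathway_p`, `grid`, `B`.
#' @export
artp_pathway_p <- function(minp_matrix, gene_grid = NULL) {
  if (is.null(dim(minp_matrix)) || ncol(minp_matrix) < 1L)
    stop("need a (B+1) x n_genes MinP matrix")
  gene_p_reps <- .rank_p(minp_matrix)   # smaller MinP = more significant
  res <- artp_gene_p(gene_p_reps, truncation_grid = gene_grid)
  structure(list(pathway_p = res$gene_p, grid = res$grid, B = res$B),
            class = "artp_pathway")
}

#' Gene-based pathway ARTP test on a study
#'
#' Runs one phenotype-permutation ensemble over the union of the genes'
#' SNPs, computes each gene's ARTP p-value, and combines the genes into a
#' pathway-level ARTP p-value from the same ensemble.
#'
#' `prefilter_alpha` reproduces the workflow that feeds only SNPs with
#' observed association p below a threshold into the gene test. This
#' conditions the test on the observed data (a selection-biased variant) and
#' is OFF by default.
#'
#' @param study a [genotype_study()].
#' @param gene_map named list: gene -> SNP column indices (as from
#'   [assign_snps_to_genes()]); empty genes are dropped.
#' @param B permutations.
#' @param seed RNG seed.
#' @param covariates covariate names.
#' @param truncation_grid,gene_grid truncation points for the SNP and gene
#'   layers.
#' @param prefilter_alpha optional observed-p prefilter (see Details).
#' @param method per-SNP statistic inside permutations, see
#'   [permutation_p_matrix()].
#' @return object of class `artp_result`: `genes` data.frame (gene, n_snps,
#'   gene_p), `pathway_p`, grids, `B`, `seed`.
#' @export
artp_test <- function(study, gene_map, B = 1000L, seed = 1L,
                      covariates = "age", truncation_grid = NULL,
                      gene_grid = NULL, prefilter_alpha = NULL,
                      method = "score") {
  gene_map <- gene_map[vapply(gene_map, length, 1L) > 0L]
  if (length(gene_map) == 0L) stop("no genes with SNPs")
  snps <- sort(unique(unlist(gene_map)))
  pm <- permutation_p_matrix(study, snps, B = B, seed = seed,
                             covariates = covariates, method = method)
  col_of <- setNames(seq_along(snps), snps)
  if (!is.null(prefilter_alpha)) {
    keep_snps <- snps[pm[1L, ] < prefilter_alpha]
    gene_map <- lapply(gene_map, intersect, keep_snps)
    gene_map <- gene_map[vapply(gene_map, length, 1L) > 0L]
    if (length(gene_map) == 0L) stop("prefilter removed every SNP")
  }
  per_gene <- lapply(gene_map, function(idx)
    artp_gene_p(pm[, col_of[as.character(idx)], drop = FALSE],
                truncation_grid = truncation_grid))
  minp <- vapply(per_gene, function(g) g$min_p, numeric(nrow(pm)))
  pw <- artp_pathway_p(minp, gene_grid = gene_grid)
  genes <- data.frame(gene = names(gene_map),
                      n_snps = vapply(gene_map, length, 1L),
                      gene_p = vapply(per_gene, function(g) g$gene_p, 1),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(genes = genes, pathway_p = pw$pathway_p,
                 truncation_grid = per_gene[[1L]]$grid, gene_grid = pw$grid,
                 B = B, seed = seed, per_gene = per_gene,
                 prefilter_alpha = prefilter_alpha),
            class = "artp_result")
}

#' @export
print.artp_result <- function(x, ...) {
  cat("ARTP gene-based pathway test (", x$B, " permutations)\n", sep = "")
  if (!is.null(x$prefilter_alpha))
    cat("  observed-p prefilter:", x$prefilter_alpha,
        "(selection-biased variant)\n")
  cat("  SNP-layer truncation grid:", paste(x$truncation_grid, collapse = " "),
      "\n  gene-layer truncation grid:", paste(x$gene_grid, collapse = " "),
      "\n")
  print.data.frame(x$genes[order(x$genes$gene_p), ], digits = 4,
                   row.names = FALSE)
  cat("Pathway P =", format(x$pathway_p, digits = 4), "\n")
  invisible(x)
}
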