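# EHH / iHH / iHS from phased haplotypes, and the gene-window empirical scan
# for candidate targets of recent positive selection.

#' Extended haplotype homozygosity curve around a core SNP
#'
#' Among the haplotypes carrying the chosen allele at the core, EHH at
#' distance x is the probability that two randomly drawn carriers are
#' identical over the whole segment from the core out to x:
#' `sum_e C(n_e, 2) / C(n_c, 2)` over the distinct extended haplotypes e.
#' Computed by incremental partition refinement in both directions; EHH(0)=1
#' and the curve is non-increasing outward.
#'
#' @param panel a [haplotype_panel()] with the genetic map attached.
#' @param core_index core SNP column.
#' @param allele `"derived"` or `"ancestral"` carrier class.
#' @param floor stop extending once EHH drops below this value (0 = run to
#'   the panel edge or to EHH = 0).
#' @return object of class `ehh_curve`: data.frames `left`/`right` with
#'   columns `index`, `dist_cM` (signed, 0 at the core), `ehh` (the core
#'   point is included in both), flags `reached_floor_left/right`, and the
#'   carrier count.
#' @export
ehh <- function(panel, core_index, allele = c("derived", "ancestral"),
                floor = 0) {
  allele <- match.arg(allele)
  a <- if (allele == "derived") 1L else 0L
  carriers <- which(panel$H[, core_index] == a)
  if (length(carriers) < 2L)
    stop("fewer than 2 carriers of the ", allele, " allele at core ",
         panel$variants$id[core_index])
  cm <- panel$variants$map_cM
  if (anyNA(cm)) stop("genetic map not attached (use add_genetic_map)")
  M <- ncol(panel$H)
  right <- .ehh_decay_cpp(panel$H, carriers - 1L, core_index - 1L, 1L, floor)
  left <- .ehh_decay_cpp(panel$H, carriers - 1L, core_index - 1L, -1L, floor)
  ridx <- core_index + seq_len(length(right$ehh))
  lidx <- core_index - seq_len(length(left$ehh))
  structure(list(
    core_index = core_index, allele = allele,
    n_carriers = length(carriers),
    right = data.frame(index = c(core_index, ridx),
                       dist_cM = cm[c(core_index, ridx)] - cm[core_index],
                       ehh = c(1, right$ehh)),
    left = data.frame(index = c(core_index, lidx),
                      dist_cM = cm[c(core_index, lidx)] - cm[core_index],
                      ehh = c(1, left$ehh)),
    reached_floor_right = right$reached_floor,
    reached_floor_left = left$reached_floor,
    floor = floor), class = "ehh_curve")
}

#' @export
print.ehh_curve <- function(x, ...) {
  cat("EHH curve at core column", x$core_index, "(", x$allele, "allele,",
      x$n_carriers, "carriers )\n")
  cat("  extent:", nrow(x$left) - 1L, "SNPs left,", nrow(x$right) - 1L,
      "SNPs right\n")
  invisible(x)
}

#' @export
plot.ehh_curve <- function(x, ...) {
  d <- rbind(x$left[rev(seq_len(nrow(x$left))), ], x$right[-1L, ])
  graphics::plot(d$dist_cM, d$ehh, type = "l", xlab = "distance from core (cM)",
                 ylab = "EHH", ylim = c(0, 1), ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Integrated EHH (iHH)
#'
#' Trapezoid integration of the EHH curve over genetic distance (cM), each
#' direction truncated after the first point where EHH falls below `floor`
#' (that trapezoid is included); the two directions are summed. The
#' `truncated` flag is set when either direction reaches the panel edge
#' before EHH falls below the floor.
#'
#' @param curve an [ehh()] curve.
#' @param floor EHH integration floor (default 0.05, the usual convention).
#' @return list: `value` (cM), `truncated` (logical).
#' @export
ihh <- function(curve, floor = 0.05) {
  one_side <- function(d) {
    x <- abs(d$dist_cM)
    e <- d$ehh
    if (length(x) < 2L) return(list(v = 0, hit_floor = FALSE))
    stop_at <- which(e < floor)
    last <- if (length(stop_at)) min(stop_at) else length(x)
    seg <- seq_len(last)
    v <- sum(diff(x[seg]) * (head(e[seg], -1L) + e[seg][-1L]) / 2)
    list(v = v, hit_floor = length(stop_at) > 0L)
  }
  if (max(abs(curve$left$dist_cM), abs(curve$right$dist_cM)) == 0)
    stop("zero genetic-map span around the core")
  r <- one_side(curve$right)
  l <- one_side(curve$left)
  list(value = r$v + l$v, truncated = !(r$hit_floor && l$hit_floor))
}

#' Genome-wide iHS scan
#'
#' For every core SNP with minor allele frequency strictly above `maf_min`,
#' computes iHH over ancestral-allele carriers (iHH_A) and derived-allele
#' carriers (iHH_D), the unstandardised score `uiHS = ln(iHH_A / iHH_D)`
#' (negative values mean unusually long derived-allele haplotypes), and the
#' standardised iHS: uiHS centred and scaled within derived-allele-frequency
#' bins of width `bin_width` (bins with fewer than `min_bin_size` SNPs are
#' merged with a neighbour, with a warning). SNPs whose EHH integration was
#' truncated at the panel edge, had a zero iHH, or fewer than 2 carriers of
#' either allele are excluded with a reason code.
#'
#' When `standardize` is a previous `ihs_scan` (e.g. over a genome-wide or
#' neutral reference panel), its per-bin means and standard deviations are
#' applied instead of estimating them from this panel -- the usual procedure
#' when scoring a candidate region, whose own extreme SNPs would otherwise
#' contaminate the frequency bins.
#'
#' @param panel a [haplotype_panel()] with genetic map attached.
#' @param maf_min MAF floor for core SNPs (default 0.05, strict `>`).
#' @param bin_width derived-allele-frequency bin width for standardisation.
#' @param ehh_floor EHH floor for iHH truncation.
#' @param min_bin_size smallest allowed bin before merging.
#' @param standardize optional reference `ihs_scan` supplying bin statistics.
#' @return data.frame of class `ihs_scan`: one row per SNP with `id`,
#'   `chrom`, `pos_bp`, `daf`, `ihh_a`, `ihh_d`, `uihs`, `ihs`, `bin`,
#'   `reason` (`NA` for scored SNPs; excluded SNPs have `ihs = NA`).
#'   Attribute `bin_stats` holds the per-bin mean/sd used.
#' @export
ihs_scan <- function(panel, maf_min = 0.05, bin_width = 0.05,
                     ehh_floor = 0.05, min_bin_size = 10L,
                     standardize = NULL) {
  v <- panel$variants
  if (anyNA(v$map_cM)) stop("genetic map not attached")
  M <- ncol(panel$H)
  daf <- colMeans(panel$H)
  out <- data.frame(id = v$id, chrom = v$chrom, pos_bp = v$pos_bp, daf = daf,
                    ihh_a = NA_real_, ihh_d = NA_real_, uihs = NA_real_,
                    ihs = NA_real_, bin = NA_integer_,
                    reason = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_len(M)) {
    maf <- min(daf[j], 1 - daf[j])
    if (maf <= maf_min) {
      out$reason[j] <- "maf"
      next
    }
    res <- lapply(c("ancestral", "derived"), function(al) {
      cu <- ehh(panel, j, al, floor = ehh_floor)
      ihh(cu, floor = ehh_floor)
    })
    if (res[[1]]$truncated || res[[2]]$truncated) {
      out$reason[j] <- "truncated"
      next
    }
    if (res[[1]]$value <= 0 || res[[2]]$value <= 0) {
      out$reason[j] <- "zero-ihh"
      next
    }
    out$ihh_a[j] <- res[[1]]$value
    out$ihh_d[j] <- res[[2]]$value
    out$uihs[j] <- log(res[[1]]$value / res[[2]]$value)
  }
  scored <- which(!is.na(out$uihs))
  bin_stats <- NULL
  if (length(scored) && !is.null(standardize)) {
    ref <- attr(standardize, "bin_stats")
    if (is.null(ref)) stop("reference scan carries no bin statistics")
    breaks <- seq(0, 1, by = attr(standardize, "bin_width"))
    bin <- findInterval(out$daf[scored], breaks, rightmost.closed = TRUE)
    # map each SNP to the nearest bin present in the reference
    near <- vapply(bin, function(b) ref$bin[which.min(abs(ref$bin - b))], 1L)
    k <- match(near, ref$bin)
    out$ihs[scored] <- (out$uihs[scored] - ref$mean[k]) / ref$sd[k]
    out$bin[scored] <- near
    bin_stats <- ref
  } else if (length(scored)) {
    breaks <- seq(0, 1, by = bin_width)
    bin <- findInterval(out$daf[scored], breaks, rightmost.closed = TRUE)
    # merge sparse bins with their nearest lower (else upper) neighbour
    repeat {
      tb <- table(bin)
      small <- names(tb)[tb < min_bin_size]
      if (length(small) == 0L || length(tb) == 1L) break
      b <- as.integer(small[1L])
      others <- as.integer(names(tb))[as.integer(names(tb)) != b]
      nb <- others[which.min(abs(others - b))]
      bin[bin == b] <- nb
      warning("iHS frequency bin ", b, " has < ", min_bin_size,
              " SNPs; merged with bin ", nb, call. = FALSE)
    }
    stats <- lapply(sort(unique(bin)), function(b) {
      i <- scored[bin == b]
      mu <- mean(out$uihs[i])
      s <- sd(out$uihs[i])
      out$ihs[i] <<- if (is.na(s) || s == 0) 0 else (out$uihs[i] - mu) / s
      data.frame(bin = b, mean = mu, sd = s, n = length(i))
    })
    out$bin[scored] <- bin
    bin_stats <- do.call(rbind, stats)
  }
  attr(out, "bin_stats") <- bin_stats
  attr(out, "bin_width") <- bin_width
  class(out) <- c("ihs_scan", "data.frame")
  out
}

#' @export
print.ihs_scan <- function(x, ...) {
  scored <- sum(!is.na(x$ihs))
  cat("iHS scan:", nrow(x), "SNPs,", scored, "scored;",
      sum(!is.na(x$ihs) & abs(x$ihs) > 2), "with |iHS| > 2\n")
  tab <- table(x$reason[!is.na(x$reason)])
  if (length(tab))
    cat("  exclusions:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' Join association and selection evidence at the SNP level
#'
#' Rows with association `p < alpha` AND `|iHS| > ihs_threshold`, sorted by
#' `|iHS|` descending (published-table shape).
#'
#' @param ihs_records an [ihs_scan()] table (or any data.frame with `id`,
#'   `ihs`).
#' @param assoc_records an `assoc_table` (or any data.frame with `id`, `or_`,
#'   `l95`, `u95`, `p`).
#' @param ihs_threshold |iHS| threshold (default 1.65, the suggestive level).
#' @param alpha association threshold (default 0.05, strict `<`).
#' @return data.frame: `id`, `chrom`, `pos_bp`, `or_`, `l95`, `u95`, `p`,
#'   `ihs`; empty (0 rows) when nothing passes.
#' @export
select_candidate_loci <- function(ihs_records, assoc_records,
                                  ihs_threshold = 1.65, alpha = 0.05) {
  m <- merge(as.data.frame(assoc_records)[, intersect(
    c("id", "chrom", "pos_bp", "or_", "l95", "u95", "p"),
    names(assoc_records))],
    as.data.frame(ihs_records)[, c("id", "ihs")], by = "id")
  keep <- !is.na(m$p) & m$p < alpha & !is.na(m$ihs) & abs(m$ihs) > ihs_threshold
  m <- m[keep, , drop = FALSE]
  m[order(-abs(m$ihs)), , drop = FALSE]
}

#' Gene-window empirical scan for candidate targets of selection
#'
#' For each gene, the index SNP is the scored SNP nearest the gene midpoint;
#' a window of `window_snps` scored SNPs centred on it (clipped at the
#' chromosome ends) is counted for SNPs with `|iHS| > sig_threshold`. The
#' empirical reference is the count in every sliding window of the same size
#' genome-wide; a gene is a candidate iff its count reaches the
#' `(1 - upper_fraction)` quantile of that distribution. The reported
#' `fraction` is the proportion of genome-wide windows with a count at least
#' as large as the gene's (smaller = more extreme).
#'
#' @param ihs_records an [ihs_scan()] table.
#' @param genes data.frame with `name`, `chrom`, `start_bp`, `end_bp`.
#' @param window_snps window size in scored SNPs (default 50).
#' @param sig_threshold |iHS| cut-off defining a significant SNP (default 2).
#' @param upper_fraction tail fraction defining candidates (default 0.10).
#' @return data.frame of class `gene_selection`: `gene`, `index_snp`,
#'   `n_window`, `n_sig`, `fraction`, `candidate`, `short_window`; attribute
#'   `window_counts` holds the genome-wide empirical distribution.
#' @export
gene_window_scan <- function(ihs_records, genes, window_snps = 50L,
                             sig_threshold = 2, upper_fraction = 0.10) {
  x <- as.data.frame(ihs_records)
  x <- x[!is.na(x$ihs), , drop = FALSE]
  x <- x[order(x$chrom, x$pos_bp), , drop = FALSE]
  sig <- as.integer(abs(x$ihs) > sig_threshold)
  # genome-wide sliding-window counts, windows within chromosomes only
  counts <- integer(0)
  per_chrom <- split(seq_len(nrow(x)), x$chrom)
  win_count <- function(s, w) {
    if (length(s) < w) return(sum(s))
    cs <- cumsum(c(0L, s))
    cs[(w + 1L):length(cs)] - cs[seq_len(length(cs) - w)]
  }
  for (idx in per_chrom) counts <- c(counts, win_count(sig[idx], window_snps))
  cut_off <- quantile(counts, 1 - upper_fraction, names = FALSE)
  out <- data.frame(gene = genes$name, index_snp = NA_character_,
                    n_window = NA_integer_, n_sig = NA_integer_,
                    fraction = NA_real_, candidate = NA,
                    short_window = NA, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(genes))) {
    on_chr <- which(x$chrom == genes$chrom[i])
    if (length(on_chr) == 0L) next
    mid <- (genes$start_bp[i] + genes$end_bp[i]) / 2
    idx <- on_chr[which.min(abs(x$pos_bp[on_chr] - mid))]
    pos_in_chr <- match(idx, on_chr)
    half <- window_snps %/% 2L
    lo <- pos_in_chr - half
    hi <- lo + window_snps - 1L
    if (lo < 1L) { lo <- 1L; hi <- min(window_snps, length(on_chr)) }
    if (hi > length(on_chr)) {
      hi <- length(on_chr)
      lo <- max(1L, hi - window_snps + 1L)
    }
    w <- on_chr[lo:hi]
    n_sig <- sum(sig[w])
    out$index_snp[i] <- x$id[idx]
    out$n_window[i] <- length(w)
    out$n_sig[i] <- n_sig
    out$fraction[i] <- mean(counts >= n_sig)
    out$candidate[i] <- n_sig > 0L && n_sig >= cut_off
    out$short_window[i] <- length(w) < window_snps
  }
  attr(out, "window_counts") <- counts
  class(out) <- c("gene_selection", "data.frame")
  out
}

#' @export
print.gene_selection <- function(x, ...) {
  cat("Gene-window selection scan:", nrow(x), "genes,",
      sum(x$candidate, na.rm = TRUE), "candidate(s)\n")
  print.data.frame(as.data.frame(x), digits = 4, row.names = FALSE)
  invisible(x)
}
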