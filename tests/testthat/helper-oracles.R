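# Shared toy builders and independent oracles. The oracles deliberately use
# naive all-pairs / full-enumeration logic so they stay independent of the
# implementation paths they check.

# tiny phased panel from an explicit 0/1 matrix (map at 1 cM/Mb, 2 kb spacing)
toy_panel <- function(H, bp_spacing = 2000, chrom = "1") {
  H <- as.matrix(H)
  pos <- seq_len(ncol(H)) * bp_spacing
  v <- variant_table(id = sprintf("s%03d", seq_len(ncol(H))), chrom = chrom,
                     pos_bp = pos, map_cM = pos / 1e6)
  haplotype_panel(H, v)
}

# brute-force EHH: compare every haplotype pair's full segment explicitly
brute_ehh <- function(H, core, allele, j) {
  carriers <- which(H[, core] == allele)
  n <- length(carriers)
  if (n < 2) return(NA_real_)
  seg <- H[carriers, min(core, j):max(core, j), drop = FALSE]
  same <- 0L
  for (a in 1:(n - 1)) for (b in (a + 1):n)
    if (all(seg[a, ] == seg[b, ])) same <- same + 1L
  same / choose(n, 2)
}

# genotype study built directly from a dosage matrix (skips the panel layer)
toy_study <- function(G, status, age = NULL, chrom = "1", bp_spacing = 2000) {
  G <- as.matrix(G)
  if (is.null(age)) age <- rnorm(nrow(G), 65, 8)
  v <- variant_table(id = sprintf("s%03d", seq_len(ncol(G))), chrom = chrom,
                     pos_bp = seq_len(ncol(G)) * bp_spacing,
                     map_cM = seq_len(ncol(G)) * bp_spacing / 1e6)
  v$effect <- "alt"
  genotype_study(G, v, status, data.frame(age = age))
}

# all distinct case/control assignments with the observed case count,
# as a matrix of 0/1 rows (includes the observed assignment)
enumerate_assignments <- function(n, n_cases) {
  combos <- utils::combn(n, n_cases)
  t(apply(combos, 2L, function(ix) {
    y <- integer(n)
    y[ix] <- 1L
    y
  }))
}

# independent ARTP oracle: naive loops over an explicit (B+1) x L p matrix
oracle_artp <- function(pm, grid) {
  nrep <- nrow(pm)
  grid <- sort(unique(pmin(grid, ncol(pm))))
  W <- matrix(NA_real_, nrep, length(grid))
  for (b in seq_len(nrep)) {
    sp <- sort(pm[b, ])
    for (gk in seq_along(grid)) W[b, gk] <- prod(sp[seq_len(grid[gk])])
  }
  phat <- matrix(NA_real_, nrep, length(grid))
  for (b in seq_len(nrep)) for (gk in seq_along(grid))
    phat[b, gk] <- (1 + sum(W[-b, gk] <= W[b, gk])) / nrep
  minp <- apply(phat, 1L, min)
  (1 + sum(minp[-1L] <= minp[1L])) / nrep
}

# all n! orderings of 1..n, one per row
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}
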