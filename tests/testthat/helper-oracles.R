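# Independent oracles used to cross-check the implementation paths.

# Two-sided minimum-likelihood hypergeometric p by direct enumeration of
# binomial-coefficient point masses (no shared code with fisher_two_sided,
# which works through log-space dhyper).
fisher_oracle <- function(N, K, n, k, tie_tol = 1e-7) {
  if (n == 0 || K == 0 || K == N) return(1)
  supp <- max(0, n + K - N):min(n, K)
  pmf <- choose(K, supp) * choose(N - K, n - supp) / choose(N, n)
  obs <- pmf[match(k, supp)]
  min(1, sum(pmf[pmf <= obs * (1 + tie_tol)]))
}

# Brute-force essentialome rules by direct per-gene counting of line calls
# (NA calls never count as essential).
oracle_essentialomes <- function(calls, fraction = 0.95) {
  stopifnot(is.matrix(calls))
  L <- ncol(calls)
  n_ess <- apply(calls, 1, function(r) sum(r == 1, na.rm = TRUE))
  genes <- rownames(calls)
  list(total = sort(genes[n_ess >= 1]),
       core = sort(genes[n_ess == L]),
       majority = sort(genes[n_ess >= ceiling(fraction * L)]))
}

# Random calls matrix with gene/line labels and optional missingness.
random_calls_matrix <- function(n_genes, n_lines, p = 0.3, na_frac = 0.1) {
  m <- matrix(rbinom(n_genes * n_lines, 1, p), n_genes, n_lines,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("L%02d", seq_len(n_lines))))
  if (na_frac > 0) {
    idx <- which(runif(length(m)) < na_frac)
    m[idx] <- NA
  }
  m
}

# Tiny expression matrix builder: one row per gene, stage means replicated
# exactly (no noise) across `reps` replicates.
flat_expression <- function(stage_means_by_gene, reps = 3,
                            stages = c("early_G1", "late_G1", "S", "G2M")) {
  stopifnot(is.matrix(stage_means_by_gene),
            ncol(stage_means_by_gene) == length(stages))
  cols <- as.vector(t(outer(stages, seq_len(reps), paste, sep = ".")))
  m <- stage_means_by_gene[, rep(seq_along(stages), each = reps), drop = FALSE]
  colnames(m) <- cols
  expression_table(m, stages = stages)
}
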