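#' Cell-cycle expression table
#'
#' TPM values for genes across ordered cell-cycle stages with replicates,
#' as produced by RNA-seq of FUCCI-sorted populations (early G1, late G1,
#' S, G2/M by default). Columns of the matrix are named `<stage>.<rep>`.
#'
#' @param tpm numeric gene x (stage, replicate) matrix, non-negative, with
#'   gene rownames and `<stage>.<rep>` colnames.
#' @param stages ordered stage labels (default the four FUCCI stages).
#' @return an object of class `expression_table`.
#' @export
expression_table <- function(tpm, stages = c("early_G1", "late_G1", "S", "G2M")) {
  stopifnot(is.matrix(tpm), is.numeric(tpm),
            !is.null(rownames(tpm)), !is.null(colnames(tpm)))
  if (any(tpm[!is.na(tpm)] < 0)) stop("TPM values must be >= 0", call. = FALSE)
  col_stage <- sub("\\.[^.]*$", "", colnames(tpm))
  unknown <- setdiff(unique(col_stage), stages)
  if (length(unknown) > 0)
    stop("columns name stage(s) outside the stage ladder: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(stages, col_stage)
  if (length(missing) > 0)
    stop("stage(s) without any replicate column: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rownames(tpm) <- normalize_gene_ids(rownames(tpm), dedupe = FALSE)
  structure(list(tpm = tpm, stages = stages, col_stage = col_stage),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  reps <- table(factor(x$col_stage, levels = x$stages))
  cat(sprintf("<expression_table> %d genes x %d stages (replicates: %s)\n",
              nrow(x$tpm), length(x$stages),
              paste(as.integer(reps), collapse = "/")))
  invisible(x)
}

#' Read a TPM expression table from TSV
#'
#' First column gene symbols, remaining columns `<stage>.<rep>`.
#'
#' @param path TSV file path.
#' @param stages ordered stage labels.
#' @return an [expression_table()].
#' @export
read_expression_table <- function(path, stages = c("early_G1", "late_G1",
                                                   "S", "G2M")) {
  expression_table(read_matrix(path, sep = "\t"), stages = stages)
}

stage_means <- function(table) {
  out <- sapply(table$stages, function(s) {
    cols <- which(table$col_stage == s)
    rowMeans(table$tpm[, cols, drop = FALSE], na.rm = TRUE)
  })
  if (!is.matrix(out)) {
    out <- matrix(out, nrow = 1,
                  dimnames = list(rownames(table$tpm), table$stages))
  }
  out
}

#' Per-gene, per-stage expressed flags
#'
#' A gene counts as expressed in a stage iff its replicate-mean TPM in that
#' stage is at or above the threshold (inclusive; the canonical rule is
#' TPM >= 1). `per_replicate = TRUE` instead requires every replicate to
#' clear the threshold.
#'
#' @param table an [expression_table()].
#' @param threshold positive TPM cutoff (default 1).
#' @param per_replicate require all replicates >= threshold instead of the
#'   replicate mean (default FALSE).
#' @return logical gene x stage matrix.
#' @export
expressed_flags <- function(table, threshold = 1, per_replicate = FALSE) {
  stopifnot(inherits(table, "expression_table"),
            is.numeric(threshold), threshold > 0)
  if (per_replicate) {
    flags <- sapply(table$stages, function(s) {
      cols <- which(table$col_stage == s)
      apply(table$tpm[, cols, drop = FALSE] >= threshold, 1, all, na.rm = TRUE)
    })
    if (!is.matrix(flags)) {
      flags <- matrix(flags, nrow = 1,
                      dimnames = list(rownames(table$tpm), table$stages))
    }
  } else {
    flags <- stage_means(table) >= threshold
  }
  rownames(flags) <- rownames(table$tpm)
  flags
}

#' Classify genes by breadth of cell-cycle expression
#'
#' `expressed_all`: expressed in every stage; `expressed_some`: in at least
#' one stage; `not_expressed`: in none.
#'
#' @param flags logical gene x stage matrix from [expressed_flags()].
#' @return factor (levels `not_expressed`, `expressed_some`,
#'   `expressed_all`) named by gene.
#' @export
classify_expression <- function(flags) {
  stopifnot(is.logical(flags), is.matrix(flags))
  n_on <- rowSums(flags)
  cat <- ifelse(n_on == ncol(flags), "expressed_all",
                ifelse(n_on >= 1, "expressed_some", "not_expressed"))
  factor(stats::setNames(cat, rownames(flags)),
         levels = c("not_expressed", "expressed_some", "expressed_all"))
}

#' Flag successive-stage differential expression
#'
#' For each ordered pair of successive stages (early G1 to late G1, late G1
#' to S, S to G2/M), tests each gene for a stage-to-stage expression shift.
#' The default `"welch"` method applies a two-sample Welch t-test on
#' log2(TPM + 1) across replicates and flags pairs with p < alpha. A gene's
#' overall DE verdict is the OR over its stage pairs. For replicate-poor
#' tables the `"fold_change"` method flags pairs whose stage-mean fold
#' change (on TPM + 1) is at least `min_fold`.
#'
#' @param table an [expression_table()].
#' @param alpha significance level per stage pair (default 0.05).
#' @param method `"welch"` (default; needs >= 2 replicates per stage) or
#'   `"fold_change"`.
#' @param min_fold fold-change cutoff for the `"fold_change"` method
#'   (default 2).
#' @return list with `pairs` (character vector of stage-pair labels),
#'   `p` (gene x pair matrix; NA for the fold-change method), `flag`
#'   (logical gene x pair matrix) and `de` (named logical per-gene
#'   verdict).
#' @export
successive_stage_de <- function(table, alpha = 0.05,
                                method = c("welch", "fold_change"),
                                min_fold = 2) {
  method <- match.arg(method)
  stopifnot(inherits(table, "expression_table"),
            is.numeric(alpha), alpha > 0, alpha < 1)
  stages <- table$stages
  pairs <- paste(stages[-length(stages)], stages[-1], sep = "->")
  nrep <- table(factor(table$col_stage, levels = stages))
  if (method == "welch" && any(nrep < 2)) {
    stop("the welch method needs >= 2 replicates per stage; use ",
         'method = "fold_change" for replicate-poor tables', call. = FALSE)
  }
  G <- nrow(table$tpm)
  p <- matrix(NA_real_, G, length(pairs),
              dimnames = list(rownames(table$tpm), pairs))
  flag <- matrix(FALSE, G, length(pairs),
                 dimnames = list(rownames(table$tpm), pairs))
  if (method == "welch") {
    logt <- log2(table$tpm + 1)
    for (j in seq_along(pairs)) {
      a <- logt[, table$col_stage == stages[j], drop = FALSE]
      b <- logt[, table$col_stage == stages[j + 1], drop = FALSE]
      p[, j] <- welch_p_rows(a, b)
      flag[, j] <- !is.na(p[, j]) & p[, j] < alpha
    }
  } else {
    sm <- stage_means(table) + 1
    for (j in seq_along(pairs)) {
      fc <- sm[, j + 1] / sm[, j]
      flag[, j] <- pmax(fc, 1 / fc) >= min_fold
    }
  }
  list(pairs = pairs, p = p, flag = flag,
       de = stats::setNames(rowSums(flag) > 0, rownames(table$tpm)))
}

# vectorized two-sample Welch t-test across matrix rows
welch_p_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  # degenerate zero-variance pairs: equal means carry no evidence of
  # change; different means are an exact step
  zero <- !is.na(se2) & se2 == 0
  p[zero & mb == ma] <- 1
  p[zero & mb != ma] <- 0
  p
}

#' Summary report of cell-cycle expression stability
#'
#' Combines expressed-stage classification and successive-stage DE into the
#' headline counts: how many genes are expressed in at least one stage, in
#' all stages, and how many expressed genes are differentially expressed
#' between successive stages (with the percentage of expressed genes that
#' are DE).
#'
#' @param table an [expression_table()].
#' @param genes optional gene list/character vector restricting the report
#'   (e.g. the MIGs); defaults to all genes in the table.
#' @param threshold TPM cutoff for expression (default 1).
#' @param alpha DE significance level (default 0.05).
#' @param method DE method, see [successive_stage_de()].
#' @return list with `n_genes`, `n_expressed_some`, `n_expressed_all`,
#'   `n_de` (DE among expressed-some genes), `pct_de` (percentage, two
#'   decimals) and the underlying `classification` and `de` objects.
#' @export
cellcycle_report <- function(table, genes = NULL, threshold = 1,
                             alpha = 0.05, method = "welch") {
  stopifnot(inherits(table, "expression_table"))
  if (!is.null(genes)) {
    keep <- intersect(rownames(table$tpm), as_gene_list(genes)$members)
    table <- expression_table(table$tpm[keep, , drop = FALSE],
                              stages = table$stages)
  }
  flags <- expressed_flags(table, threshold = threshold)
  cls <- classify_expression(flags)
  de <- successive_stage_de(table, alpha = alpha, method = method)
  expressed <- names(cls)[cls != "not_expressed"]
  n_de <- sum(de$de[expressed])
  list(n_genes = nrow(table$tpm),
       n_expressed_some = length(expressed),
       n_expressed_all = sum(cls == "expressed_all"),
       n_de = n_de,
       pct_de = if (length(expressed) > 0)
         round(100 * n_de / length(expressed), 2) else NA_real_,
       classification = cls, de = de)
}
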