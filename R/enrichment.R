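#' 2x2 contingency table for gene-set overrepresentation
#'
#' Counts for the classical urn setup: a universe of `N` genes of which `K`
#' carry the feature (e.g. are MIGs), a query set of `n` genes (e.g. an
#' essentialome) of which `k` carry the feature.
#'
#' @param N universe size.
#' @param K feature count in the universe.
#' @param n query size.
#' @param k feature count in the query.
#' @param labels optional named character vector (`feature`, `query`,
#'   `universe`) for reporting.
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(N, K, n, k, labels = NULL) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (!all(is.finite(vals)) || any(vals < 0) || any(vals != floor(vals)))
    stop("N, K, n, k must be non-negative integers", call. = FALSE)
  if (K > N || n > N) stop("K and n cannot exceed N", call. = FALSE)
  if (k > min(n, K) || k < max(0, n + K - N))
    stop(sprintf("k = %d outside the feasible range [%d, %d]",
                 k, max(0, n + K - N), min(n, K)), call. = FALSE)
  structure(list(N = as.integer(N), K = as.integer(K),
                 n = as.integer(n), k = as.integer(k),
                 labels = labels),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> k/n = %d/%d vs K/N = %d/%d\n",
              x$k, x$n, x$K, x$N))
  m <- matrix(c(x$k, x$n - x$k, x$K - x$k, x$N - x$n - x$K + x$k),
              2, 2, byrow = TRUE,
              dimnames = list(c("query", "background"),
                              c("feature", "other")))
  print(m)
  invisible(x)
}

#' Build a contingency table from gene lists
#'
#' Restricts query and feature to the universe, then counts the 2x2 cells.
#' Under the default `universe_includes_query` convention the query is part
#' of the background (the table margins sum to `N`) — this is the convention
#' that reproduces the published worked examples of this pipeline. Under
#' `universe_excludes_query` the query is removed from the universe before
#' the background margin is counted, so the comparison is query versus the
#' rest.
#'
#' @param query a [gene_list()] or character vector (e.g. an essentialome).
#' @param feature a [gene_list()] or character vector (e.g. the MIG list).
#' @param universe a [gene_universe()] or [gene_list()]/character vector.
#' @param convention background convention (see Details).
#' @return a [contingency_table()].
#' @export
build_table <- function(query, feature, universe,
                        convention = c("universe_includes_query",
                                       "universe_excludes_query")) {
  convention <- match.arg(convention)
  query <- as_gene_list(query, name = "query")
  feature <- as_gene_list(feature, name = "feature")
  uni <- if (inherits(universe, "gene_universe")) universe_genes(universe)
         else as_gene_list(universe)$members
  q <- restrict_to_universe(query, uni)$members
  f <- restrict_to_universe(feature, uni)$members
  k <- length(intersect(q, f))
  labels <- c(feature = feature$name, query = query$name,
              universe = "universe")
  if (convention == "universe_includes_query") {
    contingency_table(N = length(uni), K = length(f),
                      n = length(q), k = k, labels = labels)
  } else {
    # background margin = universe minus query; the joint 2x2 has the query
    # stacked on that background (for a query inside the universe the cells
    # coincide with the includes convention; the conventions differ when
    # background totals are supplied externally, as printed genome counts)
    bg <- setdiff(uni, q)
    contingency_table(N = length(q) + length(bg),
                      K = k + length(intersect(f, bg)),
                      n = length(q), k = k,
                      labels = c(labels, convention = convention))
  }
}

# log hypergeometric mass over the full support of a table
.hyper_support <- function(N, K, n) max(0L, n + K - N):min(n, K)

#' Exact two-sided Fisher p-value
#'
#' Exact hypergeometric test with the minimum-likelihood two-sided rule: the
#' p-value sums P(X = x) over every x in the support whose point mass does
#' not exceed P(X = k), with a 1e-7 relative tolerance for ties. The mass is
#' evaluated in log space, so tables at genome scale (N > 20,000) remain
#' exact; no normal approximation is ever used. Degenerate tables (n = 0,
#' K = 0 or K = N) return p = 1.
#'
#' @param table a [contingency_table()], or `N` when giving counts directly.
#' @param K,n,k optional direct counts (used when `table` is numeric `N`).
#' @param tie_tol relative tolerance for point-mass ties (default 1e-7).
#' @return two-sided p-value in \[0, 1\].
#' @examples
#' fisher_two_sided(contingency_table(N = 20444, K = 648, n = 742, k = 33))
#' @export
fisher_two_sided <- function(table, K = NULL, n = NULL, k = NULL,
                             tie_tol = 1e-7) {
  if (inherits(table, "contingency_table")) {
    N <- table$N; K <- table$K; n <- table$n; k <- table$k
  } else {
    N <- table
    stopifnot(!is.null(K), !is.null(n), !is.null(k))
  }
  if (n == 0 || K == 0 || K == N) return(1)
  supp <- .hyper_support(N, K, n)
  logp <- stats::dhyper(supp, K, N - K, n, log = TRUE)
  obs <- logp[match(k, supp)]
  # ties: include x with P(x) <= P(k) * (1 + tie_tol)
  p <- sum(exp(logp[logp <= obs + log1p(tie_tol)]))
  min(1, p)
}

#' Fold enrichment of a feature in a query set
#'
#' The ratio of the feature's frequency in the query to its frequency in
#' the universe, `(k/n) / (K/N)`, computed on unrounded fractions. Reports
#' conventionally round to one decimal (see [format_fold()]).
#'
#' @param table a [contingency_table()].
#' @return numeric fold enrichment.
#' @export
fold_enrichment <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  if (table$K == 0 || table$n == 0)
    stop("fold enrichment undefined for K = 0 or n = 0", call. = FALSE)
  (table$k / table$n) / (table$K / table$N)
}

#' One-decimal fold for reporting
#' @param fold numeric fold value (e.g. from [fold_enrichment()]).
#' @return fold rounded to one decimal.
#' @export
format_fold <- function(fold) round(fold, 1)

#' Full enrichment result for one feature list
#'
#' Combines the contingency table, fractions, fold, odds ratio, exact
#' two-sided p and direction into one record.
#'
#' @inheritParams build_table
#' @return an object of class `enrichment_result`.
#' @export
enrich_test <- function(query, feature, universe,
                        convention = c("universe_includes_query",
                                       "universe_excludes_query")) {
  tab <- build_table(query, feature, universe, convention)
  enrichment_result(tab)
}

#' Derive an enrichment result from a contingency table
#'
#' @param table a [contingency_table()].
#' @return an object of class `enrichment_result` with fields `table`,
#'   `query_fraction`, `universe_fraction`, `fold`, `odds_ratio`,
#'   `p_two_sided`, `direction` and (optionally, set by
#'   [control_battery()]) `p_adjusted`.
#' @export
enrichment_result <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  qf <- if (table$n > 0) table$k / table$n else NA_real_
  uf <- if (table$N > 0) table$K / table$N else NA_real_
  a <- table$k
  b <- table$n - table$k
  cc <- table$K - table$k
  d <- table$N - table$n - table$K + table$k
  or <- if (b * cc == 0) Inf else (a * d) / (b * cc)
  direction <- if (is.na(qf) || is.na(uf) || qf == uf) "none"
               else if (qf > uf) "enriched" else "depleted"
  structure(
    list(table = table,
         query_fraction = qf,
         universe_fraction = uf,
         fold = if (table$K > 0 && table$n > 0) qf / uf else NA_real_,
         odds_ratio = or,
         p_two_sided = fisher_two_sided(table),
         direction = direction,
         p_adjusted = NA_real_),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  lab <- x$table$labels
  cat(sprintf("<enrichment_result> %s in %s\n",
              if (!is.null(lab)) lab[["feature"]] else "feature",
              if (!is.null(lab)) lab[["query"]] else "query"))
  cat(sprintf("  %d/%d (%.1f%%) vs %d/%d (%.1f%%): %.1f-fold, %s\n",
              x$table$k, x$table$n, 100 * x$query_fraction,
              x$table$K, x$table$N, 100 * x$universe_fraction,
              format_fold(x$fold), x$direction))
  cat(sprintf("  two-sided P = %.3g\n", x$p_two_sided))
  invisible(x)
}

#' Run an enrichment battery of feature lists against one query
#'
#' Tests each feature list (e.g. MIGs plus control lists sharing a function
#' or a feature: intronic-miRNA hosts, kinome, transcription factors,
#' cell-cycle genes) against the same query and universe. Raw p-values are
#' reported by default, matching the single-test reporting convention of
#' the source analyses; Benjamini-Hochberg adjustment across the battery is
#' available via `adjust = "BH"`.
#'
#' @param query a [gene_list()] or character vector.
#' @param features a (possibly named) list of feature gene lists.
#' @param universe a [gene_universe()] or gene list/character vector.
#' @param convention background convention, see [build_table()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return named list of `enrichment_result`, one per feature list.
#' @export
control_battery <- function(query, features, universe,
                            convention = c("universe_includes_query",
                                           "universe_excludes_query"),
                            adjust = c("none", "BH")) {
  convention <- match.arg(convention)
  adjust <- match.arg(adjust)
  stopifnot(is.list(features))
  if (length(features) == 0) return(list())
  out <- lapply(features, function(f)
    enrich_test(query, f, universe, convention))
  if (adjust == "BH") {
    padj <- stats::p.adjust(vapply(out, `[[`, numeric(1), "p_two_sided"),
                            method = "BH")
    for (i in seq_along(out)) out[[i]]$p_adjusted <- padj[[i]]
  }
  if (is.null(names(out)))
    names(out) <- vapply(out, function(r) r$table$labels[["feature"]],
                         character(1))
  out
}
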