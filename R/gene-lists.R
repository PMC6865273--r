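#' Normalize raw gene symbols
#'
#' Gene identifiers across the source datasets (CRISPR screens, the minor
#' intron database, ortholog tables, domestication-gene supplements) are
#' symbol-keyed but vary in case and stray whitespace. Normalization maps a
#' raw symbol to its canonical form: whitespace-stripped and upper-cased.
#' Duplicates (after normalization) are collapsed to their first occurrence,
#' preserving input order. An optional alias map rewrites known symbol drift
#' (e.g. outdated aliases) after case/whitespace normalization.
#'
#' @param raw character vector of raw gene symbols.
#' @param alias optional named character vector mapping normalized alias
#'   symbols to their canonical replacement (names = alias, values = target).
#' @param dedupe collapse duplicates to first occurrence (default TRUE).
#' @return character vector of normalized symbols.
#' @examples
#' normalize_gene_ids(c("rnpc3", " BRAF", "RNPC3"))
#' @export
normalize_gene_ids <- function(raw, alias = NULL, dedupe = TRUE) {
  if (!is.character(raw)) {
    bad <- if (is.null(raw)) "NULL" else class(raw)[1]
    stop("gene symbols must be character, got ", bad, call. = FALSE)
  }
  out <- toupper(trimws(raw))
  bad <- which(is.na(out) | out == "")
  if (length(bad) > 0) {
    stop("empty or missing gene symbol at index ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(alias)) {
    stopifnot(is.character(alias), !is.null(names(alias)))
    hit <- match(out, toupper(trimws(names(alias))))
    out[!is.na(hit)] <- toupper(trimws(alias))[hit[!is.na(hit)]]
  }
  if (dedupe) out <- out[!duplicated(out)]
  out
}

#' Construct a named gene list
#'
#' A `gene_list` is an ordered collection of unique, normalized gene symbols
#' with a name and a free-text provenance note. It is the common currency of
#' the pipeline: MIG lists, control batteries, essentialomes and
#' domestication-candidate lists are all gene lists.
#'
#' @param members character vector of gene symbols (normalized on input).
#' @param name label for the list.
#' @param provenance free-text source note.
#' @param alias optional alias map passed to [normalize_gene_ids()].
#' @return an object of class `gene_list`.
#' @export
gene_list <- function(members, name = "gene_list", provenance = "", alias = NULL) {
  members <- if (length(members) == 0) character(0)
             else normalize_gene_ids(members, alias = alias)
  structure(
    list(name = as.character(name)[1],
         members = members,
         provenance = as.character(provenance)[1]),
    class = "gene_list"
  )
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("<gene_list> %s: %d genes\n", x$name, length(x$members)))
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  show <- utils::head(x$members, 6)
  cat("  ", paste(show, collapse = ", "),
      if (length(x$members) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_list <- function(x) length(x$members)

as_gene_list <- function(x, name = "gene_list", provenance = "") {
  if (inherits(x, "gene_list")) x else gene_list(x, name, provenance)
}

#' Construct the interrogated gene universe
#'
#' The universe is the set of genes a screen interrogated, together with
#' per-gene annotations: a mandatory MIG flag (does the gene carry a minor
#' intron), an optional gene-family label, and an optional age clade from
#' phylostratigraphic assignment. All downstream enrichment statistics are
#' counted against this universe.
#'
#' @param interrogated a [gene_list()] (or character vector) of interrogated
#'   genes.
#' @param is_mig logical vector (parallel to the members, or named by gene)
#'   flagging minor intron-containing genes. Recycled if length 1.
#' @param family optional character vector of gene-family labels (`NA` for
#'   genes outside any family).
#' @param age_clade optional character vector of age-clade labels.
#' @return an object of class `gene_universe`.
#' @export
gene_universe <- function(interrogated, is_mig, family = NULL, age_clade = NULL) {
  interrogated <- as_gene_list(interrogated, name = "interrogated")
  g <- interrogated$members
  align <- function(v, what, default = NA_character_) {
    if (is.null(v)) return(rep(default, length(g)))
    if (!is.null(names(v))) {
      out <- v[match(g, normalize_gene_ids(names(v), dedupe = FALSE))]
      names(out) <- NULL
      return(out)
    }
    if (length(v) == 1) return(rep(v, length(g)))
    if (length(v) != length(g)) {
      stop(what, " must be length 1, named, or parallel to the universe (",
           length(g), " genes)", call. = FALSE)
    }
    v
  }
  mig <- align(is_mig, "is_mig", default = NA)
  if (anyNA(mig)) stop("is_mig must be defined (TRUE/FALSE) for every gene",
                       call. = FALSE)
  structure(
    list(interrogated = interrogated,
         annotations = data.frame(
           gene = g,
           is_mig = as.logical(mig),
           family = as.character(align(family, "family")),
           age_clade = as.character(align(age_clade, "age_clade")),
           stringsAsFactors = FALSE)),
    class = "gene_universe"
  )
}

#' @export
print.gene_universe <- function(x, ...) {
  ann <- x$annotations
  cat(sprintf("<gene_universe> %d genes, %d MIGs (%.1f%%)\n",
              nrow(ann), sum(ann$is_mig), 100 * mean(ann$is_mig)))
  if (any(!is.na(ann$age_clade))) {
    cat("  age clades assigned for ", sum(!is.na(ann$age_clade)),
        " genes\n", sep = "")
  }
  invisible(x)
}

#' Universe members as a character vector
#' @param universe a [gene_universe()].
#' @return character vector of gene symbols.
#' @export
universe_genes <- function(universe) {
  stopifnot(inherits(universe, "gene_universe"))
  universe$interrogated$members
}

#' MIGs of a universe as a gene list
#' @param universe a [gene_universe()].
#' @return a [gene_list()] of the universe's MIGs.
#' @export
universe_migs <- function(universe) {
  stopifnot(inherits(universe, "gene_universe"))
  ann <- universe$annotations
  gene_list(ann$gene[ann$is_mig], name = "MIGs",
            provenance = "is_mig flag of the gene universe")
}

#' Restrict a gene list to the interrogated universe
#'
#' Genes in a feature list that the screen never interrogated cannot be
#' counted in any contingency table, so they are dropped before analysis
#' (mirroring the exclusion of MIGs absent from the guide library). Order of
#' the input list is preserved; the provenance note records the sizes before
#' and after restriction.
#'
#' @param list a [gene_list()] (or character vector).
#' @param universe a [gene_universe()] or a [gene_list()]/character vector
#'   to intersect with.
#' @return a [gene_list()] containing only interrogated members.
#' @export
restrict_to_universe <- function(list, universe) {
  list <- as_gene_list(list)
  uni <- if (inherits(universe, "gene_universe")) universe_genes(universe)
         else as_gene_list(universe)$members
  keep <- list$members[list$members %in% uni]
  gene_list(keep, name = list$name,
            provenance = sprintf("%s; restricted to universe (before=%d, after=%d)",
                                 list$provenance, length(list$members), length(keep)))
}
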