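#' Candidate domestication gene (CDG) collection
#'
#' One curated gene list per domesticated (or self-domesticated) species —
#' dog, cat, cattle, horse and human in the canonical five-species setup.
#' Lists are assumed pre-mapped to a shared symbol space; symbols are
#' normalized (optionally through a shared alias map) so cross-species
#' comparisons are by identical symbol.
#'
#' @param species_lists named list: species label -> [gene_list()] or
#'   character vector.
#' @param alias optional alias map applied to every list.
#' @return an object of class `cdg_collection`.
#' @export
cdg_collection <- function(species_lists, alias = NULL) {
  stopifnot(is.list(species_lists), length(species_lists) >= 1,
            !is.null(names(species_lists)),
            !anyDuplicated(names(species_lists)))
  lists <- lapply(names(species_lists), function(sp) {
    x <- species_lists[[sp]]
    if (inherits(x, "gene_list")) x
    else gene_list(x, name = sp, alias = alias,
                   provenance = paste0("CDG list: ", sp))
  })
  names(lists) <- names(species_lists)
  structure(list(species_lists = lists), class = "cdg_collection")
}

#' @export
print.cdg_collection <- function(x, ...) {
  sizes <- vapply(x$species_lists, function(l) length(l$members), integer(1))
  cat(sprintf("<cdg_collection> %d species: %s\n", length(sizes),
              paste(sprintf("%s (%d)", names(sizes), sizes), collapse = ", ")))
  invisible(x)
}

#' Genes shared among at least a number of species
#'
#' Returns the genes present in at least `min_species` of the per-species
#' CDG lists; `min_species = 1` is the union. `exact = TRUE` keeps genes in
#' exactly `min_species` lists instead.
#'
#' @param collection a [cdg_collection()].
#' @param min_species minimum number of species lists a gene must appear in.
#' @param exact require exactly `min_species` lists (default FALSE).
#' @return a [gene_list()] of shared genes.
#' @export
shared_cdg <- function(collection, min_species = 2, exact = FALSE) {
  stopifnot(inherits(collection, "cdg_collection"),
            is.numeric(min_species), min_species >= 1)
  n_sp <- length(collection$species_lists)
  if (min_species > n_sp) {
    warning("min_species (", min_species, ") exceeds the number of species (",
            n_sp, "); result is empty", call. = FALSE)
  }
  counts <- table(unlist(lapply(collection$species_lists, `[[`, "members"),
                        use.names = FALSE))
  keep <- if (exact) counts == min_species else counts >= min_species
  gene_list(sort(names(counts)[keep]),
            name = sprintf("cdg_shared_%s%d", if (exact) "eq" else "ge",
                           as.integer(min_species)),
            provenance = sprintf("genes in %s%d of %d species CDG lists",
                                 if (exact) "exactly " else ">=",
                                 as.integer(min_species), n_sp))
}

#' Overlap of two gene sets with percentage of the first
#'
#' Reports the intersection size and its share of `setA`, rounded to two
#' decimals for reporting (e.g. 4 of 51 shared CDGs being MIGs = 7.84%).
#'
#' @param setA,setB gene lists or character vectors.
#' @return list with `count`, `percentage` (of `|A|`; `NA` when `A` is
#'   empty) and `genes` (the intersection).
#' @export
overlap_report <- function(setA, setB) {
  a <- as_gene_list(setA)$members
  b <- as_gene_list(setB)$members
  shared <- intersect(a, b)
  list(count = length(shared),
       percentage = if (length(a) > 0)
         round(100 * length(shared) / length(a), 2) else NA_real_,
       genes = shared)
}

#' Family map for collapsing gene families
#'
#' Disjoint, non-empty gene families (e.g. minor-intron-rich families such
#' as CRTC, PROX, ERICH) descended from a single ancestral gene.
#'
#' @param families named list: family label -> character vector of member
#'   genes.
#' @return an object of class `family_map`.
#' @export
family_map <- function(families) {
  stopifnot(is.list(families), !is.null(names(families)) || length(families) == 0)
  families <- lapply(families, function(m) normalize_gene_ids(as.character(m)))
  if (any(lengths(families) == 0))
    stop("every family must have at least one member", call. = FALSE)
  all_members <- unlist(families, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    dup <- unique(all_members[duplicated(all_members)])
    stop("families must be disjoint; gene(s) in several families: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(list(families = families), class = "family_map")
}

#' Count minor-intron gain events by family collapsing
#'
#' Each gene family descended from one ancestral minor-intron-containing
#' gene represents a single minor-intron gain event, however many present
#' family members carry the intron today. The event count is therefore the
#' number of input genes outside any family plus the number of families
#' with at least one member present (e.g. 59 younger MIGs with families of
#' sizes 3, 2 and 2 collapse to 55 gain events). Family members absent from
#' the input are ignored with a warning.
#'
#' @param migs a [gene_list()] or character vector of MIGs.
#' @param families a [family_map()].
#' @return integer number of gain events.
#' @export
collapse_gain_events <- function(migs, families) {
  migs <- as_gene_list(migs)$members
  stopifnot(inherits(families, "family_map"))
  fam <- families$families
  absent <- setdiff(unlist(fam, use.names = FALSE), migs)
  if (length(absent) > 0) {
    warning("family member(s) not in the input gene list ignored: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  present_per_family <- vapply(fam, function(m) sum(m %in% migs), integer(1))
  in_family <- migs %in% unlist(fam, use.names = FALSE)
  as.integer(sum(!in_family) + sum(present_per_family >= 1))
}

#' MIG enrichment among CDGs against a fixed genome background
#'
#' The domestication analyses compare CDG lists against the whole
#' protein-coding genome, not a screen universe: the background is supplied
#' as fixed printed counts (canonically 648 MIGs of 20,444 protein-coding
#' genes) rather than as gene lists.
#'
#' @param n_query CDG query size (e.g. 742 human CDGs, or 1,386 pooled).
#' @param k_mig number of MIGs in the query.
#' @param background_mig number of MIGs in the genome background
#'   (default 648).
#' @param background_total genome background size (default 20444).
#' @return an `enrichment_result`.
#' @export
cdg_mig_enrichment <- function(n_query, k_mig,
                               background_mig = 648,
                               background_total = 20444) {
  tab <- contingency_table(N = background_total, K = background_mig,
                           n = n_query, k = k_mig,
                           labels = c(feature = "MIGs", query = "CDGs",
                                      universe = "protein-coding genome"))
  enrichment_result(tab)
}
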