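#' Ordered ladder of evolutionary age clades
#'
#' Phylostratigraphy assigns each gene the oldest taxonomic clade in which
#' it has detectable orthologs. The ladder orders clade labels from oldest
#' to youngest and marks the "ancient" boundary: genes at or before the
#' boundary clade are ancient (tracing back to the last eukaryotic common
#' ancestor, LECA, or earlier); everything after is younger. The default
#' ladder collapses all pre-LECA ages into the single oldest rung,
#' Eukaryota.
#'
#' @param clades character vector of clade labels, oldest first.
#' @param ancient_boundary clade label closing the ancient stratum
#'   (default: the oldest clade).
#' @return an object of class `clade_ladder`.
#' @export
clade_ladder <- function(clades = default_clades(),
                         ancient_boundary = clades[1]) {
  stopifnot(is.character(clades), length(clades) >= 1,
            !anyDuplicated(clades), ancient_boundary %in% clades)
  structure(list(clades = clades, ancient_boundary = ancient_boundary),
            class = "clade_ladder")
}

#' Default clade ladder (oldest to youngest)
#' @return character vector of the ten default clade labels.
#' @export
default_clades <- function() {
  c("Eukaryota", "Opisthokonta", "Metazoa", "Eumetazoa", "Bilateria",
    "Deuterostomia", "Chordata", "Euteleostomi", "Amniota",
    "species_specific")
}

#' @export
print.clade_ladder <- function(x, ...) {
  cat("<clade_ladder> oldest -> youngest:\n  ",
      paste(x$clades, collapse = " > "), "\n", sep = "")
  cat("  ancient boundary: ", x$ancient_boundary, "\n", sep = "")
  invisible(x)
}

#' Read a clade ladder from a YAML file
#'
#' Expects keys `clades` (ordered list, oldest first) and optionally
#' `ancient_boundary`.
#'
#' @param path YAML file path.
#' @return a [clade_ladder()].
#' @export
read_clade_ladder <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$clades)) stop("ladder YAML needs a 'clades' key", call. = FALSE)
  clade_ladder(as.character(unlist(y$clades)),
               ancient_boundary = if (!is.null(y$ancient_boundary))
                 y$ancient_boundary else as.character(unlist(y$clades))[1])
}

#' Ortholog-group membership records
#'
#' Long-format records of gene membership in orthologous groups resolved at
#' taxonomic levels (eggNOG style): one row per (gene, group, clade).
#'
#' @param gene character vector of gene symbols.
#' @param group_id character vector of ortholog-group identifiers.
#' @param clade character vector of clade labels.
#' @return an object of class `ortholog_membership` (a data frame).
#' @export
ortholog_membership <- function(gene, group_id, clade) {
  df <- data.frame(gene = normalize_gene_ids(gene, dedupe = FALSE),
                   group_id = as.character(group_id),
                   clade = as.character(clade),
                   stringsAsFactors = FALSE)
  class(df) <- c("ortholog_membership", "data.frame")
  df
}

#' Read ortholog membership from TSV
#'
#' Expects a header with columns `gene`, `group_id`, `clade`.
#'
#' @param path TSV file path.
#' @return an [ortholog_membership()].
#' @export
read_ortholog_membership <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene", "group_id", "clade")
  if (!all(need %in% names(df)))
    stop("membership TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ortholog_membership(df$gene, df$group_id, df$clade)
}

#' Assign evolutionary ages from ortholog-group membership
#'
#' Each gene receives the oldest clade among its ortholog-group memberships.
#' Genes with no membership record carry the standard phylostratigraphic
#' signal of recency — no detectable orthologs — and are assigned the
#' youngest ladder clade while being tracked in `unassigned`; `strict
#' = TRUE` leaves them out of `ages` entirely.
#'
#' @param genes a [gene_list()] or character vector of genes to age.
#' @param membership an [ortholog_membership()].
#' @param ladder a [clade_ladder()].
#' @param strict if TRUE, unassigned genes get `NA` instead of the youngest
#'   clade.
#' @return an object of class `gene_age_map` with fields `ages` (named
#'   character vector) and `unassigned` (character vector).
#' @export
assign_gene_age <- function(genes, membership, ladder = clade_ladder(),
                            strict = FALSE) {
  genes <- as_gene_list(genes)$members
  stopifnot(inherits(membership, "ortholog_membership"),
            inherits(ladder, "clade_ladder"))
  unknown <- setdiff(unique(membership$clade), ladder$clades)
  if (length(unknown) > 0) {
    stop("membership cites clade(s) absent from the ladder: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  rank <- match(membership$clade, ladder$clades)
  oldest <- tapply(rank, membership$gene, min)
  idx <- oldest[match(genes, names(oldest))]
  ages <- ladder$clades[idx]
  unassigned <- genes[is.na(idx)]
  if (!strict) ages[is.na(idx)] <- ladder$clades[length(ladder$clades)]
  names(ages) <- genes
  structure(list(ages = ages, unassigned = unassigned, ladder = ladder),
            class = "gene_age_map")
}

#' @export
print.gene_age_map <- function(x, ...) {
  cat(sprintf("<gene_age_map> %d genes (%d without ortholog membership)\n",
              length(x$ages), length(x$unassigned)))
  invisible(x)
}

.is_ancient <- function(clades, ladder) {
  boundary <- match(ladder$ancient_boundary, ladder$clades)
  rank <- match(clades, ladder$clades)
  !is.na(rank) & rank <= boundary
}

#' Partition genes into ancient and younger strata
#'
#' Ancient = age at or before the ladder's ancient boundary (LECA or
#' earlier under the default ladder); younger = strictly after. Genes
#' without an age (strict-mode unassigned) are treated as younger, so the
#' two outputs always partition the input.
#'
#' @param genes a [gene_list()] or character vector.
#' @param age_map a [assign_gene_age()] result.
#' @param ladder a [clade_ladder()]; defaults to the map's own ladder.
#' @return list with `ancient` and `younger` [gene_list()]s.
#' @export
partition_by_age <- function(genes, age_map, ladder = age_map$ladder) {
  gl <- as_gene_list(genes)
  ages <- age_map$ages[match(gl$members, names(age_map$ages))]
  ancient <- .is_ancient(ages, ladder)
  ancient[is.na(ancient)] <- FALSE
  list(ancient = gene_list(gl$members[ancient],
                           name = paste0(gl$name, "_ancient")),
       younger = gene_list(gl$members[!ancient],
                           name = paste0(gl$name, "_younger")))
}

#' Per-clade age distribution
#'
#' Counts (and percentages) of genes tracing back to each ladder clade but
#' not an older one. Counts always sum to the input size; genes without an
#' age are counted under the youngest clade.
#'
#' @inheritParams partition_by_age
#' @return data frame with columns `clade`, `count`, `percent` (oldest
#'   clade first).
#' @export
age_distribution <- function(genes, age_map, ladder = age_map$ladder) {
  gl <- as_gene_list(genes)
  ages <- age_map$ages[match(gl$members, names(age_map$ages))]
  ages[is.na(ages)] <- ladder$clades[length(ladder$clades)]
  counts <- table(factor(ages, levels = ladder$clades))
  data.frame(clade = ladder$clades,
             count = as.integer(counts),
             percent = if (length(gl$members) > 0)
               100 * as.integer(counts) / length(gl$members) else 0,
             stringsAsFactors = FALSE)
}

#' Age-stratified enrichment test
#'
#' Removes gene age as a confounder by restricting universe, query and
#' feature to one age stratum before testing (e.g. ancient MIGs in the
#' ancient essentialome against all ancient interrogated genes), then
#' delegates to the exact Fisher machinery.
#'
#' @param query,feature gene lists or character vectors.
#' @param universe a [gene_universe()].
#' @param age_map a [assign_gene_age()] result covering the universe.
#' @param stratum `"ancient"` or `"younger"`.
#' @param convention background convention, see [build_table()].
#' @return an `enrichment_result`; the table labels record the stratum.
#' @export
age_stratified_enrichment <- function(query, feature, universe, age_map,
                                      stratum = c("ancient", "younger"),
                                      convention = c("universe_includes_query",
                                                     "universe_excludes_query")) {
  stratum <- match.arg(stratum)
  convention <- match.arg(convention)
  stopifnot(inherits(universe, "gene_universe"))
  uni_split <- partition_by_age(universe_genes(universe), age_map)
  uni_stratum <- uni_split[[stratum]]$members
  if (length(uni_stratum) == 0)
    stop("the ", stratum, " stratum leaves an empty universe", call. = FALSE)
  q <- intersect(as_gene_list(query, "query")$members, uni_stratum)
  f <- intersect(as_gene_list(feature, "feature")$members, uni_stratum)
  res <- enrich_test(gene_list(q, paste0("query_", stratum)),
                     gene_list(f, paste0("feature_", stratum)),
                     gene_list(uni_stratum, paste0("universe_", stratum)),
                     convention)
  res$table$labels[["stratum"]] <- stratum
  res
}

#' Age map from a universe's clade annotations
#'
#' Wraps the `age_clade` annotation of a [gene_universe()] into a
#' `gene_age_map`, for universes whose ages are already assigned (e.g.
#' synthetic universes or pre-aged membership tables).
#'
#' @param universe a [gene_universe()] with `age_clade` set for every gene.
#' @param ladder a [clade_ladder()].
#' @return a `gene_age_map`.
#' @export
universe_age_map <- function(universe, ladder = clade_ladder()) {
  stopifnot(inherits(universe, "gene_universe"))
  ann <- universe$annotations
  if (anyNA(ann$age_clade))
    stop("universe has genes without an age_clade annotation", call. = FALSE)
  unknown <- setdiff(unique(ann$age_clade), ladder$clades)
  if (length(unknown) > 0)
    stop("age_clade cites clade(s) absent from the ladder: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(ages = stats::setNames(ann$age_clade, ann$gene),
                 unassigned = character(0), ladder = ladder),
            class = "gene_age_map")
}
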