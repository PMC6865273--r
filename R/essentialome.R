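#' Essentiality matrix
#'
#' A genes-by-cell-lines matrix of either continuous gene-effect scores
#' (`mode = "scores"`) or binary essentiality calls (`mode = "calls"`,
#' values 0/1/NA), with an optional cell-line grouping (e.g. cancer type of
#' origin). Missing values stay missing throughout: an `NA` score yields an
#' `NA` call, and an `NA` call never contributes a gene to any essentialome.
#'
#' @param values numeric matrix, genes in rows (rownames = symbols), cell
#'   lines in columns (colnames = line labels).
#' @param mode `"scores"` or `"calls"`.
#' @param line_groups optional named character vector mapping every line
#'   label to a group label.
#' @return an object of class `essentiality_matrix`.
#' @export
essentiality_matrix <- function(values, mode = c("scores", "calls"),
                                line_groups = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry gene rownames and cell-line colnames",
         call. = FALSE)
  }
  rownames(values) <- normalize_gene_ids(rownames(values), dedupe = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene rows after normalization", call. = FALSE)
  if (mode == "calls") {
    v <- values[!is.na(values)]
    if (!all(v %in% c(0, 1)))
      stop("calls-mode matrix may only hold 0, 1 or NA", call. = FALSE)
  }
  if (!is.null(line_groups)) {
    missing <- setdiff(colnames(values), names(line_groups))
    if (length(missing) > 0) {
      stop("line_groups missing for line(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    line_groups <- line_groups[colnames(values)]
  }
  structure(list(values = values, mode = mode, line_groups = line_groups),
            class = "essentiality_matrix")
}

#' @export
print.essentiality_matrix <- function(x, ...) {
  cat(sprintf("<essentiality_matrix> %d genes x %d lines (%s mode)\n",
              nrow(x$values), ncol(x$values), x$mode))
  if (!is.null(x$line_groups))
    cat("  ", length(unique(x$line_groups)), " line groups\n", sep = "")
  invisible(x)
}

#' Threshold gene-effect scores into binary essentiality calls
#'
#' A gene is called essential in a line iff its score is at or below the
#' threshold (boundary inclusive; more negative gene-effect means stronger
#' dependency). Missing scores give missing calls. A calls-mode matrix
#' passes through unchanged.
#'
#' @param matrix an [essentiality_matrix()].
#' @param threshold finite numeric cutoff.
#' @return an [essentiality_matrix()] in calls mode.
#' @export
call_essential <- function(matrix, threshold) {
  stopifnot(inherits(matrix, "essentiality_matrix"))
  if (matrix$mode == "calls") return(matrix)
  stopifnot(is.numeric(threshold), length(threshold) == 1, is.finite(threshold))
  calls <- (matrix$values <= threshold) + 0
  essentiality_matrix(calls, mode = "calls", line_groups = matrix$line_groups)
}

new_essentialome <- function(members, name, rule, params = list()) {
  structure(list(name = name,
                 members = sort(unique(as.character(members))),
                 rule = rule, params = params),
            class = c("essentialome", "gene_list"))
}

#' @export
print.essentialome <- function(x, ...) {
  cat(sprintf("<essentialome> %s (%s rule): %d genes\n",
              x$name, x$rule, length(x$members)))
  invisible(x)
}

#' Per-cell-line essentialomes
#'
#' For each cell line, the set of genes called essential (call 1) in that
#' line. Missing calls exclude the gene from that line's essentialome.
#'
#' @param calls an [essentiality_matrix()] in calls mode.
#' @return named list of `essentialome` objects, one per line.
#' @export
per_line_essentialomes <- function(calls) {
  stopifnot(inherits(calls, "essentiality_matrix"))
  if (calls$mode != "calls")
    stop("per-line essentialomes need a calls-mode matrix; run call_essential()",
         call. = FALSE)
  v <- calls$values
  out <- lapply(colnames(v), function(line) {
    hit <- which(!is.na(v[, line]) & v[, line] == 1)
    new_essentialome(rownames(v)[hit], name = line, rule = "per_line",
                     params = list(line = line))
  })
  names(out) <- colnames(v)
  out
}

check_per_line <- function(per_line) {
  stopifnot(is.list(per_line), length(per_line) >= 1)
  ok <- vapply(per_line, inherits, logical(1), "essentialome")
  if (!all(ok)) stop("per_line must be a list of essentialome objects",
                     call. = FALSE)
  invisible(per_line)
}

#' Total essentialome: essential in at least one line
#'
#' Union over the per-line essentialomes.
#'
#' @param per_line named list from [per_line_essentialomes()].
#' @return an `essentialome` with `rule = "total"`.
#' @export
total_essentialome <- function(per_line) {
  check_per_line(per_line)
  members <- unique(unlist(lapply(per_line, `[[`, "members"), use.names = FALSE))
  new_essentialome(members, name = "total", rule = "total",
                   params = list(n_lines = length(per_line)))
}

#' Core essentialome: essential in every line
#'
#' Intersection over the per-line essentialomes.
#'
#' @inheritParams total_essentialome
#' @return an `essentialome` with `rule = "core"`.
#' @export
core_essentialome <- function(per_line) {
  check_per_line(per_line)
  members <- Reduce(intersect, lapply(per_line, `[[`, "members"))
  new_essentialome(members, name = "core", rule = "core",
                   params = list(n_lines = length(per_line)))
}

#' Majority essentialome: essential in at least a fraction of lines
#'
#' Keeps genes essential in at least `ceiling(fraction * L)` of the `L`
#' lines. The ceiling makes "at least 95% of 341 lines" mean 324 lines: the
#' stated fraction is a lower bound. `fraction = 1` coincides with the core
#' rule.
#'
#' @inheritParams total_essentialome
#' @param fraction required fraction of lines, in (0, 1].
#' @return an `essentialome` with `rule = "majority"`; `params$cutoff_lines`
#'   records the integer line cutoff.
#' @export
majority_essentialome <- function(per_line, fraction = 0.95) {
  check_per_line(per_line)
  stopifnot(is.numeric(fraction), length(fraction) == 1,
            fraction > 0, fraction <= 1)
  L <- length(per_line)
  cutoff <- as.integer(ceiling(fraction * L))
  counts <- table(unlist(lapply(per_line, `[[`, "members"), use.names = FALSE))
  members <- names(counts)[counts >= cutoff]
  new_essentialome(members, name = sprintf("majority_%g", fraction),
                   rule = "majority",
                   params = list(n_lines = L, fraction = fraction,
                                 cutoff_lines = cutoff))
}

#' Group (e.g. cancer-type) essentialomes
#'
#' Combines per-line essentialomes of lines sharing a group label into one
#' essentialome per group, by union within the group.
#'
#' @inheritParams total_essentialome
#' @param line_groups named character vector mapping each line to its group.
#' @return named list of `essentialome` objects, one per group (in order of
#'   first appearance).
#' @export
group_essentialomes <- function(per_line, line_groups) {
  check_per_line(per_line)
  lines <- names(per_line)
  missing <- setdiff(lines, names(line_groups))
  if (length(missing) > 0) {
    stop("no group for line(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  groups <- unique(unname(line_groups[lines]))
  out <- lapply(groups, function(g) {
    member_lines <- lines[line_groups[lines] == g]
    members <- unique(unlist(lapply(per_line[member_lines], `[[`, "members"),
                             use.names = FALSE))
    new_essentialome(members, name = g, rule = "group",
                     params = list(group = g, lines = member_lines))
  })
  names(out) <- groups
  out
}
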