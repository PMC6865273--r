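#' Read gene lists from disk
#'
#' Supports the two plain-text dialects used throughout: single-column TSV
#' (one symbol per line, optional header) and GMT (one gene set per line:
#' name, description, then tab-separated members). Members are normalized
#' and de-duplicated; provenance records the source path.
#'
#' @param path file path.
#' @param format `"single_column_tsv"` or `"gmt"`.
#' @param header for TSV: `TRUE`, `FALSE`, or `"auto"` (default; the first
#'   line is treated as a header iff it does not look like a gene symbol
#'   under `symbol_regex`).
#' @param symbol_regex regex a first line must match to be taken as data
#'   under `header = "auto"`.
#' @param alias optional alias map (see [normalize_gene_ids()]).
#' @return for TSV a single [gene_list()]; for GMT a list of [gene_list()]s
#'   in file order, named by set name.
#' @export
read_gene_list <- function(path,
                           format = c("single_column_tsv", "gmt"),
                           header = "auto",
                           symbol_regex = "^[A-Za-z][A-Za-z0-9._-]*$",
                           alias = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read gene list: no such file: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "single_column_tsv") {
    if (identical(header, "auto")) {
      header <- length(lines) > 0 && !grepl(symbol_regex, trimws(lines[1]))
    }
    if (isTRUE(header) && length(lines) > 0) lines <- lines[-1]
    name <- sub("\\.[^.]*$", "", basename(path))
    return(gene_list(lines, name = name, provenance = path, alias = alias))
  }
  # GMT: name <tab> description <tab> member...
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2) {
      stop("malformed GMT line ", i, " in ", path,
           ": expected at least 2 tab-separated fields", call. = FALSE)
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(trimws(members))]
    out[[i]] <- gene_list(members, name = fields[1],
                          provenance = sprintf("%s (line %d; %s)",
                                               path, i, fields[2]),
                          alias = alias)
  }
  names(out) <- vapply(out, function(x) x$name, character(1))
  out
}

#' Write gene lists to disk
#'
#' Inverse of [read_gene_list()]: single-column TSV for one list, GMT for
#' one or many. Round-tripping preserves the member set.
#'
#' @param x a [gene_list()] or a list of them (GMT only).
#' @param path output file path.
#' @param format `"single_column_tsv"` or `"gmt"`.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(x, path, format = c("single_column_tsv", "gmt")) {
  format <- match.arg(format)
  if (inherits(x, "gene_list")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "gene_list")))
  if (format == "single_column_tsv") {
    if (length(x) != 1) stop("single-column TSV holds exactly one gene list",
                             call. = FALSE)
    writeLines(x[[1]]$members, path)
  } else {
    lines <- vapply(x, function(gl) {
      desc <- if (nzchar(gl$provenance)) gl$provenance else "na"
      desc <- gsub("\t", " ", desc, fixed = TRUE)
      paste(c(gl$name, desc, gl$members), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a genes-by-columns numeric matrix
#'
#' Reads the delimited matrix dialect shared by gene-effect score tables
#' (first column gene label, remaining columns cell lines) and TPM tables
#' (columns `<stage>.<rep>`). Row labels are normalized gene symbols and
#' must be unique; column labels are preserved verbatim. Empty cells are
#' kept as `NA` — missing is not zero, and downstream thresholding skips
#' missing entries rather than fabricating calls.
#'
#' @param path file path.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @param alias optional alias map for row labels.
#' @return numeric matrix with gene rownames.
#' @export
read_matrix <- function(path, sep = ",", alias = NULL) {
  if (!file.exists(path)) stop("cannot read matrix: no such file: ", path,
                               call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      na.strings = c("", "NA"), fill = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(df) < 2) stop("matrix in ", path,
                         " needs a gene column plus at least one data column",
                         call. = FALSE)
  genes <- normalize_gene_ids(as.character(df[[1]]), alias = alias,
                              dedupe = FALSE)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    stop("duplicate gene rows in ", path, ": ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  }
  body <- df[-1]
  nonnum <- names(body)[!vapply(body, is.numeric, logical(1))]
  if (length(nonnum) > 0) {
    stop("non-numeric matrix column(s) in ", path, ": ",
         paste(nonnum, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(body)
  rownames(m) <- genes
  m
}
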