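#' Pipeline configuration
#'
#' Bundles the handful of constants the analysis depends on. Defaults follow
#' the conventions of the study design this pipeline implements: the
#' majority essentialome keeps genes essential in at least 95% of cell
#' lines, a gene counts as expressed at TPM >= 1, successive-stage
#' differential expression is called at p < 0.05, and enrichment tables are
#' built with the query inside the background universe (the convention that
#' reproduces the published worked examples).
#'
#' @param essentiality_threshold numeric score cutoff (call = score <=
#'   threshold, boundary inclusive) or the string `"precalled"` when the
#'   input matrix already carries binary calls. There is no default numeric
#'   cutoff: reproducing published essentialome sizes requires the original
#'   calls, and the pipeline will not invent one.
#' @param majority_fraction fraction of lines for the majority rule, in
#'   (0, 1]; default 0.95.
#' @param tpm_threshold expressed-gene TPM cutoff (inclusive); default 1.
#' @param de_alpha significance level for successive-stage DE; default 0.05.
#' @param background_convention `"universe_includes_query"` (default) or
#'   `"universe_excludes_query"`.
#' @param seed non-negative integer seed for any stochastic step.
#' @return an object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(essentiality_threshold = "precalled",
                            majority_fraction = 0.95,
                            tpm_threshold = 1.0,
                            de_alpha = 0.05,
                            background_convention = c("universe_includes_query",
                                                      "universe_excludes_query"),
                            seed = 0L) {
  background_convention <- match.arg(background_convention)
  if (!identical(essentiality_threshold, "precalled")) {
    stopifnot(is.numeric(essentiality_threshold),
              length(essentiality_threshold) == 1,
              is.finite(essentiality_threshold))
  }
  stopifnot(is.numeric(majority_fraction), length(majority_fraction) == 1,
            majority_fraction > 0, majority_fraction <= 1,
            is.numeric(tpm_threshold), is.finite(tpm_threshold),
            is.numeric(de_alpha), de_alpha > 0, de_alpha < 1,
            is.numeric(seed), seed >= 0)
  structure(
    list(essentiality_threshold = essentiality_threshold,
         majority_fraction = majority_fraction,
         tpm_threshold = tpm_threshold,
         de_alpha = de_alpha,
         background_convention = background_convention,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (f in names(x)) cat("  ", f, ": ", format(x[[f]]), "\n", sep = "")
  invisible(x)
}
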