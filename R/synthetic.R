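#' Configuration for the synthetic-data generators
#'
#' The generators emulate the study design the pipeline targets: a
#' genome-scale interrogated universe with a MIG share near 3.5%, an
#' age-clade distribution dominated by ancient (LECA-or-earlier) genes,
#' binary essentiality calls across many cell lines with a planted
#' MIG-essentiality odds ratio, a four-stage TPM table with replicates and
#' a small planted fraction of stage-to-stage DE genes, and five
#' species-level CDG lists with planted multi-species overlaps. Every
#' planted parameter is recorded in a truth object so downstream stages can
#' be scored without re-deriving ground truth.
#'
#' @param n_genes universe size (default 17,000).
#' @param mig_fraction MIG share of the universe (default 0.035).
#' @param n_lines number of cell lines (default 50).
#' @param base_essential_rate overall per-gene consensus essentiality rate
#'   (default 0.10).
#' @param planted_odds_ratio MIG-vs-non-MIG essentiality odds ratio
#'   (default 2.5).
#' @param stratified_odds_ratios optional named numeric
#'   `c(ancient = , younger = )` overriding `planted_odds_ratio` per age
#'   stratum.
#' @param ancient_essential_boost odds multiplier making ancient genes more
#'   often essential than younger ones (default 2.6), with the overall rate
#'   held at `base_essential_rate`.
#' @param age_probs named per-clade probabilities over the default ladder
#'   (oldest first); default puts 66.8% at Eukaryota.
#' @param drop_rate per-line probability that a consensus-essential gene is
#'   missed in one line (1 -> 0 flip; default 0.02).
#' @param gain_rate per-line probability that a consensus-non-essential
#'   gene is spuriously called in one line (0 -> 1 flip; default 2e-4).
#' @param mig_family_sizes sizes of planted MIG families (default 3, 2, 2).
#' @param n_replicates replicates per cell-cycle stage (default 3).
#' @param tpm_log2_mean,tpm_log2_sd log2-scale baseline TPM distribution
#'   (defaults 3 and 2).
#' @param tpm_cv multiplicative replicate coefficient of variation
#'   (default 0.05).
#' @param de_fraction fraction of genes with a planted successive-stage
#'   expression step (default 0.01).
#' @param de_fold planted fold change (default 4).
#' @param cdg_sizes named per-species CDG list sizes (default dog/cat/
#'   cattle/horse 161 each and human 742, totalling 1,386).
#' @param planted_cdg_mig_odds_ratio MIG sampling odds multiplier for CDG
#'   lists (default 1.4).
#' @param n_shared2,n_shared3 numbers of genes planted into exactly two and
#'   exactly three species lists (defaults 45 and 6, so 51 genes are shared
#'   by at least two species).
#' @param seed default seed for the generators.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 17000,
                             mig_fraction = 0.035,
                             n_lines = 50,
                             base_essential_rate = 0.10,
                             planted_odds_ratio = 2.5,
                             stratified_odds_ratios = NULL,
                             ancient_essential_boost = 2.6,
                             age_probs = default_age_probs(),
                             drop_rate = 0.02,
                             gain_rate = 2e-4,
                             mig_family_sizes = c(3, 2, 2),
                             n_replicates = 3,
                             tpm_log2_mean = 3,
                             tpm_log2_sd = 2,
                             tpm_cv = 0.05,
                             de_fraction = 0.01,
                             de_fold = 4,
                             cdg_sizes = c(dog = 161, cat = 161, cattle = 161,
                                           horse = 161, human = 742),
                             planted_cdg_mig_odds_ratio = 1.4,
                             n_shared2 = 45,
                             n_shared3 = 6,
                             seed = 1L) {
  probs <- c(mig_fraction, base_essential_rate, drop_rate, gain_rate,
             de_fraction, age_probs)
  stopifnot(all(probs >= 0), all(probs <= 1),
            abs(sum(age_probs) - 1) < 1e-8,
            identical(names(age_probs), default_clades()),
            n_genes >= 1, n_lines >= 1, n_replicates >= 1,
            planted_odds_ratio > 0, ancient_essential_boost > 0,
            de_fold > 0, planted_cdg_mig_odds_ratio > 0,
            all(cdg_sizes >= 1), n_shared2 >= 0, n_shared3 >= 0)
  if (!is.null(stratified_odds_ratios)) {
    stopifnot(all(c("ancient", "younger") %in% names(stratified_odds_ratios)),
              all(stratified_odds_ratios > 0))
  }
  cfg <- as.list(environment())
  cfg$probs <- NULL
  structure(cfg, class = "synthetic_config")
}

#' Default per-clade age probabilities
#'
#' Shaped so that 66.8% of genes trace to Eukaryota (LECA or earlier) and
#' the remainder tapers across the younger rungs.
#'
#' @return named numeric vector over [default_clades()], summing to 1.
#' @export
default_age_probs <- function() {
  c(Eukaryota = 0.668, Opisthokonta = 0.070, Metazoa = 0.060,
    Eumetazoa = 0.050, Bilateria = 0.045, Deuterostomia = 0.020,
    Chordata = 0.020, Euteleostomi = 0.030, Amniota = 0.012,
    species_specific = 0.025)
}

#' Generate a synthetic gene universe
#'
#' Deterministic given the seed. MIG flags are Bernoulli at
#' `mig_fraction`; age clades are multinomial over the default ladder;
#' MIG families of the configured sizes are planted among the MIGs.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (default `config$seed`).
#' @return a [gene_universe()]; the attached attribute `"truth"` records
#'   the planted family map.
#' @export
generate_universe <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  G <- config$n_genes
  genes <- sprintf("G%05d", seq_len(G))
  is_mig <- stats::rbinom(G, 1, config$mig_fraction) == 1
  ages <- sample(names(config$age_probs), G, replace = TRUE,
                 prob = config$age_probs)
  family <- rep(NA_character_, G)
  sizes <- config$mig_family_sizes
  migs_idx <- which(is_mig)
  if (length(sizes) > 0 && sum(sizes) <= length(migs_idx)) {
    picked <- sample(migs_idx, sum(sizes))
    fam_labels <- rep(sprintf("FAM%d", seq_along(sizes)), times = sizes)
    family[picked] <- fam_labels
  }
  uni <- gene_universe(gene_list(genes, name = "synthetic_universe",
                                 provenance = sprintf("seed=%d", seed)),
                       is_mig = is_mig, family = family, age_clade = ages)
  fam_list <- split(genes[!is.na(family)], family[!is.na(family)])
  attr(uni, "truth") <- list(seed = seed,
                             family_map = if (length(fam_list) > 0)
                               family_map(fam_list) else NULL)
  uni
}

# younger-stratum rate solving mix(p_y) = base rate given the ancient boost
.stratum_rates <- function(base, boost, frac_ancient) {
  if (boost == 1 || frac_ancient %in% c(0, 1)) {
    return(c(ancient = base, younger = base))
  }
  mix <- function(py) {
    pa <- boost * py / (1 + py * (boost - 1))
    frac_ancient * pa + (1 - frac_ancient) * py - base
  }
  py <- stats::uniroot(mix, c(1e-9, base))$root
  pa <- boost * py / (1 + py * (boost - 1))
  c(ancient = pa, younger = py)
}

.boost_odds <- function(p, or) {
  odds <- p / (1 - p) * or
  odds / (1 + odds)
}

#' Generate a synthetic essentiality call matrix
#'
#' Each gene draws a latent consensus essentiality call whose odds are
#' multiplied by the planted odds ratio for MIGs (optionally per age
#' stratum) and by the ancient-gene boost. Per-line calls are noisy
#' realizations of the consensus: essential genes are dropped per line
#' with `drop_rate` and non-essential genes gain a spurious call with
#' `gain_rate`, so the core, majority and total essentialomes separate
#' non-trivially while the union-based total still tracks the planted
#' effect.
#'
#' @param universe a [gene_universe()] from [generate_universe()].
#' @param config a [synthetic_config()].
#' @param seed integer seed (default `config$seed + 1`).
#' @return an [essentiality_matrix()] in calls mode; attribute `"truth"`
#'   records the consensus calls and every planted parameter.
#' @export
generate_essentiality <- function(universe, config, seed = config$seed + 1) {
  stopifnot(inherits(universe, "gene_universe"),
            inherits(config, "synthetic_config"))
  set.seed(seed)
  ann <- universe$annotations
  G <- nrow(ann)
  ladder <- clade_ladder()
  ancient <- .is_ancient(ann$age_clade, ladder)
  rates <- .stratum_rates(config$base_essential_rate,
                          config$ancient_essential_boost, mean(ancient))
  p <- ifelse(ancient, rates[["ancient"]], rates[["younger"]])
  ors <- if (!is.null(config$stratified_odds_ratios)) {
    ifelse(ancient, config$stratified_odds_ratios[["ancient"]],
           config$stratified_odds_ratios[["younger"]])
  } else rep(config$planted_odds_ratio, G)
  p[ann$is_mig] <- .boost_odds(p[ann$is_mig], ors[ann$is_mig])
  consensus <- stats::rbinom(G, 1, p)
  line_p <- consensus * (1 - config$drop_rate) +
    (1 - consensus) * config$gain_rate
  calls <- matrix(stats::rbinom(G * config$n_lines, 1, line_p),
                  nrow = G, ncol = config$n_lines,
                  dimnames = list(ann$gene,
                                  sprintf("LINE%03d", seq_len(config$n_lines))))
  m <- essentiality_matrix(calls, mode = "calls")
  attr(m, "truth") <- list(seed = seed, consensus = stats::setNames(consensus, ann$gene),
                           p_gene = stats::setNames(p, ann$gene),
                           stratum_rates = rates,
                           planted_odds_ratio = config$planted_odds_ratio,
                           stratified_odds_ratios = config$stratified_odds_ratios,
                           drop_rate = config$drop_rate,
                           gain_rate = config$gain_rate)
  m
}

#' Generate a synthetic cell-cycle TPM table
#'
#' Baseline TPM is log-normal per gene and shared across stages; a
#' `de_fraction` of genes receive a `de_fold` step (random direction) at
#' one randomly chosen successive stage boundary; multiplicative
#' log-normal replicate noise with coefficient of variation `tpm_cv` is
#' applied on top.
#'
#' @param universe a [gene_universe()].
#' @param config a [synthetic_config()].
#' @param seed integer seed (default `config$seed + 2`).
#' @return an [expression_table()]; attribute `"truth"` lists the planted
#'   DE genes, their stage boundary and direction.
#' @export
generate_expression <- function(universe, config, seed = config$seed + 2) {
  stopifnot(inherits(universe, "gene_universe"),
            inherits(config, "synthetic_config"))
  set.seed(seed)
  genes <- universe_genes(universe)
  G <- length(genes)
  stages <- c("early_G1", "late_G1", "S", "G2M")
  R <- config$n_replicates
  base <- 2^stats::rnorm(G, config$tpm_log2_mean, config$tpm_log2_sd)
  stage_tpm <- matrix(base, G, length(stages))
  n_de <- round(config$de_fraction * G)
  de_idx <- if (n_de > 0) sample(G, n_de) else integer(0)
  boundary <- sample(length(stages) - 1, n_de, replace = TRUE)
  up <- sample(c(TRUE, FALSE), n_de, replace = TRUE)
  for (i in seq_len(n_de)) {
    fold <- if (up[i]) config$de_fold else 1 / config$de_fold
    stage_tpm[de_idx[i], (boundary[i] + 1):length(stages)] <-
      stage_tpm[de_idx[i], (boundary[i] + 1):length(stages)] * fold
  }
  cols <- as.vector(t(outer(stages, seq_len(R), paste, sep = ".")))
  tpm <- matrix(0, G, length(stages) * R, dimnames = list(genes, cols))
  sdlog <- sqrt(log1p(config$tpm_cv^2))
  for (s in seq_along(stages)) {
    for (r in seq_len(R)) {
      noise <- exp(stats::rnorm(G, -sdlog^2 / 2, sdlog))
      tpm[, (s - 1) * R + r] <- stage_tpm[, s] * noise
    }
  }
  tab <- expression_table(tpm, stages = stages)
  attr(tab, "truth") <- list(seed = seed,
                             de_genes = genes[de_idx],
                             boundary = stats::setNames(boundary, genes[de_idx]),
                             up = stats::setNames(up, genes[de_idx]),
                             de_fold = config$de_fold,
                             tpm_cv = config$tpm_cv)
  tab
}

#' Generate synthetic candidate domestication gene lists
#'
#' Plants `n_shared3` genes into three species lists each and `n_shared2`
#' into two, then fills every species list with genes unique to that
#' species, sampled with MIG odds multiplied by
#' `planted_cdg_mig_odds_ratio`. Keeping non-planted genes
#' species-unique makes the planted genes exactly the multi-species
#' overlaps, so the truth record fully determines the sharing structure.
#'
#' @param universe a [gene_universe()].
#' @param config a [synthetic_config()].
#' @param seed integer seed (default `config$seed + 3`).
#' @return a [cdg_collection()]; attribute `"truth"` records the planted
#'   shared-by-two and shared-by-three gene sets.
#' @export
generate_cdg_lists <- function(universe, config, seed = config$seed + 3) {
  stopifnot(inherits(universe, "gene_universe"),
            inherits(config, "synthetic_config"))
  set.seed(seed)
  ann <- universe$annotations
  sizes <- config$cdg_sizes
  if (any(sizes > nrow(ann)))
    stop("cdg_sizes cannot exceed the universe size", call. = FALSE)
  species <- names(sizes)
  n_sp <- length(species)
  if (config$n_shared3 > 0 && n_sp < 3)
    stop("planting shared-by-three genes needs at least 3 species", call. = FALSE)
  pool <- ann$gene
  w <- ifelse(ann$is_mig, config$planted_cdg_mig_odds_ratio, 1)
  names(w) <- pool
  shared3 <- if (config$n_shared3 > 0) sample(pool, config$n_shared3)
             else character(0)
  pool2 <- setdiff(pool, shared3)
  shared2 <- if (config$n_shared2 > 0) sample(pool2, config$n_shared2)
             else character(0)
  lists <- stats::setNames(vector("list", n_sp), species)
  for (sp in species) lists[[sp]] <- character(0)
  for (g in shared3) {
    for (sp in sample(species, 3)) lists[[sp]] <- c(lists[[sp]], g)
  }
  for (g in shared2) {
    for (sp in sample(species, 2)) lists[[sp]] <- c(lists[[sp]], g)
  }
  used <- c(shared3, shared2)
  avail <- setdiff(pool, used)
  for (sp in species) {
    need <- sizes[[sp]] - length(lists[[sp]])
    if (need < 0)
      stop("cdg_sizes[", sp, "] too small for the planted shared genes",
           call. = FALSE)
    if (need > length(avail))
      stop("universe too small to keep species lists disjoint", call. = FALSE)
    fill <- sample(avail, need, prob = w[avail])
    lists[[sp]] <- c(lists[[sp]], fill)
    avail <- setdiff(avail, fill)
  }
  coll <- cdg_collection(lists)
  attr(coll, "truth") <- list(seed = seed, shared2 = sort(shared2),
                              shared3 = sort(shared3),
                              planted_cdg_mig_odds_ratio =
                                config$planted_cdg_mig_odds_ratio)
  coll
}
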