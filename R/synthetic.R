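#' Configuration for the synthetic cfDNA cohort generator
#'
#' Encodes the statistical structure the promoter-footprint analysis
#' assumes: per-gene normalized pTSS coverage is lognormal with a mean
#' that decreases with the gene's expression percentile (the nucleosome
#' footprint), a planted subset of genes differs between preterm and term
#' groups by a configured log2 fold change, each sample carries a
#' multiplicative noise factor, and clinical covariates (pre-pregnancy
#' BMI, fetal fraction) are drawn identically for both groups unless a
#' location shift is requested.
#'
#' @param n_preterm,n_term Samples per group (default 20 + 20, the scale
#'   of a discovery cohort).
#' @param n_genes Number of pTSS features (default 1000).
#' @param n_diff Number of genes with a planted group effect (default 60).
#' @param log2fc_magnitude Planted |log2 fold change| (default 1.2; the
#'   differential gate downstream is |log2FC| >= 1). Sign is random per
#'   gene.
#' @param baseline_log_mean Natural-log mean of normalized coverage for an
#'   unexpressed gene (default `log(10)`).
#' @param baseline_log_sd Per-gene, per-sample biological noise on the
#'   natural-log scale (default 0.25).
#' @param expression_slope Decrease in natural-log coverage per unit
#'   expression percentile (default 1: a fully expressed promoter has
#'   e-fold lower coverage — the footprint).
#' @param sample_noise_log_sd SD (natural-log scale) of the multiplicative
#'   technical noise attributed to sample handling/depth, drawn
#'   independently per sample-and-gene cell (default 0.25).
#' @param fetal_fraction_beta Beta(alpha, beta) parameters for the fetal
#'   fraction covariate (default c(10, 90), mean 0.10).
#' @param ff_attenuation If TRUE the planted multiplier is attenuated by
#'   the sample's fetal fraction, `1 + ff * (2^lfc - 1)` — the
#'   placental-signal mixture; if FALSE (default) the planted effect is at
#'   full strength (equivalent to ff = 1).
#' @param bmi_mean,bmi_sd BMI covariate distribution (kg/m^2; default
#'   22, 3).
#' @param bmi_shift,ff_shift Optional location shifts added to the preterm
#'   group's BMI (kg/m^2) and fetal fraction, producing weakly informative
#'   clinical covariates (standalone AUC slightly above 0.5); both default
#'   to 0 (uninformative).
#' @param fragment_length_mean,fragment_length_sd Fragment length model in
#'   bp (default 167 +/- 20, the mononucleosome peak).
#' @param ndr_depth_factor Relative fragment density inside the
#'   nucleosome-depleted region for a fully expressed promoter, in
#'   \[0, 1\] (default 0.3).
#' @param nucleosome_spacing Nucleosome repeat length in bp for the
#'   phased-occupancy model (default 190).
#' @param seed Integer seed; fixed seed gives byte-identical cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_preterm = 20L, n_term = 20L, n_genes = 1000L,
                       n_diff = 60L, log2fc_magnitude = 1.2,
                       baseline_log_mean = log(10), baseline_log_sd = 0.25,
                       expression_slope = 1.0, sample_noise_log_sd = 0.25,
                       fetal_fraction_beta = c(10, 90),
                       ff_attenuation = FALSE,
                       bmi_mean = 22, bmi_sd = 3,
                       bmi_shift = 0, ff_shift = 0,
                       fragment_length_mean = 167,
                       fragment_length_sd = 20,
                       ndr_depth_factor = 0.3,
                       nucleosome_spacing = 190,
                       seed = 1L) {
  cfg <- list(n_preterm = as.integer(n_preterm), n_term = as.integer(n_term),
              n_genes = as.integer(n_genes), n_diff = as.integer(n_diff),
              log2fc_magnitude = log2fc_magnitude,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              expression_slope = expression_slope,
              sample_noise_log_sd = sample_noise_log_sd,
              fetal_fraction_beta = fetal_fraction_beta,
              ff_attenuation = isTRUE(ff_attenuation),
              bmi_mean = bmi_mean, bmi_sd = bmi_sd,
              bmi_shift = bmi_shift, ff_shift = ff_shift,
              fragment_length_mean = fragment_length_mean,
              fragment_length_sd = fragment_length_sd,
              ndr_depth_factor = ndr_depth_factor,
              nucleosome_spacing = nucleosome_spacing,
              seed = as.integer(seed))
  with(cfg, {
    if (n_preterm <= 0 || n_term <= 0 || n_genes <= 0)
      stop("sample and gene counts must be positive")
    if (n_diff < 0 || n_diff > n_genes)
      stop("invalid config: n_diff must lie in [0, n_genes]")
    if (ndr_depth_factor < 0 || ndr_depth_factor > 1)
      stop("ndr_depth_factor must lie in [0, 1]")
    if (fragment_length_mean <= 0) stop("fragment_length_mean must be > 0")
    if (length(fetal_fraction_beta) != 2 || any(fetal_fraction_beta <= 0))
      stop("fetal_fraction_beta must be a positive (alpha, beta) pair")
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a coverage-level cfDNA cohort with planted effects
#'
#' Generates a samples x genes normalized pTSS coverage matrix:
#' `coverage[s, g] = exp(N(mu_g, baseline_log_sd)) * m[s, g] *
#' exp(N(0, sample_noise_log_sd))` with
#' `mu_g = baseline_log_mean - expression_slope * percentile_g`, where the
#' group multiplier `m` is `1 + ff * (2^(sign_g * lfc) - 1)` for planted
#' genes in preterm samples (ff = 1 unless `ff_attenuation`) and 1
#' otherwise. The two noise terms are independent per sample-and-gene
#' cell: a biological component (`baseline_log_sd`) and a technical,
#' sample-level-variance component (`sample_noise_log_sd`); observations
#' are therefore exchangeable across samples within each gene, so null
#' cohorts are exactly calibrated for rank tests.
#'
#' @param config A [sim_config()].
#' @return A list with elements `coverage` (a `coverage_matrix`-classed
#'   list whose `normalized` slot is the samples x genes matrix), `meta`
#'   (sample metadata: `sample_id`, `group`, `cohort`, `gest_age_weeks`,
#'   `bmi`, `fetal_fraction`) and `truth` (planted `diff_gene_ids`, per-gene
#'   `sign`, `log2fc`, `expression_percentile`).
#' @export
simulate_coverage_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_preterm + config$n_term
  g <- config$n_genes
  gene_ids <- sprintf("g%04d", seq_len(g))
  sample_ids <- sprintf("S%03d", seq_len(n))
  group <- c(rep("preterm", config$n_preterm), rep("term", config$n_term))

  percentile <- sample((seq_len(g) - 0.5) / g)
  diff_idx <- if (config$n_diff > 0) sort(sample.int(g, config$n_diff))
              else integer(0)
  sign <- integer(g)
  sign[diff_idx] <- sample(c(-1L, 1L), length(diff_idx), replace = TRUE)
  lfc <- sign * config$log2fc_magnitude

  ff <- stats::rbeta(n, config$fetal_fraction_beta[1],
                     config$fetal_fraction_beta[2])
  ff <- pmin(1, ff + ifelse(group == "preterm", config$ff_shift, 0))
  bmi <- stats::rnorm(n, config$bmi_mean, config$bmi_sd) +
    ifelse(group == "preterm", config$bmi_shift, 0)
  gest_age <- stats::runif(n, 12, 28)

  mu <- config$baseline_log_mean - config$expression_slope * percentile

  mult <- matrix(1, nrow = n, ncol = g)
  if (length(diff_idx) > 0) {
    eff_ff <- if (config$ff_attenuation) ff else rep(1, n)
    is_case <- group == "preterm"
    for (j in diff_idx)
      mult[is_case, j] <- 1 + eff_ff[is_case] * (2^lfc[j] - 1)
  }

  bio_noise <- matrix(exp(stats::rnorm(n * g, 0, config$baseline_log_sd)),
                      nrow = n, ncol = g)
  tech_noise <- matrix(exp(stats::rnorm(n * g, 0,
                                        config$sample_noise_log_sd)),
                       nrow = n, ncol = g)
  base <- matrix(exp(mu), nrow = n, ncol = g, byrow = TRUE)
  coverage <- base * bio_noise * mult * tech_noise
  dimnames(coverage) <- list(sample_ids, gene_ids)

  meta <- data.frame(sample_id = sample_ids, group = group,
                     cohort = "simulated", gest_age_weeks = gest_age,
                     bmi = bmi, fetal_fraction = ff,
                     stringsAsFactors = FALSE)
  truth <- list(diff_gene_ids = gene_ids[diff_idx],
                sign = stats::setNames(sign, gene_ids),
                log2fc = stats::setNames(lfc, gene_ids),
                expression_percentile = stats::setNames(percentile, gene_ids))
  cov_obj <- structure(list(
    normalized = coverage, raw_counts = NULL,
    sample_ids = sample_ids, region_ids = gene_ids,
    total_fragments = NULL, normalization_tag = "simulated"
  ), class = "coverage_matrix")
  list(coverage = cov_obj, meta = meta, truth = truth)
}

#' Per-position fragment-midpoint sampling weights for a promoter window
#'
#' Models nucleosome occupancy across the 2-kb pTSS window: a
#' cosine-phased baseline with period `nucleosome_spacing`, and a
#' nucleosome-depleted region (NDR) at oriented offsets -150..+49 relative
#' to the TSS whose density is scaled by
#' `1 - percentile * (1 - ndr_depth_factor)` — unexpressed promoters
#' (percentile 0) have no depletion; a fully expressed promoter with
#' `ndr_depth_factor = 0` has zero density in the NDR.
#'
#' @param expression_percentile Gene expression percentile in \[0, 1\].
#' @param region_length Window width in bp (default 2000).
#' @param config A [sim_config()] supplying `nucleosome_spacing` and
#'   `ndr_depth_factor`.
#' @param normalize If TRUE (default) weights sum to 1; if FALSE the raw
#'   occupancy mass is returned (used to scale total fragment yield).
#' @return Numeric weight vector of length `region_length`, indexed by
#'   oriented offset `-region_length/2 .. region_length/2 - 1`.
#' @export
occupancy_weights <- function(expression_percentile, region_length = 2000L,
                              config = sim_config(), normalize = TRUE) {
  if (expression_percentile < 0 || expression_percentile > 1)
    stop("expression_percentile must lie in [0, 1]")
  offset <- seq.int(-region_length %/% 2, region_length %/% 2 - 1L)
  w <- 1 + 0.5 * cos(2 * pi * offset / config$nucleosome_spacing)
  ndr <- offset >= -150L & offset < 50L
  scale <- 1 - expression_percentile * (1 - config$ndr_depth_factor)
  w[ndr] <- w[ndr] * scale
  if (normalize) {
    s <- sum(w)
    if (s <= 0) stop("degenerate occupancy: all weights zero")
    w <- w / s
  }
  w
}

#' Simulate cfDNA fragments over pTSS regions
#'
#' Draws fragment midpoints from [occupancy_weights()] (oriented by region
#' strand) and lengths from Normal(`fragment_length_mean`,
#' `fragment_length_sd`) truncated to \[50, 400\] bp. The number of
#' fragments per region is Poisson with mean `depth_per_region` scaled by
#' the region's relative occupancy mass, so nucleosome-depleted (expressed)
#' promoters yield proportionally fewer protected fragments — the
#' footprint seen in coverage.
#'
#' @param regions pTSS regions (equal width, matching
#'   `occupancy_weights()` length).
#' @param expression_percentile Named vector (by `transcript_id` or
#'   `gene_symbol`) of expression percentiles; regions without an entry
#'   get 0.
#' @param depth_per_region Expected fragments for an undepleted region.
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param sample_id Sample label written to the `sample` column.
#' @return A BED-style data.frame (`chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `sample`), sorted by chrom then start; `name` is
#'   `sample_id:transcript_id`.
#' @export
simulate_fragments <- function(regions, expression_percentile,
                               depth_per_region, config = sim_config(),
                               seed = config$seed, sample_id = "S1") {
  if (nrow(regions) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = integer(), strand = character(),
                      sample = character(), stringsAsFactors = FALSE))
  set.seed(seed)
  width <- regions$end[1] - regions$start[1]
  ref_mass <- sum(occupancy_weights(0, width, config, normalize = FALSE))
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    pct <- expression_percentile[regions$transcript_id[i]]
    if (is.na(pct)) pct <- expression_percentile[regions$gene_symbol[i]]
    if (is.na(pct)) pct <- 0
    w_raw <- occupancy_weights(pct, width, config, normalize = FALSE)
    n_frag <- stats::rpois(1, depth_per_region * sum(w_raw) / ref_mass)
    if (n_frag == 0L) next
    offs <- sample(seq_along(w_raw), n_frag, replace = TRUE,
                   prob = w_raw) - 1L - width %/% 2L
    mid <- if (regions$strand[i] == "-") regions$tss[i] - offs
           else regions$tss[i] + offs
    len <- round(stats::rnorm(n_frag, config$fragment_length_mean,
                              config$fragment_length_sd))
    while (any(bad <- len < 50 | len > 400))
      len[bad] <- round(stats::rnorm(sum(bad), config$fragment_length_mean,
                                     config$fragment_length_sd))
    start <- pmax(0L, as.integer(mid - len %/% 2L))
    out[[i]] <- data.frame(
      chrom = regions$chrom[i], start = start,
      end = as.integer(start + len),
      name = paste0(sample_id, ":", regions$transcript_id[i]),
      score = 0L, strand = regions$strand[i], sample = sample_id,
      stringsAsFactors = FALSE)
  }
  frags <- do.call(rbind, out)
  if (is.null(frags))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = integer(), strand = character(),
                      sample = character(), stringsAsFactors = FALSE))
  frags <- frags[order(frags$chrom, frags$start, frags$end), , drop = FALSE]
  rownames(frags) <- NULL
  frags
}
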