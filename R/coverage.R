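#' Count cfDNA fragments overlapping pTSS regions
#'
#' A fragment counts toward a region when the two intervals share at least
#' one base (0-based half-open on both sides); a fragment spanning two
#' regions counts once in each. If `fragments` carries a `sample` column a
#' regions x samples count matrix is returned, otherwise a single count
#' vector.
#'
#' @param fragments A data.frame of fragment intervals (`chrom`, `start`,
#'   `end`, optional `sample`).
#' @param regions pTSS regions from [build_ptss()].
#' @return An integer matrix (regions x samples) with region
#'   `transcript_id`s as rownames, or a named integer vector when no
#'   `sample` column is present.
#' @export
count_fragments <- function(fragments, regions) {
  stopifnot(is.data.frame(fragments), is.data.frame(regions))
  if (nrow(regions) == 0L) stop("no regions to count over")
  if (nrow(fragments) > 0L &&
      length(intersect(unique(fragments$chrom), unique(regions$chrom))) == 0L)
    stop("no chromosome names shared between fragments and regions; ",
         "check naming convention (e.g., 'chr1' vs '1')")
  gr_reg <- bed_to_granges(regions, strand = "*")
  ids <- regions$transcript_id
  if ("sample" %in% names(fragments)) {
    samples <- unique(fragments$sample)
    counts <- matrix(0L, nrow = nrow(regions), ncol = length(samples),
                     dimnames = list(ids, samples))
    for (s in samples) {
      fr <- fragments[fragments$sample == s, , drop = FALSE]
      counts[, s] <- GenomicRanges::countOverlaps(
        gr_reg, bed_to_granges(fr, strand = "*"), ignore.strand = TRUE)
    }
    counts
  } else {
    n <- GenomicRanges::countOverlaps(
      gr_reg, bed_to_granges(fragments, strand = "*"), ignore.strand = TRUE)
    stats::setNames(as.integer(n), ids)
  }
}

#' Normalize raw pTSS fragment counts to depth-independent coverage
#'
#' Fragments per kilobase of region per million mapped fragments:
#' `raw / ((region_length/1000) * (total_fragments/1e6))`. For the
#' standard 2-kb pTSS window `region_length` is 2000. The value is
#' invariant to uniform subsampling of the library in expectation.
#'
#' @param raw Raw overlap count(s).
#' @param total_fragments Total mapped fragments in the sample (> 0).
#' @param region_length Region width in bp (default 2000).
#' @return Normalized coverage, same shape as `raw`.
#' @export
normalize_coverage <- function(raw, total_fragments, region_length = 2000) {
  if (any(total_fragments <= 0))
    stop("total_fragments must be positive; normalization undefined at 0")
  raw / ((region_length / 1000) * (total_fragments / 1e6))
}

#' Assemble a coverage matrix from fragments and regions
#'
#' Convenience constructor combining [count_fragments()] and
#' [normalize_coverage()] into the samples x regions container used by the
#' differential and classifier stages.
#'
#' @param fragments Fragment intervals with a `sample` column.
#' @param regions pTSS regions.
#' @param total_fragments Optional named vector of per-sample totals;
#'   defaults to the number of fragments observed per sample.
#' @return A list of class `coverage_matrix` with elements `normalized`
#'   and `raw_counts` (samples x regions matrices), `sample_ids`,
#'   `region_ids`, `total_fragments`, `normalization_tag`.
#' @export
coverage_matrix <- function(fragments, regions, total_fragments = NULL) {
  counts <- count_fragments(fragments, regions)
  if (is.null(dim(counts)))
    counts <- matrix(counts, ncol = 1,
                     dimnames = list(names(counts), "S1"))
  counts <- t(counts)  # samples x regions
  if (is.null(total_fragments)) {
    tab <- table(fragments$sample)
    total_fragments <- stats::setNames(as.integer(tab), names(tab))
    total_fragments <- total_fragments[rownames(counts)]
  }
  norm <- sweep(counts, 1,
                (mean(regions$end - regions$start) / 1000) *
                  (total_fragments / 1e6), "/")
  structure(list(
    normalized = norm,
    raw_counts = counts,
    sample_ids = rownames(counts),
    region_ids = colnames(counts),
    total_fragments = total_fragments,
    normalization_tag = "fragments_per_kb_per_million"
  ), class = "coverage_matrix")
}

# Pull the samples x regions numeric matrix out of a coverage_matrix or
# plain matrix argument.
as_coverage <- function(x) {
  if (inherits(x, "coverage_matrix")) x$normalized
  else if (is.matrix(x)) x
  else stop("expected a coverage_matrix or a samples x regions matrix")
}

#' GC-bias reweighting of fragments
#'
#' Histogram reweighting: fragments are binned by GC fraction into
#' `n_bins` equal-width bins on \[0, 1\]; a fragment's weight is the median
#' occupied-bin count divided by its own bin's count, so over-represented
#' GC strata are down-weighted. Corrected region counts are sums of
#' weights of overlapping fragments. Off by default in the pipeline:
#' synthetic cohorts carry no GC bias.
#'
#' @param gc Per-fragment GC fraction in \[0, 1\].
#' @param n_bins Number of histogram bins (>= 2).
#' @return Per-fragment numeric weights.
#' @export
gc_reweight <- function(gc, n_bins = 100L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (any(gc < 0 | gc > 1)) stop("GC fractions must lie in [0, 1]")
  bin <- pmin(pmax(ceiling(gc * n_bins), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  med <- stats::median(counts[counts > 0])
  w <- ifelse(counts > 0, med / counts, 0)
  w[bin]
}

#' Composite per-base depth profile across oriented pTSS windows
#'
#' Computes per-base fragment depth within each region, flips - strand
#' regions so that offset -1000 is always upstream of the TSS, rescales
#' each averaging unit by its sample's mean per-base depth across the
#' profiled regions (removing library-size differences), and returns the
#' mean and standard error over units at each offset. With
#' `by = "region"` the averaging units are regions (gene-set composite
#' profiles); with `by = "sample"` per-sample composite profiles are
#' averaged over samples (group profiles).
#'
#' @param fragments Fragment intervals (optional `sample` column, required
#'   for `by = "sample"`).
#' @param regions Oriented pTSS regions (equal widths).
#' @param by Averaging unit, `"region"` or `"sample"`.
#' @return A data.frame with columns `offset` (-flank .. flank-1),
#'   `mean_depth`, `sem`, and attribute `n_units`.
#' @export
depth_profile <- function(fragments, regions, by = c("region", "sample")) {
  by <- match.arg(by)
  if (nrow(regions) == 0L) stop("empty region subset: no profile to compute")
  width <- unique(regions$end - regions$start)
  if (length(width) != 1L) stop("regions must share a single width")

  per_region_depth <- function(fr) {
    # per-base depth inside each region, oriented; rows = regions
    depth <- matrix(0, nrow = nrow(regions), ncol = width)
    if (nrow(fr) > 0L) {
      for (ch in unique(regions$chrom)) {
        idx <- which(regions$chrom == ch)
        frc <- fr[fr$chrom == ch, , drop = FALSE]
        if (nrow(frc) == 0L) next
        cov <- IRanges::coverage(
          IRanges::IRanges(start = frc$start + 1L, end = frc$end))
        covv <- as.numeric(cov)
        for (i in idx) {
          lo <- regions$start[i] + 1L
          hi <- regions$end[i]
          v <- numeric(width)
          take <- seq.int(lo, hi)
          inside <- take >= 1L & take <= length(covv)
          v[inside] <- covv[take[inside]]
          if (regions$strand[i] == "-") v <- rev(v)
          depth[i, ] <- v
        }
      }
    }
    depth
  }

  if (by == "sample") {
    if (!"sample" %in% names(fragments))
      stop("by = 'sample' requires a 'sample' column in fragments")
    samples <- unique(fragments$sample)
    units <- matrix(0, nrow = length(samples), ncol = width)
    for (k in seq_along(samples)) {
      d <- per_region_depth(
        fragments[fragments$sample == samples[k], , drop = FALSE])
      prof <- colMeans(d)
      m <- mean(prof)
      units[k, ] <- if (m > 0) prof / m else prof
    }
  } else {
    units <- per_region_depth(fragments)
    m <- mean(units)
    if (m > 0) units <- units / m
  }

  n <- nrow(units)
  mu <- colMeans(units)
  sem <- if (n > 1) apply(units, 2, stats::sd) / sqrt(n) else rep(0, width)
  out <- data.frame(offset = seq.int(-width %/% 2, width %/% 2 - 1L),
                    mean_depth = mu, sem = sem)
  attr(out, "n_units") <- n
  out
}

#' Estimate fetal fraction from the chromosome-Y read proportion
#'
#' For a male fetus, the proportion of fragments mapping to chrY scales
#' linearly with the fetal fraction between the maternal background and
#' the fraction observed in pure male DNA:
#' `ff = (pY - background) / (male_reference - background)`, clipped to
#' \[0, 1\].
#'
#' @param fragments Fragment intervals (`chrom` column), or a precomputed
#'   chrY proportion via `p_y`.
#' @param y_chrom Chromosome label counted as Y (default `"chrY"`).
#' @param male_reference_fraction chrY fragment proportion in pure male
#'   genomic DNA.
#' @param female_background_fraction chrY-mapping proportion in
#'   non-pregnant female plasma (mismapping background), default 0.
#' @param p_y Optional precomputed chrY proportion (overrides `fragments`).
#' @return Estimated fetal fraction in \[0, 1\].
#' @export
estimate_ff_chry <- function(fragments = NULL, y_chrom = "chrY",
                             male_reference_fraction,
                             female_background_fraction = 0,
                             p_y = NULL) {
  if (male_reference_fraction <= female_background_fraction)
    stop("male_reference_fraction must exceed female_background_fraction")
  if (is.null(p_y)) {
    if (is.null(fragments) || nrow(fragments) == 0L)
      stop("no fragments: chrY proportion undefined")
    p_y <- mean(fragments$chrom == y_chrom)
  }
  ff <- (p_y - female_background_fraction) /
    (male_reference_fraction - female_background_fraction)
  pmin(pmax(ff, 0), 1)
}
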