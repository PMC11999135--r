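#' Read a refFlat-style gene annotation table
#'
#' Parses UCSC RefSeq / refFlat tab-separated text. Only the first six
#' columns are used: gene symbol, transcript id, chromosome, strand,
#' transcription start and end. Coordinates are 0-based half-open, as in
#' all UCSC genePred-derived formats.
#'
#' @param path Path to a refFlat (or genePred with ids) text file, no header.
#' @return A data.frame with columns `gene_symbol`, `transcript_id`,
#'   `chrom`, `strand`, `txStart`, `txEnd`.
#' @export
read_refflat <- function(path) {
  anno <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, comment.char = "#",
                            quote = "")
  if (ncol(anno) < 6)
    stop("refFlat file must have at least 6 columns, got ", ncol(anno))
  anno <- anno[, 1:6]
  names(anno) <- c("gene_symbol", "transcript_id", "chrom", "strand",
                   "txStart", "txEnd")
  anno$txStart <- as.integer(anno$txStart)
  anno$txEnd <- as.integer(anno$txEnd)
  anno
}

#' Read a BED interval file
#'
#' Minimal validating reader for BED3/BED6 (0-based half-open). Malformed
#' lines (fewer than 3 fields, non-numeric or inverted coordinates) raise
#' an error naming the offending line number.
#'
#' @param path Path to a BED file.
#' @return A data.frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  for (i in seq_along(fields)) {
    if (nf[i] < 3L)
      stop("malformed BED line ", i, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(fields[[i]][2]))
    e <- suppressWarnings(as.numeric(fields[[i]][3]))
    if (is.na(s) || is.na(e))
      stop("malformed BED line ", i, ": non-numeric coordinates")
    if (e < s)
      stop("malformed BED line ", i, ": end < start")
  }
  out <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = as.integer(vapply(fields, `[`, "", 2L)),
    end   = as.integer(vapply(fields, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  if (all(nf >= 4L)) out$name <- vapply(fields, `[`, "", 4L)
  if (all(nf >= 5L)) out$score <- suppressWarnings(
    as.numeric(vapply(fields, `[`, "", 5L)))
  if (all(nf >= 6L)) out$strand <- vapply(fields, `[`, "", 6L)
  out
}

#' Write intervals to a BED file
#'
#' @param x A data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand` (written as BED6 when all three are present).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end")
  if (all(c("name", "score", "strand") %in% names(x)))
    cols <- c(cols, "name", "score", "strand")
  else if ("name" %in% names(x))
    cols <- c(cols, "name")
  utils::write.table(x[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Convert a 0-based half-open interval data.frame to GRanges (1-based closed).
bed_to_granges <- function(x, strand = NULL) {
  if (nrow(x) == 0L)
    return(GenomicRanges::GRanges())
  s <- if (!is.null(strand)) strand
       else if ("strand" %in% names(x)) x$strand
       else "*"
  s[!s %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = s
  )
}

#' Build promoter (pTSS) windows around transcription start sites
#'
#' For each transcript the promoter window spans `flank` bp on either side
#' of the transcription start site: the TSS is `txStart` for + strand
#' transcripts and `txEnd - 1` for - strand transcripts (0-based half-open
#' convention throughout), and the window is `[tss - flank, tss + flank)`,
#' i.e., exactly `2 * flank` bp. cfDNA coverage in this window reflects the
#' nucleosome footprint of the promoter: expressed promoters are
#' nucleosome-depleted and yield lower coverage.
#'
#' Records with an unknown strand symbol are dropped with a warning, as are
#' windows that would extend below position 0. Transcripts producing the
#' same window (chrom/start/end/strand) are collapsed into one region whose
#' ids are comma-concatenated.
#'
#' @param annotation A data.frame as returned by [read_refflat()] (columns
#'   `chrom`, `strand`, `txStart`, `txEnd`, `transcript_id`, `gene_symbol`).
#' @param flank Half-width of the promoter window in bp (default 1000,
#'   giving the standard 2-kb pTSS window).
#' @return A data.frame of pTSS regions with columns `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `transcript_id`, `gene_symbol`,
#'   `tss`. Every region has width `2 * flank`.
#' @export
build_ptss <- function(annotation, flank = 1000L) {
  stopifnot(is.data.frame(annotation), flank > 0)
  req <- c("chrom", "strand", "txStart", "txEnd")
  if (!all(req %in% names(annotation)))
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  if (!"transcript_id" %in% names(annotation))
    annotation$transcript_id <- paste0("tx", seq_len(nrow(annotation)))
  if (!"gene_symbol" %in% names(annotation))
    annotation$gene_symbol <- annotation$transcript_id

  bad <- !annotation$strand %in% c("+", "-")
  if (any(bad)) {
    warning(sum(bad), " record(s) with unknown strand symbol dropped")
    annotation <- annotation[!bad, , drop = FALSE]
  }
  if (nrow(annotation) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      transcript_id = character(), gene_symbol = character(),
                      tss = integer(), stringsAsFactors = FALSE))

  tss <- ifelse(annotation$strand == "+",
                annotation$txStart, annotation$txEnd - 1L)
  start <- as.integer(tss - flank)
  end <- as.integer(tss + flank)
  keep <- start >= 0L
  regions <- data.frame(
    chrom = annotation$chrom[keep],
    start = start[keep],
    end = end[keep],
    strand = annotation$strand[keep],
    transcript_id = annotation$transcript_id[keep],
    gene_symbol = annotation$gene_symbol[keep],
    tss = as.integer(tss[keep]),
    stringsAsFactors = FALSE
  )

  key <- paste(regions$chrom, regions$start, regions$end, regions$strand)
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    tid <- vapply(split(regions$transcript_id, key), paste, "",
                  collapse = ",")
    gsym <- vapply(split(regions$gene_symbol, key),
                   function(g) paste(unique(g), collapse = ","), "")
    regions <- regions[first, , drop = FALSE]
    regions$transcript_id <- tid[key[first]]
    regions$gene_symbol <- gsym[key[first]]
  }
  rownames(regions) <- NULL
  regions
}

#' Remove pTSS regions overlapping blacklist intervals
#'
#' A region sharing at least one base with any blacklist interval (both
#' 0-based half-open) is removed; touching intervals do not overlap. This
#' mirrors the removal of promoter windows falling in signal-artifact
#' blacklist regions (e.g., the ENCODE/Duke blacklist) before coverage
#' profiling.
#'
#' @param regions pTSS regions from [build_ptss()].
#' @param blacklist A data.frame of intervals (`chrom`, `start`, `end`),
#'   e.g., from [read_bed()].
#' @return The subset of `regions` with no blacklist overlap, input order
#'   preserved.
#' @export
filter_blacklist <- function(regions, blacklist) {
  if (nrow(regions) == 0L || is.null(blacklist) || nrow(blacklist) == 0L)
    return(regions)
  gr <- bed_to_granges(regions, strand = "*")
  bl <- bed_to_granges(blacklist, strand = "*")
  hit <- IRanges::overlapsAny(gr, bl, ignore.strand = TRUE)
  out <- regions[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
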