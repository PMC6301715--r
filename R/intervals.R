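# Genomic intervals are plain data.frames in BED convention throughout the
# package: columns chrom, start, end, name, score, strand with 0-based,
# half-open [start, end) coordinates. Interval sets ("peak sets") are kept
# sorted by (chrom, start).

#' Construct a genomic interval table
#'
#' @param chrom chromosome names
#' @param start 0-based inclusive starts
#' @param end exclusive ends
#' @param name optional feature names
#' @param score optional numeric score (e.g. tag density per 10M reads)
#' @param strand one of "+", "-", "." per interval
#' @param sort sort by (chrom, start)? Default TRUE.
#' @return data.frame with class `genomic_intervals`
#' @export
genomic_intervals <- function(chrom, start, end, name = ".", score = 0,
                              strand = ".", sort = TRUE) {
  if (any(start < 0)) stop("negative start coordinate")
  if (any(start >= end)) stop("start must be < end (0-based half-open)")
  if (any(!nzchar(chrom))) stop("chrom must be non-empty")
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   name = as.character(name), score = as.numeric(score),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  if (sort) df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Read a BED3-BED6 file
#'
#' Coordinates are kept 0-based half-open, exactly as stored in BED.
#' Malformed intervals raise an error naming the offending line.
#'
#' @param path path to a BED file
#' @return a `genomic_intervals` data.frame, sorted by (chrom, start)
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty BED file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    stop("BED line ", bad[1], ": invalid interval (need 0 <= start < end)")
  }
  grab <- function(k, default) {
    vapply(fields, function(f) if (length(f) >= k) f[k] else default, "")
  }
  genomic_intervals(
    chrom = vapply(fields, `[`, "", 1L), start = start, end = end,
    name = grab(4L, "."),
    score = suppressWarnings(as.numeric(grab(5L, "0"))),
    strand = grab(6L, "."))
}

#' Write intervals as BED6
#'
#' @param x a `genomic_intervals` data.frame
#' @param path output path
#' @export
write_bed <- function(x, path) {
  out <- data.frame(x$chrom, x$start, x$end,
                    x$name %||% ".", x$score %||% 0, x$strand %||% ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# IRanges view of one chromosome's intervals (1-based closed coordinates).
.as_iranges <- function(x) IRanges::IRanges(start = x$start + 1L, end = x$end)

#' All pairs of overlapping intervals between two sets
#'
#' @param a,b `genomic_intervals` tables
#' @param min_bp minimum overlap in bases (default 1)
#' @return data.frame with columns `query` (row index in `a`), `subject`
#'   (row index in `b`) and `overlap_bp`
#' @export
overlap_pairs <- function(a, b, min_bp = 1L) {
  stopifnot(min_bp >= 1)
  res <- list()
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == chr)
    ib <- which(b$chrom == chr)
    hits <- IRanges::findOverlaps(.as_iranges(a[ia, ]), .as_iranges(b[ib, ]),
                                  minoverlap = min_bp)
    qi <- ia[S4Vectors::queryHits(hits)]
    si <- ib[S4Vectors::subjectHits(hits)]
    ov <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
    res[[chr]] <- data.frame(query = qi, subject = si, overlap_bp = ov)
  }
  if (length(res) == 0) {
    return(data.frame(query = integer(), subject = integer(),
                      overlap_bp = integer()))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$query, out$subject), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive TSS positions from a gene annotation
#'
#' The TSS is the interval start on the plus strand and `end - 1` on the
#' minus strand (0-based coordinates).
#'
#' @param genes BED6-style gene table with strand
#' @return data.frame with columns chrom, pos, gene
#' @export
tss_from_genes <- function(genes) {
  pos <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  data.frame(chrom = genes$chrom, pos = as.integer(pos),
             gene = genes$name, stringsAsFactors = FALSE)
}

#' Signed distance from each peak center to its nearest TSS
#'
#' Distance is peak center minus TSS position of the nearest TSS (smallest
#' absolute distance; ties broken toward the smaller TSS coordinate). Peaks
#' on chromosomes with no TSS get NA and are flagged in `defined`.
#'
#' @param peaks `genomic_intervals` table
#' @param tss data.frame with columns chrom, pos (see [tss_from_genes()])
#' @return data.frame with columns name, chrom, center, distance, defined
#' @export
distance_to_nearest_tss <- function(peaks, tss) {
  if (nrow(tss) == 0) stop("empty TSS set")
  center <- interval_center(peaks)
  dist <- rep(NA_real_, nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    ip <- which(peaks$chrom == chr)
    tp <- sort(tss$pos[tss$chrom == chr])
    if (length(tp) == 0) next
    idx <- findInterval(center[ip], tp)
    lo <- pmax(idx, 1L)            # candidate at or below
    hi <- pmin(idx + 1L, length(tp))  # candidate above
    d_lo <- center[ip] - tp[lo]
    d_hi <- center[ip] - tp[hi]
    no_lo <- idx == 0L
    # tie (equal |distance|) resolves to the smaller coordinate (lo)
    use_hi <- no_lo | (!no_lo & abs(d_hi) < abs(d_lo))
    dist[ip] <- ifelse(use_hi, d_hi, d_lo)
  }
  data.frame(name = peaks$name, chrom = peaks$chrom, center = center,
             distance = dist, defined = !is.na(dist),
             stringsAsFactors = FALSE)
}

#' Center coordinate of each interval
#'
#' @param x `genomic_intervals` table
#' @return integer vector, floor((start + end) / 2)
#' @export
interval_center <- function(x) as.integer(floor((x$start + x$end) / 2))

#' Fixed-width window around each interval's center
#'
#' Windows are clipped at coordinate 0 (the chromosome start); a clipped
#' window is shorter than `width`.
#'
#' @param x `genomic_intervals` table
#' @param width even positive window width in bases
#' @return `genomic_intervals` table of windows (input order preserved)
#' @export
window_around_center <- function(x, width) {
  stopifnot(width > 0, width %% 2 == 0)
  center <- interval_center(x)
  half <- width %/% 2
  genomic_intervals(chrom = x$chrom, start = pmax(0L, center - half),
                    end = center + half, name = x$name, score = x$score,
                    strand = x$strand, sort = FALSE)
}
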