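#' STR region catalog
#'
#' Construct a validated catalog of short-tandem-repeat regions.  Coordinates
#' are 0-based half-open (BED convention).  The repeat period (unit length)
#' must be 1..6 and the unit must spell the period exactly.
#'
#' @param chrom Character vector of reference sequence names.
#' @param start,end Integer vectors, 0-based half-open interval bounds.
#' @param period Integer vector of repeat-unit lengths in bp (1..6).
#' @param unit Character vector of repeat units (uppercase A/C/G/T).
#' @return A `data.frame` of class `str_regions` with columns `chrom`,
#'   `start`, `end`, `period`, `unit`, `ref_size`.
#' @examples
#' str_regions("chr1", 100L, 120L, 2L, "AC")
#' @export
str_regions <- function(chrom, start, end, period, unit) {
  start <- as.integer(start); end <- as.integer(end)
  period <- as.integer(period); unit <- toupper(as.character(unit))
  if (any(period < 1L | period > 6L))
    stop("period must be between 1 and 6")
  if (any(nchar(unit) != period))
    stop("unit length must equal period")
  if (any(!grepl("^[ACGT]+$", unit)))
    stop("unit may contain only A/C/G/T")
  if (any(start >= end))
    stop("start must be < end")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    period = period, unit = unit,
                    ref_size = end - start, stringsAsFactors = FALSE)
  class(out) <- c("str_regions", "data.frame")
  out
}

#' Read an STR region catalog
#'
#' Reads a BED-like tab-separated catalog with columns
#' `chrom start end period unit`.  Lines starting with `#` are ignored.
#'
#' @param path Path to the catalog file.
#' @return An [str_regions] data frame.
#' @export
read_str_catalog <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  if (length(lines) == 0L) stop("catalog is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L))
    stop("malformed catalog line(s): ", paste(which(keep)[nf < 5L], collapse = ", "))
  mat <- t(vapply(fields, function(f) f[1:5], character(5)))
  str_regions(mat[, 1], as.integer(mat[, 2]), as.integer(mat[, 3]),
              as.integer(mat[, 4]), mat[, 5])
}

#' Write an STR region catalog
#'
#' @param regions An [str_regions] data frame.
#' @param path Output path.
#' @export
write_str_catalog <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end", "period", "unit")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter a catalog by reference tract size
#'
#' Drops regions whose reference tract is longer than `max_size` bp (short
#' reads cannot span longer tracts, so they are excluded from benchmarks).
#' The boundary is inclusive: a region of exactly `max_size` bp is kept.
#'
#' @param regions An [str_regions] data frame.
#' @param max_size Maximum reference tract size in bp (default 100).
#' @return The filtered catalog.
#' @export
filter_catalog <- function(regions, max_size = 100L) {
  stopifnot(max_size > 0)
  regions[regions$ref_size <= max_size, , drop = FALSE]
}

#' Long-homopolymer screen
#'
#' Bases following long homopolymer runs are enriched for sequencing errors
#' on Illumina instruments; realignment of such regions is counterproductive
#' and can be skipped.  A region is screened out when its period is 1 and its
#' reference tract is at least `threshold` bp.
#'
#' @param regions An [str_regions] data frame (or a single-row subset).
#' @param threshold Minimum homopolymer length in bp to skip (default 15).
#' @return Logical vector, `TRUE` for regions to skip.
#' @export
is_long_homopolymer <- function(regions, threshold = 15L) {
  stopifnot(threshold >= 1)
  regions$period == 1L & regions$ref_size >= threshold
}

#' Extract the maximal clean repeat tract within a region
#'
#' Catalogued STR intervals frequently include irregular bases that do not
#' follow the annotated unit.  This scans the region sequence for the longest
#' interval that, read in frame with the unit anchored at the interval start,
#' mismatches tandem copies of the unit in at most `error_rate` of its bases.
#' The leftmost interval wins ties.
#'
#' @param region_seq Character scalar, the reference sequence of the region.
#' @param unit Repeat unit (uppercase DNA).
#' @param error_rate Maximum tolerated in-frame mismatch fraction (default
#'   0.1).
#' @return `list(offset =, length =)`, 0-based offset within the region, or
#'   `NULL` if no interval of at least one unit length passes the threshold
#'   (the region then carries no usable repeat tract).
#' @examples
#' extract_maximal_repeat_region("GGACACACTG", "AC", 0)   # offset 2, length 6
#' @export
extract_maximal_repeat_region <- function(region_seq, unit, error_rate = 0.1) {
  region_seq <- toupper(region_seq); unit <- toupper(unit)
  L <- nchar(region_seq); u <- nchar(unit)
  stopifnot(u >= 1, L >= u, error_rate >= 0, error_rate <= 1)
  rb <- strsplit(region_seq, "", fixed = TRUE)[[1]]
  ub <- strsplit(unit, "", fixed = TRUE)[[1]]
  best_len <- 0L; best_off <- NA_integer_
  for (s in seq_len(L)) { # candidate start (1-based), unit frame anchored here
    max_len <- L - s + 1L
    if (max_len < u || max_len <= best_len) next
    mism <- rb[s:L] != ub[((seq_len(max_len) - 1L) %% u) + 1L]
    cm <- cumsum(mism)
    lens <- seq_len(max_len)
    ok <- lens >= u & cm <= error_rate * lens
    if (!any(ok)) next
    len <- max(lens[ok])
    if (len > best_len) { best_len <- len; best_off <- s - 1L }
  }
  if (best_len == 0L) return(NULL)
  list(offset = best_off, length = best_len)
}

#' Trim catalog regions to their maximal clean repeat tracts
#'
#' Applies [extract_maximal_repeat_region] to every region against the
#' reference and replaces each interval with its trimmed tract.  Regions with
#' no usable tract are dropped with a warning.
#'
#' @param regions An [str_regions] data frame.
#' @param reference A named character vector or `Biostrings::DNAStringSet` of
#'   reference sequences.
#' @param error_rate Mismatch fraction tolerated in the tract (default 0.1).
#' @return The trimmed catalog (possibly fewer rows).
#' @export
trim_regions <- function(regions, reference, error_rate = 0.1) {
  reference <- as_reference(reference)
  keep <- logical(nrow(regions))
  for (r in seq_len(nrow(regions))) {
    rseq <- ref_subseq(reference, regions$chrom[r],
                       regions$start[r], regions$end[r])
    tr <- extract_maximal_repeat_region(rseq, regions$unit[r], error_rate)
    if (is.null(tr)) next
    keep[r] <- TRUE
    regions$start[r] <- regions$start[r] + tr$offset
    regions$end[r] <- regions$start[r] + tr$length
  }
  if (any(!keep))
    warning(sum(!keep), " region(s) without a usable repeat tract dropped")
  regions$ref_size <- regions$end - regions$start
  regions[keep, , drop = FALSE]
}

# Reference access helpers: accept a named character vector, a DNAStringSet
# or a FASTA path; always hand back a named character vector.
as_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference) && !grepl("^[ACGTNacgtn]+$", reference)) {
    dss <- Biostrings::readDNAStringSet(reference)
    reference <- as.character(dss)
    names(reference) <- sub("\\s.*$", "", names(reference))
  } else if (inherits(reference, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(reference))
    reference <- as.character(reference)
    names(reference) <- nm
  }
  stopifnot(is.character(reference), !is.null(names(reference)))
  reference
}

# 0-based half-open subsequence of a reference chromosome.
ref_subseq <- function(reference, chrom, start, end) {
  seq <- reference[[chrom]]
  if (is.null(seq)) stop("chromosome not in reference: ", chrom)
  if (start < 0 || end > nchar(seq)) stop("region outside reference bounds")
  substr(seq, start + 1L, end)
}
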