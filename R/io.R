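#' Tabular and genomic-format readers and writers
#'
#' All tabular interchange is headered TSV; intervals use the BED family.
#' Coordinate conventions are converted exactly once at the I/O boundary:
#' BED files are 0-based half-open on disk; CpG positions and DMR intervals
#' are 1-based inclusive internally; the Bismark coverage dialect stores the
#' 1-based position in both coordinate columns.
#'
#' @name mzt_io
#' @param path File path.
#' @param x Object to write.
NULL

tsv_cols <- function(path, required, what) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(tbl))
  if (length(miss)) {
    stop(what, " '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tbl
}

#' @rdname mzt_io
#' @export
read_counts_tsv <- function(path) tsv_cols(path, "gene_id", "counts table")

#' @rdname mzt_io
#' @export
write_counts_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname mzt_io
#' @export
read_sample_sheet <- function(path) {
  tsv_cols(path, c("sample_id", "stage", "genotype", "treatment", "replicate"),
           "sample sheet")
}

#' @rdname mzt_io
#' @export
write_sample_sheet <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname mzt_io
#' @details `read_bismark_cov()` reads the Bismark coverage dialect
#'   (chrom, start, end, percent methylation, methylated count, unmethylated
#'   count; 1-based positions). The percent column is recomputed from the
#'   counts on read and a deviation beyond 0.5 percentage points (files store
#'   rounded percentages) raises an error naming the line.
#' @export
read_bismark_cov <- function(path) {
  tbl <- readr::read_tsv(path,
                         col_names = c("chrom", "start", "end", "pct", "m", "u"),
                         col_types = "ciinii", progress = FALSE)
  depth <- tbl$m + tbl$u
  bad <- which(depth > 0 & abs(tbl$pct - 100 * tbl$m / depth) > 0.5)
  if (length(bad)) {
    stop("percent-methylation column disagrees with counts in '", path,
         "' at line(s) ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(chrom = tbl$chrom, pos = tbl$start, m = tbl$m, u = tbl$u)
}

#' @rdname mzt_io
#' @export
write_bismark_cov <- function(x, path) {
  depth <- x$m + x$u
  out <- data.frame(chrom = x$chrom, start = x$pos, end = x$pos,
                    pct = round(100 * x$m / pmax(depth, 1), 2),
                    m = x$m, u = x$u)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

read_bed_lines <- function(path, min_fields) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < min_fields)
  if (length(bad)) {
    stop("malformed BED line ", bad[1], " in '", path, "': expected at least ",
         min_fields, " fields, found ", nf[bad[1]], call. = FALSE)
  }
  parts
}

bed_coords <- function(parts, path) {
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | end <= start | start < 0)
  if (length(bad)) {
    stop("malformed BED line ", bad[1], " in '", path,
         "': invalid interval coordinates", call. = FALSE)
  }
  list(chrom = vapply(parts, `[[`, "", 1), start = start, end = end)
}

#' @rdname mzt_io
#' @details `read_bed()` reads BED3+ (including the package's BED6-with-signal
#'   dialect, signal in column 5, and narrowPeak, signal in column 7);
#'   malformed lines raise an error with the line number.
#' @export
read_bed <- function(path) {
  parts <- read_bed_lines(path, 3)
  co <- bed_coords(parts, path)
  nf <- min(lengths(parts))
  out <- tibble::tibble(chrom = co$chrom, start = co$start, end = co$end)
  if (nf >= 4) out$name <- vapply(parts, `[[`, "", 4)
  if (nf >= 5) out$signal <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 5)))
  if (nf >= 6) out$strand <- vapply(parts, `[[`, "", 6)
  if (nf >= 10) out$signal <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 7)))
  out
}

#' @rdname mzt_io
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "signal", "strand"),
                    names(x))
  readr::write_tsv(x[cols], path, col_names = FALSE)
  invisible(path)
}

#' @rdname mzt_io
#' @export
read_bed12 <- function(path) {
  parts <- read_bed_lines(path, 12)
  co <- bed_coords(parts, path)
  f <- function(i) vapply(parts, `[[`, "", i)
  tibble::tibble(
    chrom = co$chrom, start = co$start, end = co$end, name = f(4),
    score = suppressWarnings(as.numeric(f(5))), strand = f(6),
    thick_start = as.numeric(f(7)), thick_end = as.numeric(f(8)),
    rgb = f(9), block_count = as.integer(f(10)),
    block_sizes = sub(",$", "", f(11)), block_starts = sub(",$", "", f(12))
  )
}

#' @rdname mzt_io
#' @export
write_bed12 <- function(x, path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand", "thick_start",
            "thick_end", "rgb", "block_count", "block_sizes", "block_starts")
  readr::write_tsv(x[cols], path, col_names = FALSE)
  invisible(path)
}

#' @rdname mzt_io
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x[nzchar(x)]
}

#' @rdname mzt_io
#' @export
write_gene_list <- function(x, path) {
  readr::write_lines(x, path)
  invisible(path)
}

#' Coordinate conversion between BED and 1-based inclusive intervals
#'
#' `bed_to_pos1()` converts a 0-based half-open (start, end) pair to 1-based
#' inclusive; `pos1_to_bed()` is its inverse. Applied exactly once at I/O
#' boundaries.
#'
#' @param start,end Interval coordinates.
#' @return A list with `start` and `end` in the target convention.
#' @export
bed_to_pos1 <- function(start, end) list(start = start + 1, end = end)

#' @rdname bed_to_pos1
#' @export
pos1_to_bed <- function(start, end) list(start = start - 1, end = end)
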