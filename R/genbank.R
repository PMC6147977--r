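#' Record-level statistics of a GenBank flat file
#'
#' Parses an annotated genome record (GenBank flat-file format) and reports
#' sequence length, GC content, and feature counts.  GC is computed as
#' `(G + C) / (A + C + G + T) * 100` over the ORIGIN sequence — ambiguity
#' codes are excluded from both numerator and denominator — and rounded
#' half-up to 2 decimals.  `n_cds` and `n_trna` count `CDS` and `tRNA`
#' feature keys.  Only the fields needed for these statistics are parsed;
#' feature qualifiers and sequence annotation are ignored.
#'
#' @param path Path to a GenBank flat file (one or more records).
#' @return For a single-record file, a `genome_record_stats` list with
#'   `record_id`, `length`, `gc_percent`, `n_cds`, `n_trna`; for a
#'   multi-record file, a list of such objects.
#' @export
genome_record_stats <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop(sprintf("'%s' is empty", path), call. = FALSE)
  ends <- grep("^//\\s*$", lines)
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  records <- Map(function(s, e) lines[s:e], starts, ends)
  records <- Filter(function(r) any(grepl("^LOCUS", r)), records)
  if (!length(records)) stop(sprintf("'%s': no LOCUS record found", path),
                             call. = FALSE)
  out <- lapply(records, parse_genbank_record)
  if (length(out) == 1L) out[[1L]] else out
}

parse_genbank_record <- function(lines) {
  locus <- lines[grep("^LOCUS", lines)[1L]]
  record_id <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1L]][1L]
  acc <- grep("^VERSION", lines, value = TRUE)
  if (length(acc)) {
    v <- strsplit(trimws(sub("^VERSION", "", acc[1L])), "\\s+")[[1L]][1L]
    if (nzchar(v)) record_id <- v
  }

  feat_start <- grep("^FEATURES", lines)
  origin <- grep("^ORIGIN", lines)
  n_cds <- 0L; n_trna <- 0L
  if (length(feat_start)) {
    feat_end <- if (length(origin)) origin[1L] - 1L else length(lines)
    feats <- lines[(feat_start[1L] + 1L):feat_end]
    # feature keys sit at column 6 of the flat file
    keys <- sub("^\\s+(\\S+).*$", "\\1", grep("^ {5}\\S", feats, value = TRUE))
    n_cds <- sum(keys == "CDS")
    n_trna <- sum(keys == "tRNA")
  }

  if (!length(origin))
    stop(sprintf("record '%s': missing ORIGIN sequence", record_id),
         call. = FALSE)
  seq_lines <- lines[(origin[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(seq))
    stop(sprintf("record '%s': missing ORIGIN sequence", record_id),
         call. = FALSE)

  counts <- table(strsplit(seq, "", fixed = TRUE)[[1L]])
  n <- function(b) if (b %in% names(counts)) as.integer(counts[[b]]) else 0L
  acgt <- n("A") + n("C") + n("G") + n("T")
  gc <- if (acgt == 0) 0 else (n("G") + n("C")) / acgt * 100
  structure(list(record_id = record_id, length = nchar(seq),
                 gc_percent = round_half_up(gc, 2L), n_cds = n_cds,
                 n_trna = n_trna),
            class = "genome_record_stats")
}

round_half_up <- function(x, digits = 0L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' @export
print.genome_record_stats <- function(x, ...) {
  cat(sprintf("<genome_record_stats> %s: %s bp, GC %.2f%%, %d CDS, %d tRNA\n",
              x$record_id, format(x$length, big.mark = ","), x$gc_percent,
              x$n_cds, x$n_trna))
  invisible(x)
}
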