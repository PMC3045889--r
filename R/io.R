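#' Read ditag reads from FASTA or FASTQ
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; plain or gzipped files
#' are handled transparently and record ids are preserved (so that rejection
#' logs can name the offending read).
#'
#' @param path Path to a FASTA or FASTQ file (optionally .gz).
#' @param format `"fasta"`, `"fastq"`, or `"auto"` to infer from the filename.
#' @return Named character vector of reads.
#' @export
read_ditag_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  out <- as.character(x)
  # keep the id up to the first whitespace, as aligners do
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' @param x Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' Write / read a UniTag count matrix as TSV
#'
#' The flat layout has a `#`-prefixed header block with one line of library
#' metadata per library (`# library\tid\torgan\tcondition\ttotal_tags`),
#' followed by a tab-separated table `unitag_id`, `sequence`, one integer
#' column per library.
#'
#' @param x A `tag_counts` object.
#' @param path File path.
#' @return `write_tag_counts()` returns `path` invisibly; `read_tag_counts()`
#'   returns a `tag_counts` object.
#' @export
write_tag_counts <- function(x, path) {
  stopifnot(inherits(x, "tag_counts"))
  libs <- tag_libraries(x)
  hdr <- sprintf("# library\t%s\t%s\t%s\t%d", libs$id, libs$organ, libs$condition, libs$total_tags)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(x), con,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_tag_counts
#' @export
read_tag_counts <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^# library\t", lines)
  meta <- strsplit(sub("^# library\t", "", lines[hdr]), "\t")
  libs <- tibble(
    id = vapply(meta, `[`, "", 1),
    organ = vapply(meta, `[`, "", 2),
    condition = vapply(meta, `[`, "", 3)
  )
  body <- utils::read.table(
    text = lines[!hdr], sep = "\t", header = TRUE,
    colClasses = "character", check.names = FALSE
  )
  for (l in libs$id) body[[l]] <- as.integer(body[[l]])
  new_tag_counts(as_tibble(body), libs)
}

#' Read pairwise hits in BLAST tabular (outfmt 6) layout
#'
#' Expects at least the first four of the standard twelve columns
#' (`qseqid sseqid pident length ...`); an `evalue` column (11) is kept when
#' present. Malformed rows raise a warning with their line number; more than
#' `max_errors` malformed rows abort the import.
#'
#' @param path Path to the tabular file.
#' @param max_errors Error budget before the whole file is rejected.
#' @return Tibble `query`, `subject`, `pident`, `length`, and `evalue`
#'   (NA when the file has fewer than 11 columns).
#' @export
read_blast_tab <- function(path, max_errors = 10) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(
      query = character(), subject = character(),
      pident = numeric(), length = integer(), evalue = numeric()
    ))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  pident <- suppressWarnings(vapply(parts, function(p) as.numeric(p[3]), numeric(1)))
  len <- suppressWarnings(vapply(parts, function(p) as.numeric(p[4]), numeric(1)))
  bad <- lengths(parts) < 4 | is.na(pident) | is.na(len)
  if (any(bad)) {
    if (sum(bad) > max_errors) {
      abort(sprintf("%d malformed rows in '%s' (budget %d)", sum(bad), path, max_errors))
    }
    warn(sprintf(
      "skipping %d malformed row(s) at line(s) %s",
      sum(bad), paste(which(bad), collapse = ", ")
    ))
    parts <- parts[!bad]; pident <- pident[!bad]; len <- len[!bad]
  }
  tibble(
    query = vapply(parts, `[`, "", 1),
    subject = vapply(parts, `[`, "", 2),
    pident = pident,
    length = as.integer(len),
    evalue = suppressWarnings(vapply(parts, function(p) as.numeric(p[11]), numeric(1)))
  )
}
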