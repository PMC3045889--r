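#' Extract anchored 26 bp tags from ditag reads
#'
#' A ditag read carries two SuperSAGE tags ligated tail-to-tail: the first tag
#' read in sense orientation from position 1, the second recovered as the
#' reverse complement of the last 26 bases. Both tags must be 26 bp, start
#' with the NlaIII anchor `CATG` (so the read itself must start *and* end with
#' `CATG`), and contain only unambiguous bases. Accepted read lengths default
#' to 50--54 bp (EcoP15I cut-length variation around the nominal 52 bp ditag).
#'
#' A read is *rejected* only when it yields no tag at all; a read whose first
#' tag passes but whose second anchor is missing still yields one tag, and the
#' failure is tallied per tag in the report. Rejection reasons are
#' `no_start_anchor`, `no_end_anchor`, `bad_length` and `ambiguous_base`
#' (non-ACGT IUPAC codes reject the affected tag; characters outside the IUPAC
#' alphabet reject the whole read).
#'
#' @param reads Character vector of uppercase DNA reads, one ditag per
#'   element. Names are used as read ids (auto-generated when absent).
#' @param min_len,max_len Accepted read length window.
#' @return A tibble with columns `read_id`, `end` (1 = 5' tag, 2 = 3' tag) and
#'   `tag`, carrying an [extraction_report] in attribute `"report"` (see
#'   [extraction_report()]).
#' @seealso [count_tags()] to turn extracted tags into a count matrix.
#' @export
#' @examples
#' read <- paste0("CATG", strrep("A", 22), strrep("G", 22), "CATG")
#' extract_ditag_tags(read)
extract_ditag_tags <- function(reads, min_len = 50, max_len = 54) {
  if (length(reads) == 0) {
    return(structure(
      tibble(read_id = character(), end = integer(), tag = character()),
      report = new_extraction_report(0L, 0L, integer(4), integer(3)),
      class = c("tag_extraction", class(tibble()))
    ))
  }
  ids <- names(reads) %||% paste0("read_", seq_along(reads))
  reads <- unname(toupper(reads))

  reasons <- c("no_start_anchor", "no_end_anchor", "bad_length", "ambiguous_base")
  read_rej <- setNames(integer(4), reasons)
  tag_rej <- setNames(integer(3), c("no_start_anchor", "no_end_anchor", "ambiguous_base"))

  len <- nchar(reads)
  whole_bad <- !iupac_ok(reads)
  len_bad <- !whole_bad & (len < min_len | len > max_len)

  read_rej["ambiguous_base"] <- sum(whole_bad)
  read_rej["bad_length"] <- sum(len_bad)

  usable <- !whole_bad & !len_bad
  out_id <- character(0); out_end <- integer(0); out_tag <- character(0)

  if (any(usable)) {
    u <- which(usable)
    tag1 <- substr(reads[u], 1L, 26L)
    tag2 <- revcomp(substr(reads[u], len[u] - 25L, len[u]))

    ok1 <- is_valid_tag(tag1)
    ok2 <- is_valid_tag(tag2)
    # reason for a failed tag: missing anchor beats ambiguity
    r1 <- ifelse(!startsWith(tag1, "CATG"), "no_start_anchor", "ambiguous_base")
    r2 <- ifelse(!startsWith(tag2, "CATG"), "no_end_anchor", "ambiguous_base")

    accepted <- ok1 | ok2
    # reads with zero tags: read-level rejection, tag1's reason takes precedence
    if (any(!accepted)) {
      tab <- table(r1[!accepted])
      read_rej[names(tab)] <- read_rej[names(tab)] + as.integer(tab)
    }
    # tag-level failures inside accepted reads
    t1_fail <- accepted & !ok1
    t2_fail <- accepted & !ok2
    if (any(t1_fail)) {
      tab <- table(r1[t1_fail]); tag_rej[names(tab)] <- tag_rej[names(tab)] + as.integer(tab)
    }
    if (any(t2_fail)) {
      tab <- table(r2[t2_fail]); tag_rej[names(tab)] <- tag_rej[names(tab)] + as.integer(tab)
    }

    out_id <- c(ids[u][ok1], ids[u][ok2])
    out_end <- c(rep(1L, sum(ok1)), rep(2L, sum(ok2)))
    out_tag <- c(tag1[ok1], tag2[ok2])
    n_accepted <- sum(accepted)
  } else {
    n_accepted <- 0L
  }

  ord <- order(match(out_id, ids), out_end)
  res <- tibble(read_id = out_id[ord], end = out_end[ord], tag = out_tag[ord])
  structure(
    res,
    report = new_extraction_report(length(reads), n_accepted, read_rej, tag_rej),
    class = c("tag_extraction", class(res))
  )
}

new_extraction_report <- function(seen, accepted, read_rej, tag_rej) {
  structure(
    list(
      reads_seen = as.integer(seen),
      reads_accepted = as.integer(accepted),
      reads_rejected_by_reason = read_rej,
      tags_rejected_by_reason = tag_rej
    ),
    class = "extraction_report"
  )
}

#' Retrieve the extraction report of a tag extraction
#'
#' @param x Result of [extract_ditag_tags()].
#' @return An `extraction_report`: counters `reads_seen`, `reads_accepted`,
#'   `reads_rejected_by_reason` (reads yielding no tag, by first failing
#'   reason) and `tags_rejected_by_reason` (failed tag ends within accepted
#'   reads). `reads_seen == reads_accepted + sum(reads_rejected_by_reason)`
#'   always holds.
#' @export
extraction_report <- function(x) attr(x, "report")

#' @export
print.extraction_report <- function(x, ...) {
  cat("Ditag extraction report\n")
  cat("  reads seen:     ", x$reads_seen, "\n")
  cat("  reads accepted: ", x$reads_accepted, "\n")
  rej <- x$reads_rejected_by_reason
  for (r in names(rej)) if (rej[[r]] > 0) cat("  rejected reads, ", r, ": ", rej[[r]], "\n", sep = "")
  trej <- x$tags_rejected_by_reason
  for (r in names(trej)) if (trej[[r]] > 0) cat("  dropped tag ends, ", r, ": ", trej[[r]], "\n", sep = "")
  invisible(x)
}

#' Assemble a UniTag count matrix from extracted tags
#'
#' Groups identical 26 bp tags into UniTags, assigns stable sequential ids in
#' first-seen order, and tabulates occurrences per library. The result is a
#' wide tibble (one row per UniTag, one integer column per library) carrying
#' the library metadata -- including `total_tags`, the library size N used by
#' the significance statistic -- as an attribute.
#'
#' @param tags A data frame with columns `library` (library id) and `tag`
#'   (26 bp anchored sequences), e.g. stacked outputs of
#'   [extract_ditag_tags()] labelled by library.
#' @param libraries A data frame declaring the libraries up front: columns
#'   `id`, `organ` (e.g. `"root"`/`"nodule"`) and `condition` (e.g.
#'   `"control"`/`"NaCl"`). Tags attributed to an undeclared library are a
#'   hard error.
#' @param id_prefix Prefix for UniTag ids; ids are `<prefix><n>` with `n`
#'   assigned in first-seen order.
#' @return A `tag_counts` tibble: `unitag_id`, `sequence`, then one count
#'   column per library id. Attribute `"libraries"` holds the metadata tibble
#'   with recomputed `total_tags` (= column sums). Retrieve it with
#'   [tag_libraries()].
#' @export
#' @examples
#' libs <- tibble::tibble(
#'   id = c("L1", "L2"), organ = "root",
#'   condition = c("control", "NaCl")
#' )
#' tg <- paste0("CATG", strrep("A", 21), c("C", "C", "G"))
#' count_tags(tibble::tibble(library = c("L1", "L1", "L2"), tag = tg), libs)
count_tags <- function(tags, libraries, id_prefix = "STCa-") {
  tags <- as_tibble(tags)
  stopifnot(all(c("library", "tag") %in% names(tags)))
  libraries <- as_tibble(libraries)
  stopifnot(all(c("id", "organ", "condition") %in% names(libraries)))
  if (anyDuplicated(libraries$id)) abort("duplicated library ids")
  unknown <- setdiff(unique(tags$library), libraries$id)
  if (length(unknown) > 0) {
    abort(paste0("tags attributed to undeclared library: ", paste(unknown, collapse = ", ")))
  }
  assert_valid_tags(tags$tag)

  seqs <- unique(tags$tag) # first-seen order
  tab <- table(factor(tags$tag, levels = seqs), factor(tags$library, levels = libraries$id))
  counts <- as_tibble(as.data.frame.matrix(tab))
  counts[] <- lapply(counts, as.integer)
  out <- dplyr::bind_cols(
    tibble(unitag_id = paste0(id_prefix, seq_along(seqs)), sequence = seqs),
    counts
  )
  new_tag_counts(out, libraries)
}

new_tag_counts <- function(tbl, libraries) {
  libraries$total_tags <- vapply(
    libraries$id, function(l) as.integer(sum(tbl[[l]])), integer(1),
    USE.NAMES = FALSE
  )
  structure(
    as_tibble(tbl),
    libraries = as_tibble(libraries),
    class = unique(c("tag_counts", class(as_tibble(tbl))))
  )
}

#' Library metadata of a tag count matrix or profile
#'
#' @param x A `tag_counts` or `tag_profile` object.
#' @return Tibble with columns `id`, `organ`, `condition`, `total_tags`.
#' @export
tag_libraries <- function(x) attr(x, "libraries")

lib_cols <- function(x) tag_libraries(x)$id

#' Remove organ-wise singleton UniTags
#'
#' A UniTag is a singleton in an organ when its summed count across that
#' organ's libraries (control + stress) equals 1. Such counts are zeroed in
#' that organ and UniTags left with no counts anywhere are dropped; library
#' `total_tags` are recomputed over the retained tags, reproducing the
#' organ-wise "(excluding singletons)" accounting of SAGE studies.
#'
#' @param x A `tag_counts` object.
#' @return Filtered `tag_counts`; attribute `"removed"` is a tibble
#'   (`unitag_id`, `organ`) of the zeroed singleton observations.
#' @export
filter_singletons <- function(x) {
  stopifnot(inherits(x, "tag_counts"))
  libs <- tag_libraries(x)
  out <- as_tibble(x)
  removed <- tibble(unitag_id = character(), organ = character())
  for (org in unique(libs$organ)) {
    cols <- libs$id[libs$organ == org]
    organ_sum <- rowSums(out[, cols, drop = FALSE])
    hit <- organ_sum == 1
    if (any(hit)) {
      removed <- bind_rows(removed, tibble(unitag_id = out$unitag_id[hit], organ = org))
      out[hit, cols] <- 0L
    }
  }
  keep <- rowSums(out[, libs$id, drop = FALSE]) > 0
  out <- out[keep, , drop = FALSE]
  res <- new_tag_counts(out, libs[, c("id", "organ", "condition")])
  attr(res, "removed") <- removed
  res
}

#' Remove low-complexity UniTags
#'
#' Operates on the 22 variable positions 5--26 (the CATG anchor is ignored).
#' A tag is low-complexity when (a) one base occupies at least
#' `max_base_frac` of the variable positions, or (b) a 1--2 nt motif tandem
#' repeat spans at least `min_repeat_span` consecutive variable positions.
#'
#' @param x A `tag_counts` object.
#' @param max_base_frac Mononucleotide dominance threshold (default 0.8).
#' @param min_repeat_span Minimum tandem-repeat span, in bases (default 18).
#' @return Filtered `tag_counts`; attribute `"removed"` is a tibble
#'   (`unitag_id`, `sequence`, `rule`) of discarded tags.
#' @export
filter_low_complexity <- function(x, max_base_frac = 0.8, min_repeat_span = 18) {
  stopifnot(inherits(x, "tag_counts"))
  rule <- vapply(x$sequence, low_complexity_rule,
    character(1),
    max_base_frac = max_base_frac, min_repeat_span = min_repeat_span,
    USE.NAMES = FALSE
  )
  drop <- rule != ""
  removed <- tibble(
    unitag_id = x$unitag_id[drop], sequence = x$sequence[drop], rule = rule[drop]
  )
  libs <- tag_libraries(x)
  res <- new_tag_counts(as_tibble(x)[!drop, , drop = FALSE], libs[, c("id", "organ", "condition")])
  attr(res, "removed") <- removed
  res
}

# classify one tag; returns "" (keep), "mononucleotide" or "tandem_repeat"
low_complexity_rule <- function(seq, max_base_frac = 0.8, min_repeat_span = 18) {
  v <- strsplit(substr(seq, 5L, 26L), "")[[1]]
  n <- length(v)
  if (max(table(v)) >= max_base_frac * n) return("mononucleotide")
  # longest period-1 run
  run1 <- max(rle(v)$lengths)
  if (run1 >= min_repeat_span) return("tandem_repeat")
  # longest period-2 run: consecutive positions with v[i] == v[i + 2]
  if (n >= 3) {
    eq <- v[seq_len(n - 2)] == v[seq_len(n - 2) + 2L]
    r <- rle(eq)
    span2 <- if (any(r$values)) max(r$lengths[r$values]) + 2L else 0L
    if (span2 >= min_repeat_span) return("tandem_repeat")
  }
  ""
}
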