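as_est_set <- function(ests) {
  if (inherits(ests, "DNAStringSet")) return(ests)
  if (is.character(ests) && length(ests) == 1 && file.exists(ests) && is.null(names(ests))) {
    return(Biostrings::readDNAStringSet(ests))
  }
  Biostrings::DNAStringSet(ests)
}

#' Match UniTags to an EST collection
#'
#' Anchored scan for every occurrence of each 26 bp tag on either strand of
#' the ESTs, allowing up to `max_mismatches` mismatches but never inside the
#' CATG anchor (the anchor is the trusted band of the dictionary search).
#' ESTs shorter than 26 bases are skipped with a notice.
#'
#' @param tags A `tag_counts` object, or a named character vector of tag
#'   sequences (names = unitag ids).
#' @param ests EST collection: a `DNAStringSet`, a named character vector, or
#'   the path of a FASTA file.
#' @param max_mismatches Maximum mismatches outside the anchor (default 1).
#' @return Tibble of matches: `unitag_id`, `est_id`, `matched_bases`
#'   (26 - mismatches), `offset` (0-based start of the occurrence on the EST
#'   forward strand), `strand` (`"+"`/`"-"`).
#' @export
match_tags_to_ests <- function(tags, ests, max_mismatches = 1) {
  if (inherits(tags, "tag_counts")) {
    tag_seq <- setNames(tags$sequence, tags$unitag_id)
  } else {
    tag_seq <- tags
    if (is.null(names(tag_seq))) names(tag_seq) <- paste0("tag_", seq_along(tag_seq))
  }
  assert_valid_tags(tag_seq)
  subj <- as_est_set(ests)
  if (is.null(names(subj))) names(subj) <- paste0("EST_", seq_along(subj))
  short <- Biostrings::width(subj) < 26
  if (any(short)) {
    inform(sprintf("skipping %d EST(s) shorter than 26 bases", sum(short)))
    subj <- subj[!short]
  }
  if (length(subj) == 0 || length(tag_seq) == 0) {
    return(tibble(
      unitag_id = character(), est_id = character(),
      matched_bases = integer(), offset = integer(), strand = character()
    ))
  }
  est_chr <- as.character(subj)
  est_w <- Biostrings::width(subj)

  scan_strand <- function(patterns, tb) {
    pd <- Biostrings::PDict(
      Biostrings::DNAStringSet(patterns),
      tb.start = tb[1], tb.end = tb[2]
    )
    res <- vector("list", length(subj))
    for (i in seq_along(subj)) {
      m <- Biostrings::startIndex(
        Biostrings::matchPDict(pd, subj[[i]], max.mismatch = max_mismatches)
      )
      nh <- lengths(m)
      if (sum(nh) == 0) next
      res[[i]] <- data.frame(
        index = rep(seq_along(m), nh),
        group = i,
        start = unlist(m, use.names = FALSE)
      )
    }
    out <- bind_rows(res)
    if (nrow(out) == 0) {
      out <- data.frame(index = integer(), group = integer(), start = integer())
    }
    out$end <- out$start + 25L
    out
  }

  # sense tags: anchor at 1-4; minus strand searched as revcomp(tag), whose
  # anchor sits at pattern positions 23-26 (CATG is its own reverse complement)
  fwd <- scan_strand(unname(tag_seq), c(1L, 4L))
  rev <- scan_strand(unname(revcomp(tag_seq)), c(23L, 26L))

  row_tbl <- function(df, strand) {
    if (nrow(df) == 0) {
      return(tibble(
        unitag_id = character(), est_id = character(),
        matched_bases = integer(), offset = integer(), strand = character()
      ))
    }
    ti <- df$index
    si <- df$group
    seg <- substr(est_chr[si], df$start, df$end)
    pat <- if (strand == "+") tag_seq[ti] else revcomp(tag_seq)[ti]
    mm <- vapply(
      seq_len(nrow(df)),
      function(k) length(mismatch_positions(seg[k], unname(pat[k]))),
      integer(1)
    )
    tibble(
      unitag_id = names(tag_seq)[ti],
      est_id = names(subj)[si],
      matched_bases = 26L - mm,
      offset = df$start - 1L,
      strand = strand
    )
  }

  out <- bind_rows(row_tbl(fwd, "+"), row_tbl(rev, "-"))
  arrange(out, .data$unitag_id, .data$est_id, .data$offset)
}

#' Apply the high-homology retention gate to tag-EST matches
#'
#' The built-in surrogate for an `E < 1e-5` cutoff on a 26-mer hit is at
#' least `min_matched_bases` (default 25 of 26) matched bases. Imported hits
#' carrying a printed `evalue` column can be gated on it directly by setting
#' `max_evalue`.
#'
#' @param matches Tibble from [match_tags_to_ests()] (or imported hits with
#'   at least `unitag_id`, `est_id` and either `matched_bases` or `evalue`).
#' @param min_matched_bases Matched-base gate, default 25.
#' @param max_evalue When non-NULL and an `evalue` column is present, retain
#'   `evalue < max_evalue` instead of the matched-base gate.
#' @return The retained subset of `matches`.
#' @export
retain_matches <- function(matches, min_matched_bases = 25, max_evalue = NULL) {
  matches <- as_tibble(matches)
  if (!is.null(max_evalue)) {
    if (!"evalue" %in% names(matches)) abort("no evalue column to gate on")
    return(filter(matches, .data$evalue < max_evalue))
  }
  filter(matches, .data$matched_bases >= min_matched_bases)
}

#' Transfer tiered protein annotation onto matched ESTs
#'
#' Walks the tier tables in priority order (e.g. Cicer/Fabaceae, then
#' Arabidopsis, then rice/maize) and gives each matched EST the first tier
#' entry that passes: not anonymous, not flagged weak-similarity, and
#' e-value at or below the tier's gate (default 1e-50). Priority beats
#' e-value magnitude: a passing higher-tier hit wins over a stronger
#' lower-tier one. ESTs passing no tier are reported with tier
#' `"anonymous"` (candidate novel transcripts). Tags inherit their EST's
#' record, one row per retained match.
#'
#' @param matches Retained matches (columns `unitag_id`, `est_id`).
#' @param tiers Named list of tier tables in priority order; each a data
#'   frame with columns `est_id`, `protein_accession`, `protein_name`,
#'   `evalue`, and optional logicals `is_anonymous`, `is_weak_similarity`.
#' @param evalue_gate E-value gate per tier (recycled), default 1e-50.
#' @return Tibble `unitag_id`, `est_id`, `tier`, `protein_accession`,
#'   `protein_name`, `evalue`; unannotated ESTs get tier `"anonymous"` and
#'   NA accession.
#' @export
transfer_annotation <- function(matches, tiers, evalue_gate = 1e-50) {
  matches <- as_tibble(matches)
  if (is.null(names(tiers)) || any(!nzchar(names(tiers)))) abort("tier tables must be named")
  gates <- rep_len(evalue_gate, length(tiers))
  ests <- unique(matches$est_id)
  best <- tibble(
    est_id = ests, tier = "anonymous",
    protein_accession = NA_character_, protein_name = NA_character_,
    evalue = NA_real_
  )
  unresolved <- rep(TRUE, length(ests))
  for (k in seq_along(tiers)) {
    tt <- as_tibble(tiers[[k]])
    if (!"is_anonymous" %in% names(tt)) tt$is_anonymous <- FALSE
    if (!"is_weak_similarity" %in% names(tt)) tt$is_weak_similarity <- FALSE
    pass <- tt |>
      filter(
        !.data$is_anonymous, !.data$is_weak_similarity,
        .data$evalue <= gates[k], .data$est_id %in% ests[unresolved]
      ) |>
      arrange(.data$evalue) |>
      distinct(.data$est_id, .keep_all = TRUE)
    hit <- match(pass$est_id, ests)
    best$tier[hit] <- names(tiers)[k]
    best$protein_accession[hit] <- pass$protein_accession
    best$protein_name[hit] <- pass$protein_name
    best$evalue[hit] <- pass$evalue
    unresolved[hit] <- FALSE
  }
  left_join(matches[, c("unitag_id", "est_id")], best, by = "est_id")
}

#' Attach GO terms to annotation records
#'
#' @param records Annotation records from [transfer_annotation()].
#' @param go_map Two-column data frame mapping `protein_accession` to GO ids
#'   (first two columns are used whatever their names; duplicate rows are
#'   deduplicated).
#' @return `records` with a `go_terms` list-column of sorted unique GO ids
#'   (empty for unmapped accessions).
#' @export
link_go <- function(records, go_map) {
  records <- as_tibble(records)
  go_map <- as_tibble(go_map)
  acc <- go_map[[1]]
  term <- go_map[[2]]
  by_acc <- split(term, acc)
  records$go_terms <- lapply(records$protein_accession, function(a) {
    if (is.na(a)) character(0) else sort(unique(by_acc[[a]])) %||% character(0)
  })
  records
}

#' UniTag-per-EST multiplicity report
#'
#' Tabulates, for every matched EST, how many distinct UniTags target it and
#' summarises the classes 1, 2, 3, 4, 5 and >5 UniTags per EST -- the
#' EST-bridged view in which large tag families typically pair one abundant
#' UniTag with several rare isoform tags.
#'
#' @param matches Retained matches (columns `unitag_id`, `est_id`).
#' @param profile Optional `tag_profile`; when given, each EST's summed
#'   member copies per 100,000 are added to the per-EST table.
#' @return Tibble `class`, `n_ests`, `pct` (percent of matched ESTs);
#'   attribute `"per_est"` holds `est_id`, `n_unitags` (+ `total_copies`).
#' @export
multiplicity_report <- function(matches, profile = NULL) {
  matches <- distinct(as_tibble(matches), .data$unitag_id, .data$est_id)
  per_est <- matches |>
    count(.data$est_id, name = "n_unitags")
  if (!is.null(profile)) {
    copies <- rowSums(as_tibble(profile)[, lib_cols(profile), drop = FALSE])
    tag_copies <- tibble(unitag_id = profile$unitag_id, copies = copies)
    per_est <- matches |>
      left_join(tag_copies, by = "unitag_id") |>
      group_by(.data$est_id) |>
      summarise(
        n_unitags = n(),
        total_copies = sum(.data$copies, na.rm = TRUE), .groups = "drop"
      )
  }
  lvls <- c("1", "2", "3", "4", "5", ">5")
  cls <- ifelse(per_est$n_unitags > 5, ">5", as.character(per_est$n_unitags))
  tab <- table(factor(cls, levels = lvls))
  structure(
    tibble(
      class = lvls, n_ests = as.integer(tab),
      pct = 100 * as.integer(tab) / max(1L, nrow(per_est))
    ),
    per_est = per_est
  )
}
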