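#' Positional identity between two fixed-length tags
#'
#' Number of positions (out of 26) at which two anchor-aligned tags carry the
#' same base -- the ungapped similarity used to group SNP-associated
#' alternative tags (SAATs). Vectorised over pairs.
#'
#' @param a,b Character vectors of valid 26 bp tags (recycled to a common
#'   length).
#' @return Integer vector of identities in \[0, 26\]; symmetric in `a`, `b`.
#' @export
#' @examples
#' tag_identity(
#'   "CATGTAATGTAATATTGTTGTGAAAA",
#'   "CATGTAATGTAATATTGTTGTGATTT"
#' ) # 23
tag_identity <- function(a, b) {
  assert_valid_tags(a); assert_valid_tags(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(
    seq_len(n),
    function(i) sum(charToRaw(a[i]) == charToRaw(b[i])),
    integer(1)
  )
}

# All-vs-all identity edges at identity >= threshold, via one-hot crossprod
# (dot product of one-hot rows = number of matching positions). Chunked over
# rows to bound memory on large tag sets.
identity_edges <- function(seqs, threshold, chunk = 2000L) {
  n <- length(seqs)
  if (n < 2) {
    return(tibble(i = integer(), j = integer(), identity = integer()))
  }
  mat <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE), nrow = n, byrow = TRUE)
  onehot <- do.call(cbind, lapply(c("A", "C", "G", "T"), function(b) (mat == b) * 1))
  res <- vector("list", ceiling(n / chunk))
  for (ci in seq_along(res)) {
    rows <- (((ci - 1L) * chunk + 1L)):min(ci * chunk, n)
    sim <- onehot[rows, , drop = FALSE] %*% t(onehot)
    hit <- which(sim >= threshold, arr.ind = TRUE)
    i <- rows[hit[, 1]]
    j <- hit[, 2]
    keep <- i < j # upper triangle only; drops self-pairs
    res[[ci]] <- tibble(
      i = i[keep], j = j[keep],
      identity = as.integer(sim[hit][keep])
    )
  }
  bind_rows(res)
}

#' Cluster UniTags into SNP-associated alternative tag (SAAT) families
#'
#' Tags are linked when their ungapped positional identity is at least
#' `min_identity` (default 23 of 26, i.e. homology over more than 22 bases)
#' and families are the single-linkage connected components of that graph;
#' tags without any similar hit form singleton families. The family
#' representative is the member with the highest summed copies per 100,000
#' across libraries (ties broken by lexicographically smallest sequence), and
#' SNP positions are called per member against the representative.
#'
#' @param x A `tag_counts` object, or a data frame with columns `unitag_id`
#'   and `sequence` (representatives then fall back to the lexicographic
#'   tie-break unless `profile` is given).
#' @param min_identity Identity threshold in \[1, 26\]; default 23.
#' @param pairs Optional externally computed links (e.g. from
#'   [import_similarity_pairs()]): a data frame with columns `query` and
#'   `subject` holding unitag ids. When given, the built-in identity metric
#'   is not used for linking (hit counts still come from `pairs`).
#' @param profile Optional `tag_profile` supplying member abundances for the
#'   representative choice; computed from `x` when `x` is a `tag_counts`.
#' @return A `saat_families` tibble: `family_id`, `unitag_id`, `sequence`,
#'   `is_representative`, `n_similar_hits` (other tags linked to this one),
#'   `snp_positions` (`;`-joined 1-based positions where the member differs
#'   from the representative, all in 5--26). Attribute `"hit_histogram"`
#'   tabulates tags with 0, 1, 2 and >=3 similar hits.
#' @export
build_saat_families <- function(x, min_identity = 23, pairs = NULL, profile = NULL) {
  if (min_identity < 1 || min_identity > 26) abort("min_identity must be in [1, 26]")
  if (inherits(x, "tag_counts") && is.null(profile)) profile <- normalize_counts(x)
  tags <- as_tibble(x)[, c("unitag_id", "sequence")]
  if (anyDuplicated(tags$unitag_id)) abort("unitag ids must be unique")
  assert_valid_tags(tags$sequence)
  n <- nrow(tags)

  if (is.null(pairs)) {
    edges <- identity_edges(tags$sequence, min_identity)
  } else {
    pairs <- as_tibble(pairs)
    stopifnot(all(c("query", "subject") %in% names(pairs)))
    i <- match(pairs$query, tags$unitag_id)
    j <- match(pairs$subject, tags$unitag_id)
    ok <- !is.na(i) & !is.na(j) & i != j
    edges <- tibble(i = pmin(i[ok], j[ok]), j = pmax(i[ok], j[ok])) |> distinct()
  }

  g <- igraph::graph_from_data_frame(
    edges[, c("i", "j")],
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  comp <- igraph::components(g)$membership[as.character(seq_len(n))]
  # family ids in order of first-seen member
  fam <- match(comp, unique(comp))
  deg <- igraph::degree(g)[as.character(seq_len(n))]

  copies <- if (!is.null(profile)) {
    rowSums(as_tibble(profile)[, lib_cols(profile), drop = FALSE])[
      match(tags$unitag_id, profile$unitag_id)
    ]
  } else {
    rep(0, n)
  }
  copies[is.na(copies)] <- 0

  out <- tags
  out$family_id <- paste0("SAAT-", fam)
  out$n_similar_hits <- as.integer(deg)
  out$.copies <- copies
  out <- out |>
    group_by(.data$family_id) |>
    mutate(
      is_representative = rank_representative(.data$.copies, .data$sequence),
      snp_positions = vapply(
        .data$sequence,
        function(s) {
          rep_seq <- .data$sequence[.data$is_representative][1]
          paste(mismatch_positions(s, rep_seq), collapse = ";")
        },
        character(1),
        USE.NAMES = FALSE
      )
    ) |>
    ungroup() |>
    select(-".copies")
  hist_lv <- c("0", "1", "2", ">=3")
  hits <- ifelse(out$n_similar_hits >= 3, ">=3", as.character(out$n_similar_hits))
  tab <- table(factor(hits, levels = hist_lv))
  structure(
    out[, c(
      "family_id", "unitag_id", "sequence", "is_representative",
      "n_similar_hits", "snp_positions"
    )],
    hit_histogram = tibble(
      similar_hits = hist_lv, n = as.integer(tab),
      pct = 100 * as.integer(tab) / nrow(tags)
    ),
    min_identity = min_identity,
    class = unique(c("saat_families", class(out)))
  )
}

# logical vector marking the representative: max copies, then smallest sequence
rank_representative <- function(copies, sequence) {
  best <- which(copies == max(copies))
  rep_idx <- best[order(sequence[best])][1]
  seq_along(copies) == rep_idx
}

#' Similar-hit histogram of a SAAT clustering
#'
#' @param families A `saat_families` object.
#' @return Tibble `similar_hits` (0, 1, 2, >=3), `n`, `pct`.
#' @export
hit_histogram <- function(families) attr(families, "hit_histogram")

#' Within-family expression summary
#'
#' Sums each member's copies per 100,000 across libraries, reports the
#' representative's share of the family total, and (when a DGE table is
#' given) flags families whose members are regulated in discordant
#' directions -- the hallmark of SAAT isoforms with diverging profiles.
#'
#' @param families A `saat_families` object.
#' @param profile A `tag_profile` covering the members.
#' @param dge Optional `dge_table` supplying per-member directions.
#' @return Per-family tibble: `family_id`, `n_members`, `family_copies`,
#'   `representative`, `representative_copies`, `representative_share`, and
#'   with `dge`: `n_up`, `n_down`, `discordant`. Attribute `"members"` holds
#'   the per-member table (`family_id`, `unitag_id`, `copies`, `direction`).
#' @export
family_profile <- function(families, profile, dge = NULL) {
  stopifnot(inherits(families, "saat_families"), inherits(profile, "tag_profile"))
  idx <- match(families$unitag_id, profile$unitag_id)
  if (anyNA(idx)) abort("family members missing from profile")
  copies <- rowSums(as_tibble(profile)[idx, lib_cols(profile), drop = FALSE])
  members <- tibble(
    family_id = families$family_id,
    unitag_id = families$unitag_id,
    is_representative = families$is_representative,
    copies = copies,
    direction = if (!is.null(dge)) {
      dge$direction[match(families$unitag_id, dge$unitag_id)]
    } else {
      NA_character_
    }
  )
  out <- members |>
    group_by(.data$family_id) |>
    summarise(
      n_members = n(),
      family_copies = sum(.data$copies),
      representative = .data$unitag_id[.data$is_representative][1],
      representative_copies = .data$copies[.data$is_representative][1],
      representative_share = ifelse(
        .data$family_copies > 0,
        .data$representative_copies / .data$family_copies, 1
      ),
      n_up = sum(.data$direction == "up", na.rm = TRUE),
      n_down = sum(.data$direction == "down", na.rm = TRUE),
      discordant = .data$n_up > 0 & .data$n_down > 0,
      .groups = "drop"
    )
  if (is.null(dge)) out <- select(out, -"n_up", -"n_down", -"discordant")
  attr(out, "members") <- members
  out
}

#' Import pairwise tag links from BLAST tabular hits
#'
#' Accepts a hit when the equivalent number of matched bases,
#' `length * pident / 100` rounded to the nearest base, reaches
#' `min_matched_bases`. Self-hits are discarded and links are symmetrized
#' (one row per unordered pair). Use the result as the `pairs` argument of
#' [build_saat_families()] to substitute an external aligner for the built-in
#' positional identity (e.g. to admit gapped isoforms).
#'
#' @param path BLAST outfmt 6 tabular file.
#' @param min_matched_bases Acceptance threshold, default 23.
#' @param max_errors Malformed-row budget before the import aborts.
#' @return Tibble `query`, `subject`, `matched_bases`.
#' @export
import_similarity_pairs <- function(path, min_matched_bases = 23, max_errors = 10) {
  hits <- read_blast_tab(path, max_errors = max_errors)
  matched <- round(hits$length * hits$pident / 100)
  keep <- hits$query != hits$subject & matched >= min_matched_bases
  out <- tibble(
    query = pmin(hits$query[keep], hits$subject[keep]),
    subject = pmax(hits$query[keep], hits$subject[keep]),
    matched_bases = as.integer(matched[keep])
  )
  distinct(out)
}
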