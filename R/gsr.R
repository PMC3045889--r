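#' Aggregate per-tag scores into per-accession gene scores
#'
#' Gene score resampling works on one score per gene (protein accession).
#' Each annotated UniTag contributes its |R(ln)|; accessions hit by several
#' tags are summarised by the best (max) or mean absolute score. Unannotated
#' tags are excluded from the scored universe.
#'
#' @param dge A `dge_table`.
#' @param tag2acc Data frame mapping `unitag_id` to `protein_accession`
#'   (at most one accession per tag; e.g. annotation records from
#'   [transfer_annotation()], deduplicated).
#' @param mode `"max_abs"` (default) or `"mean_abs"`.
#' @return Tibble `protein_accession`, `score`, `n_tags`, `provenance` (the
#'   unitag supplying the max score).
#' @export
aggregate_scores <- function(dge, tag2acc, mode = c("max_abs", "mean_abs")) {
  mode <- match.arg(mode)
  tag2acc <- as_tibble(tag2acc)[, c("unitag_id", "protein_accession")] |>
    filter(!is.na(.data$protein_accession)) |>
    distinct()
  if (anyDuplicated(tag2acc$unitag_id)) {
    abort("a scored tag maps to more than one accession")
  }
  scored <- as_tibble(dge)[, c("unitag_id", "r_ln")] |>
    dplyr::inner_join(tag2acc, by = "unitag_id") |>
    mutate(abs_score = abs(.data$r_ln))
  scored |>
    group_by(.data$protein_accession) |>
    summarise(
      score = if (mode == "max_abs") max(.data$abs_score) else mean(.data$abs_score),
      n_tags = n(),
      provenance = .data$unitag_id[which.max(.data$abs_score)],
      .groups = "drop"
    )
}

#' Gene score resampling (GSR) over-representation analysis
#'
#' For each category, the observed aggregate is the mean score of its
#' accessions present in the scored universe (categories with analyzed size
#' outside `[min_size, max_size]` are skipped with a notice). The null is
#' built by drawing `B` random same-size accession sets from the universe
#' without replacement; the p-value is
#' `(1 + #{null aggregates >= observed}) / (B + 1)`, so it is never exactly 0
#' and the procedure needs no per-gene hit threshold. Results are
#' deterministic given `seed`.
#'
#' @param categories Data frame with columns `category` and
#'   `protein_accession` (optional logical `is_custom`), or a named list of
#'   accession vectors.
#' @param scores Gene scores from [aggregate_scores()] (columns
#'   `protein_accession`, `score`).
#' @param B Number of resamples, default 10,000.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param min_size,max_size Analyzed category size bounds, defaults 5 and 100.
#' @return A `gsr_result`: tibble `category`, `k`, `observed_aggregate`,
#'   `p_value`, `is_custom`, with attributes `B`, `seed`, `universe_size` and
#'   `skipped` (categories outside the size bounds). [tidy()], [glance()] and
#'   [autoplot()] methods are available.
#' @export
gsr <- function(categories, scores, B = 10000, seed, min_size = 5, max_size = 100) {
  if (missing(seed)) abort("gsr() requires an explicit seed")
  cats <- as_category_tbl(categories)
  scores <- as_tibble(scores)
  universe <- scores$score
  names(universe) <- scores$protein_accession
  if (length(universe) == 0) abort("empty scored universe")
  if (any(universe < 0)) abort("gene scores must be non-negative")

  by_cat <- split(cats$protein_accession, cats$category)
  custom <- tapply(cats$is_custom, cats$category, any)
  sizes <- vapply(by_cat, function(a) sum(unique(a) %in% names(universe)), integer(1))
  analyzable <- sizes >= min_size & sizes <= max_size
  if (any(!analyzable)) {
    inform(sprintf(
      "skipping %d category(ies) outside size bounds [%d, %d]",
      sum(!analyzable), min_size, max_size
    ))
  }

  res <- withr::with_seed(seed, {
    lapply(names(by_cat)[analyzable], function(cat) {
      acc <- intersect(unique(by_cat[[cat]]), names(universe))
      k <- length(acc)
      obs <- mean(universe[acc])
      null <- vapply(
        seq_len(B),
        function(b) mean(universe[sample.int(length(universe), k)]),
        numeric(1)
      )
      tibble(
        category = cat, k = k, observed_aggregate = obs,
        p_value = (1 + sum(null >= obs)) / (B + 1)
      )
    })
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(
      category = character(), k = integer(),
      observed_aggregate = numeric(), p_value = numeric()
    )
  }
  out$is_custom <- as.logical(custom[out$category])
  out <- arrange(out, .data$p_value, .data$category)
  structure(out,
    B = B, seed = seed, universe_size = length(universe),
    skipped = names(by_cat)[!analyzable],
    class = unique(c("gsr_result", class(out)))
  )
}

as_category_tbl <- function(categories) {
  if (is.data.frame(categories)) {
    cats <- as_tibble(categories)
    stopifnot(all(c("category", "protein_accession") %in% names(cats)))
    if (!"is_custom" %in% names(cats)) cats$is_custom <- FALSE
    return(cats[, c("category", "protein_accession", "is_custom")])
  }
  if (is.list(categories)) {
    return(tibble(
      category = rep(names(categories), lengths(categories)),
      protein_accession = unlist(categories, use.names = FALSE),
      is_custom = FALSE
    ))
  }
  abort("categories must be a data frame or a named list")
}

#' Add a custom category to a category table
#'
#' Custom pathway categories (e.g. an SOS-pathway or ROS-scavenger set) are
#' analyzed by [gsr()] exactly like GO terms; they are only flagged
#' `is_custom`. A label colliding with an existing category id is a hard
#' error.
#'
#' @param categories Category table (or named list; coerced).
#' @param label Unique label of the new category.
#' @param accessions Non-empty character vector of member accessions.
#' @return The extended category tibble.
#' @export
add_custom_category <- function(categories, label, accessions) {
  cats <- as_category_tbl(categories)
  if (length(accessions) == 0) abort("custom category needs at least one accession")
  if (label %in% cats$category) {
    abort(sprintf("category label '%s' already exists", label))
  }
  bind_rows(cats, tibble(
    category = label, protein_accession = unique(accessions), is_custom = TRUE
  ))
}

#' GO slim summary of the most regulated UniTags
#'
#' Takes the `top_n` tags of a DGE table ranked by fold change (descending
#' for `"up"`, ascending for `"down"`; ties at the cut broken by smaller
#' p-value, then unitag id), maps them through their annotation records to GO
#' terms and onto slim terms, and counts distinct accessions per slim term.
#' Tags without an annotated accession are tallied under `"unannotated"`.
#'
#' @param dge A `dge_table`.
#' @param records Annotation records with `go_terms` (from [link_go()]).
#' @param slim_map Data frame mapping `go_id` to `slim_id` (first two
#'   columns used).
#' @param top_n Number of top tags, default 40.
#' @param direction `"up"` (default) or `"down"`.
#' @return Tibble `slim_id`, `n_accessions`, sorted by count.
#' @export
goslim_top_summary <- function(dge, records, slim_map, top_n = 40,
                               direction = c("up", "down")) {
  direction <- match.arg(direction)
  ord <- order(
    if (direction == "up") -dge$fold_change else dge$fold_change,
    dge$p_value, dge$unitag_id
  )
  top <- dge$unitag_id[head(ord, top_n)]
  records <- as_tibble(records)
  slim_map <- as_tibble(slim_map)
  slim_of <- split(slim_map[[2]], slim_map[[1]])
  rec_idx <- match(top, records$unitag_id)
  rows <- lapply(seq_along(top), function(i) {
    ri <- rec_idx[i]
    acc <- if (is.na(ri)) NA_character_ else records$protein_accession[ri]
    if (is.na(acc)) {
      return(tibble(slim_id = "unannotated", protein_accession = paste0(".tag:", top[i])))
    }
    gos <- records$go_terms[[ri]]
    slims <- unique(unlist(slim_of[gos], use.names = FALSE))
    if (length(slims) == 0) slims <- "unannotated"
    tibble(slim_id = slims, protein_accession = acc)
  })
  bind_rows(rows) |>
    distinct() |>
    count(.data$slim_id, name = "n_accessions") |>
    arrange(desc(.data$n_accessions), .data$slim_id)
}
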