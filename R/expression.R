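#' Normalize tag counts to copies per 100,000 tags
#'
#' Digital expression profiles are made comparable across libraries of
#' different sequencing depth by scaling each count to
#' `count * 100000 / total_tags`. Per library the normalized column sums to
#' 100,000 exactly (up to floating-point rounding). Values are kept at full
#' precision; round only for display.
#'
#' @param x A `tag_counts` object.
#' @return A `tag_profile` tibble of the same shape with numeric
#'   copies-per-100k columns; library metadata travels in attribute
#'   `"libraries"`.
#' @export
normalize_counts <- function(x) {
  stopifnot(inherits(x, "tag_counts"))
  libs <- tag_libraries(x)
  if (any(libs$total_tags <= 0)) abort("library with zero total tags cannot be normalized")
  out <- as_tibble(x)
  for (i in seq_len(nrow(libs))) {
    l <- libs$id[i]
    out[[l]] <- out[[l]] * 1e5 / libs$total_tags[i]
  }
  structure(out,
    libraries = libs,
    class = unique(c("tag_profile", class(as_tibble(out))))
  )
}

#' Pool a count matrix over organs
#'
#' Sums each tag's counts across all libraries of the same organ, yielding
#' one pseudo-library per organ (condition `"pooled"`). Useful for
#' organ-level summaries such as abundance classes, which are conventionally
#' reported on the organ's full tag sample rather than per condition.
#'
#' @param x A `tag_counts` object.
#' @return A `tag_counts` with one column per organ.
#' @export
pool_by_organ <- function(x) {
  stopifnot(inherits(x, "tag_counts"))
  libs <- tag_libraries(x)
  organs <- unique(libs$organ)
  out <- as_tibble(x)[, c("unitag_id", "sequence")]
  for (org in organs) {
    cols <- libs$id[libs$organ == org]
    out[[org]] <- as.integer(rowSums(as_tibble(x)[, cols, drop = FALSE]))
  }
  new_tag_counts(out, tibble(id = organs, organ = organs, condition = "pooled"))
}

#' Abundance-class report of a normalized profile
#'
#' Tags with nonzero counts are binned by copies per 100,000 into the four
#' classes `[0,10)`, `[10,100]`, `(100,500]` and `(500,Inf)`, printed as
#' `<10`, `10-100`, `(100,500]`, `>500`. Typical deep SAGE libraries put
#' ~85--90% of tags in the `<10` class and under 1% above 500 copies.
#'
#' @param profile A `tag_profile` from [normalize_counts()].
#' @return Tibble `library`, `class`, `n`, `pct`, where `pct` is the
#'   percentage of that library's expressed (nonzero) tags.
#' @export
abundance_classes <- function(profile) {
  stopifnot(inherits(profile, "tag_profile"))
  lvls <- c("<10", "10-100", "(100,500]", ">500")
  res <- lapply(lib_cols(profile), function(l) {
    v <- profile[[l]]
    v <- v[v > 0]
    cls <- dplyr::case_when(
      v < 10 ~ "<10",
      v <= 100 ~ "10-100",
      v <= 500 ~ "(100,500]",
      TRUE ~ ">500"
    )
    tab <- table(factor(cls, levels = lvls))
    tibble(
      library = l, class = factor(lvls, levels = lvls),
      n = as.integer(tab), pct = 100 * as.integer(tab) / length(v)
    )
  })
  bind_rows(res)
}

#' Fold change and natural-log expression ratio R(ln)
#'
#' The fold change of a tag between two libraries is the ratio of normalized
#' abundances, `((x_trt + pc) / N_trt) / ((x_ctrl + pc) / N_ctrl)`, and
#' `R_ln = ln(fold)`. The pseudocount `pc` is applied to *both* counts, and
#' only when one of them is zero, so that observed nonzero ratios are
#' untouched while zeros yield finite folds. `R_ln > 1` corresponds to the
#' classical "at least 2.7-fold" up-regulation threshold (e = 2.718...).
#'
#' @param count_ctrl,count_trt Non-negative integer counts (vectorised).
#' @param n_ctrl,n_trt Library sizes (total tags), positive.
#' @param pseudocount Non-negative pseudocount, default 1.
#' @return Tibble with columns `fold_change` and `r_ln`.
#' @export
#' @examples
#' fold_and_ratio(0, 8, 1e5, 1e5) # fold 9, R_ln = ln 9
fold_and_ratio <- function(count_ctrl, count_trt, n_ctrl, n_trt, pseudocount = 1) {
  stopifnot(pseudocount >= 0, all(n_ctrl > 0), all(n_trt > 0))
  if (any(count_ctrl < 0) || any(count_trt < 0)) abort("negative counts")
  zero <- pmin(count_ctrl, count_trt) == 0
  if (any(zero & count_ctrl == 0 & count_trt == 0 & pseudocount == 0)) {
    abort("fold change undefined: both counts zero and pseudocount 0")
  }
  pc <- ifelse(zero, pseudocount, 0)
  fold <- ((count_trt + pc) / n_trt) / ((count_ctrl + pc) / n_ctrl)
  tibble(fold_change = fold, r_ln = log(fold))
}

#' Audic-Claverie significance of a digital expression difference
#'
#' Exact test for a difference between counts `x` and `y` of the same tag in
#' two libraries of sizes `N1` and `N2`. Conditional on `x`, under the null
#' of equal relative abundance, `y` follows
#' `p(y|x) = r^y (x+y)! / (x! y! (1+r)^(x+y+1))` with `r = N2/N1` -- a
#' negative binomial with size `x + 1` and success probability `N1/(N1+N2)`.
#' The two-sided p-value doubles the smaller of the lower tail
#' `P(Y <= y | x)` and its complement, capped at 1. This doubling convention
#' is the one that is exactly symmetric under swapping the libraries
#' (`p(x, y, N1, N2) = p(y, x, N2, N1)`), because
#' `P(Y <= y | x; N1, N2) + P(Y <= x | y; N2, N1) = 1` holds identically.
#' Tails are evaluated through the log-gamma based cumulative distribution,
#' stable for counts well beyond 10^5.
#'
#' @param x,y Observed counts (non-negative integers, vectorised).
#' @param n1,n2 Library sizes for `x` and `y` respectively.
#' @return Numeric vector of two-sided p-values in \[0, 1\].
#' @export
#' @examples
#' audic_claverie_pvalue(5, 0, 1e5, 1e5) # 2 * (1/2)^6 = 0.03125
audic_claverie_pvalue <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0)) abort("counts must be non-negative")
  if (any(n1 <= 0) || any(n2 <= 0)) abort("library sizes must be positive")
  prob <- n1 / (n1 + n2) # P(success) of the conditional negative binomial
  lower <- pnbinom(y, size = x + 1, prob = prob)
  upper <- pnbinom(y, size = x + 1, prob = prob, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Differential expression table for a library pair
#'
#' For every UniTag observed in at least one of the two libraries, computes
#' normalized abundances, fold change and R(ln) (see [fold_and_ratio()]), the
#' Audic-Claverie two-sided p-value, and the regulation direction (`up` when
#' fold > 1, `down` when fold < 1, `flat` otherwise). Raw p-values are
#' reported; set `adjust = TRUE` for an additional Benjamini-Hochberg column.
#'
#' @param x A `tag_counts` object.
#' @param control,treatment Library ids (must differ and be present in `x`).
#' @param pseudocount Pseudocount for zero counts, default 1.
#' @param adjust Add a `p_adj` (BH) column? Default `FALSE`.
#' @return A `dge_table` tibble: `unitag_id`, `sequence`, `count_control`,
#'   `count_treatment`, `cp100k_control`, `cp100k_treatment`, `fold_change`,
#'   `r_ln`, `p_value`, `direction` (+ `p_adj`). Attributes record the pair
#'   and library sizes. [glance()] summarises tags beyond the |R_ln|
#'   thresholds 1.0, ln 3, ln 8 and ln 20; see also [threshold_summary()].
#' @export
differential_table <- function(x, control, treatment, pseudocount = 1, adjust = FALSE) {
  stopifnot(inherits(x, "tag_counts"))
  libs <- tag_libraries(x)
  if (!all(c(control, treatment) %in% libs$id)) abort("unknown library id")
  if (control == treatment) abort("control and treatment must be different libraries")
  n_ctrl <- libs$total_tags[libs$id == control]
  n_trt <- libs$total_tags[libs$id == treatment]

  cc <- x[[control]]
  ct <- x[[treatment]]
  keep <- cc + ct > 0
  cc <- cc[keep]; ct <- ct[keep]

  fr <- fold_and_ratio(cc, ct, n_ctrl, n_trt, pseudocount)
  out <- tibble(
    unitag_id = x$unitag_id[keep],
    sequence = x$sequence[keep],
    count_control = cc,
    count_treatment = ct,
    cp100k_control = cc * 1e5 / n_ctrl,
    cp100k_treatment = ct * 1e5 / n_trt,
    fold_change = fr$fold_change,
    r_ln = fr$r_ln,
    p_value = audic_claverie_pvalue(cc, ct, n_ctrl, n_trt),
    direction = dplyr::case_when(
      fr$fold_change > 1 ~ "up",
      fr$fold_change < 1 ~ "down",
      TRUE ~ "flat"
    )
  )
  if (adjust) out$p_adj <- p.adjust(out$p_value, method = "BH")
  structure(out,
    control = control, treatment = treatment,
    n_control = n_ctrl, n_treatment = n_trt, pseudocount = pseudocount,
    class = unique(c("dge_table", class(out)))
  )
}

#' Counts of regulated tags at standard |R(ln)| thresholds
#'
#' @param dge A `dge_table`.
#' @param r_ln_thresholds Thresholds on |R_ln|; defaults to 1.0 (2.7-fold)
#'   and the 3-, 8- and 20-fold marks.
#' @return Tibble `r_ln_threshold`, `fold_equivalent`, `n_up`, `n_down`,
#'   `pct_up`, `pct_down` (percent of tags in the table).
#' @export
threshold_summary <- function(dge, r_ln_thresholds = c(1, log(3), log(8), log(20))) {
  stopifnot(inherits(dge, "dge_table"))
  n <- nrow(dge)
  bind_rows(lapply(r_ln_thresholds, function(th) {
    up <- sum(dge$r_ln >= th)
    dn <- sum(dge$r_ln <= -th)
    tibble(
      r_ln_threshold = th, fold_equivalent = exp(th),
      n_up = up, n_down = dn,
      pct_up = 100 * up / n, pct_down = 100 * dn / n
    )
  }))
}

#' Regulated UniTag sets from a DGE table
#'
#' Fold thresholds are applied on the linear scale with a `>=` comparison
#' (`fold >= fold` for up, `fold <= 1/fold` for down).
#'
#' @param dge A `dge_table`.
#' @param fold Linear fold-change threshold (e.g. 3, 8 or 20).
#' @param direction `"up"` or `"down"`.
#' @return Character vector of UniTag ids.
#' @export
regulated_tags <- function(dge, fold = 3, direction = c("up", "down")) {
  stopifnot(inherits(dge, "dge_table"), fold > 0)
  direction <- match.arg(direction)
  if (direction == "up") {
    dge$unitag_id[dge$fold_change >= fold]
  } else {
    dge$unitag_id[dge$fold_change <= 1 / fold]
  }
}

#' Venn decomposition of named UniTag sets
#'
#' Counts the exclusive regions of the Venn diagram spanned by 2--3 (or more)
#' named sets drawn from a shared UniTag id space, as used to report shared
#' salt-stress responses between organs at a given fold threshold.
#'
#' @param sets Non-empty named list of character vectors.
#' @return Tibble `region` (set names joined by `&` for intersections),
#'   `n` (exclusive element count); all regions are listed, including empty
#'   ones, and the `n` column sums to the union size.
#' @export
#' @examples
#' venn_overlap(list(A = c("t1", "t2"), B = c("t2", "t3")))
venn_overlap <- function(sets) {
  if (!is.list(sets) || length(sets) == 0) abort("need a non-empty named list of sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) abort("sets must be named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, nrow = length(universe))
  k <- length(sets)
  regions <- unlist(lapply(seq_len(k), function(m) {
    combn(names(sets), m, paste, collapse = "&", simplify = FALSE)
  }))
  pattern <- apply(member, 1, function(row) paste(names(sets)[row], collapse = "&"))
  tab <- table(factor(pattern, levels = regions))
  tibble(region = regions, n = as.integer(tab))
}
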