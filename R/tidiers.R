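#' @method tidy dge_table
#' @export
tidy.dge_table <- function(x, ...) {
  as_tibble(unclass_keep(x))
}

#' Summary of a differential-expression table
#'
#' One row with the library pair, tag count, and the number of tags beyond
#' the 2.7-fold (|R_ln| >= 1) mark in each direction, plus the smallest
#' p-value.
#'
#' @param x A `dge_table`.
#' @param ... Unused.
#' @method glance dge_table
#' @export
glance.dge_table <- function(x, ...) {
  tibble(
    control = attr(x, "control"),
    treatment = attr(x, "treatment"),
    n_tags = nrow(x),
    n_up_2.7fold = sum(x$r_ln >= 1),
    n_down_2.7fold = sum(x$r_ln <= -1),
    min_p = if (nrow(x)) min(x$p_value) else NA_real_,
    pseudocount = attr(x, "pseudocount")
  )
}

#' @method tidy gsr_result
#' @export
tidy.gsr_result <- function(x, ...) {
  as_tibble(unclass_keep(x))
}

#' Summary of a GSR analysis
#'
#' @param x A `gsr_result`.
#' @param ... Unused.
#' @method glance gsr_result
#' @export
glance.gsr_result <- function(x, ...) {
  tibble(
    n_categories = nrow(x),
    n_p_below_0.05 = sum(x$p_value < 0.05),
    n_skipped = length(attr(x, "skipped")),
    universe_size = attr(x, "universe_size"),
    B = attr(x, "B"),
    seed = attr(x, "seed")
  )
}

#' Summary of a SAAT clustering
#'
#' @param x A `saat_families` object.
#' @param ... Unused.
#' @method glance saat_families
#' @export
glance.saat_families <- function(x, ...) {
  fam_sizes <- table(x$family_id)
  tibble(
    n_tags = nrow(x),
    n_families = length(fam_sizes),
    n_singletons = sum(fam_sizes == 1),
    largest_family = as.integer(max(fam_sizes)),
    min_identity = attr(x, "min_identity")
  )
}

# strip the package class but keep tibble behaviour
unclass_keep <- function(x) {
  class(x) <- setdiff(class(x), c("dge_table", "gsr_result", "saat_families", "tag_counts", "tag_profile", "tag_extraction"))
  x
}

#' @export
print.gsr_result <- function(x, ...) {
  cat(sprintf(
    "Gene score resampling: %d categories, universe %d, B = %d (seed %s)\n",
    nrow(x), attr(x, "universe_size"), attr(x, "B"), format(attr(x, "seed"))
  ))
  NextMethod()
}
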