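# shared fixtures and independent oracles

tag_of <- function(suffix) {
  stopifnot(nchar(suffix) <= 22)
  paste0("CATG", suffix, strrep("A", 22 - nchar(suffix)))
}

# stack extracted tags from simulated reads and count them
extract_counts <- function(lib) {
  tags <- dplyr::bind_rows(lapply(names(lib$reads), function(l) {
    tibble::tibble(library = l, tag = extract_ditag_tags(lib$reads[[l]])$tag)
  }))
  count_tags(tags, lib$libraries[, c("id", "organ", "condition")])
}

# brute-force Audic-Claverie: direct summation of the conditional pmf
# p(k|x) = r^k (x+k)! / (x! k! (1+r)^(x+k+1)) via its exact term recurrence
ac_oracle <- function(x, y, n1, n2) {
  r <- n2 / n1
  kmax <- max(y, ceiling(x * r + 10 * sqrt((x + 1) * max(r, 1)) + 50))
  p <- numeric(kmax + 1)
  p[1] <- (1 / (1 + r))^(x + 1)
  for (k in 0:(kmax - 1)) {
    p[k + 2] <- p[k + 1] * r * (x + k + 1) / ((k + 1) * (1 + r))
  }
  lower <- sum(p[seq_len(y + 1)])
  upper <- if (y + 2 > length(p)) 0 else sum(p[seq.int(y + 2, length(p))])
  upper <- upper + max(0, 1 - sum(p)) # truncated remainder also lies above y
  min(1, 2 * min(lower, upper))
}

# exhaustive GSR p on a tiny universe: fraction of same-size subsets whose
# mean score reaches the observed category mean
gsr_exact_p <- function(scores, members) {
  obs <- mean(scores[members])
  subs <- utils::combn(names(scores), length(members))
  mean(apply(subs, 2, function(s) mean(scores[s]) >= obs - 1e-12))
}

# pairwise-cooccurrence F1 between two partitions given as id -> label maps
pair_keys <- function(ids, labels) {
  sp <- split(ids, labels)
  sp <- sp[lengths(sp) > 1]
  unlist(lapply(sp, function(m) {
    cm <- utils::combn(sort(m), 2)
    paste(cm[1, ], cm[2, ], sep = "|")
  }), use.names = FALSE)
}

pair_f1 <- function(ids, true_labels, pred_labels) {
  tr <- pair_keys(ids, true_labels)
  pr <- pair_keys(ids, pred_labels)
  if (length(tr) + length(pr) == 0) return(1)
  2 * length(intersect(tr, pr)) / (length(tr) + length(pr))
}

# deterministic distinct valid tag for index i (22-digit base-4 suffix)
idx_tag <- function(i) {
  digits <- integer(22)
  n <- i
  for (k in 22:1) {
    digits[k] <- n %% 4
    n <- n %/% 4
  }
  paste0("CATG", paste(c("A", "C", "G", "T")[digits + 1], collapse = ""))
}

# hand-built normalized profile (for boundary tests)
toy_profile <- function(values, lib = "L1") {
  n <- length(values)
  tbl <- tibble::tibble(
    unitag_id = paste0("STCa-", seq_len(n)),
    sequence = vapply(seq_len(n), idx_tag, character(1))
  )
  tbl[[lib]] <- values
  structure(
    tbl,
    libraries = tibble::tibble(
      id = lib, organ = "root", condition = "control", total_tags = sum(values)
    ),
    class = c("tag_profile", class(tibble::tibble()))
  )
}
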