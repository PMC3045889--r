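tagX <- "CATGCTTGTTATAGTTAGCCTTTCTC"

flip_at <- function(seq, pos) {
  v <- strsplit(seq, "")[[1]]
  v[pos] <- chartr("ACGT", "TGCA", v[pos])
  paste(v, collapse = "")
}

test_that("planted tags are found on both strands at the right offset", {
  ests <- c(
    plus = paste0(strrep("G", 11), tagX, strrep("T", 8)),
    minus = paste0(strrep("T", 5), revcomp(tagX), strrep("C", 7)),
    none = paste0(strrep("A", 12), strrep("C", 30)) # no anchor at all
  )
  m <- match_tags_to_ests(c(tag1 = tagX), ests)
  expect_identical(nrow(m), 2L)
  plus <- m[m$est_id == "plus", ]
  expect_identical(plus$offset, 11L)
  expect_identical(plus$strand, "+")
  expect_identical(plus$matched_bases, 26L)
  minus <- m[m$est_id == "minus", ]
  expect_identical(minus$strand, "-")
  expect_identical(minus$offset, 5L)
  expect_identical(minus$matched_bases, 26L)
})

test_that("one mismatch is tolerated outside the anchor, never inside", {
  one_mm <- paste0("AA", flip_at(tagX, 10), "GG")
  two_mm <- paste0("AA", flip_at(flip_at(tagX, 10), 20), "GG")
  anchor_mm <- paste0("AA", flip_at(tagX, 2), "GG")
  m <- match_tags_to_ests(
    c(t = tagX),
    c(one = one_mm, two = two_mm, anchor = anchor_mm)
  )
  expect_identical(m$est_id, "one")
  expect_identical(m$matched_bases, 25L)

  # short ESTs are skipped with a notice
  expect_message(
    m2 <- match_tags_to_ests(c(t = tagX), c(stub = "CATGAA", ok = paste0(tagX, "TT"))),
    "shorter"
  )
  expect_identical(m2$est_id, "ok")
})

test_that("retention gates on matched bases or imported e-values", {
  matches <- tibble::tibble(
    unitag_id = c("t1", "t2", "t3"),
    est_id = c("e1", "e2", "e3"),
    matched_bases = c(26L, 25L, 24L),
    evalue = c(1e-7, 1e-4, 1e-9)
  )
  expect_identical(retain_matches(matches)$unitag_id, c("t1", "t2"))
  expect_identical(
    retain_matches(matches, max_evalue = 1e-5)$unitag_id,
    c("t1", "t3")
  )
  expect_error(
    retain_matches(matches[, 1:3], max_evalue = 1e-5),
    "evalue"
  )
})

test_that("annotation transfer honours tier priority and exclusion flags", {
  matches <- tibble::tibble(
    unitag_id = paste0("t", 1:4),
    est_id = c("e_both", "e_weak", "e_loose", "e_missing")
  )
  tiers <- list(
    "Cicer/Fabaceae" = tibble::tibble(
      est_id = c("e_both", "e_weak", "e_loose"),
      protein_accession = c("FAB1", "FAB2", "FAB3"),
      protein_name = c("fab one", "fab two", "fab three"),
      evalue = c(1e-60, 1e-70, 1e-40), # e_loose fails the 1e-50 gate
      is_anonymous = FALSE,
      is_weak_similarity = c(FALSE, TRUE, FALSE)
    ),
    "Arabidopsis" = tibble::tibble(
      est_id = c("e_both", "e_loose"),
      protein_accession = c("ARA1", "ARA2"),
      protein_name = c("ara one", "ara two"),
      evalue = c(1e-80, 1e-90)
    )
  )
  rec <- transfer_annotation(matches, tiers)
  by_est <- setNames(rec$tier, rec$est_id)
  # priority beats e-value magnitude: 1e-60 Fabaceae wins over 1e-80 Arabidopsis
  expect_identical(by_est[["e_both"]], "Cicer/Fabaceae")
  expect_identical(rec$protein_accession[rec$est_id == "e_both"], "FAB1")
  # weak-similarity entries are never selected
  expect_identical(by_est[["e_weak"]], "anonymous")
  # gate failure falls through to the next tier
  expect_identical(by_est[["e_loose"]], "Arabidopsis")
  expect_identical(by_est[["e_missing"]], "anonymous")
  expect_true(is.na(rec$protein_accession[rec$est_id == "e_missing"]))
})

test_that("GO linking is a deduplicated set per accession", {
  rec <- tibble::tibble(
    unitag_id = c("t1", "t2"), est_id = c("e1", "e2"),
    protein_accession = c("ACC1", NA)
  )
  go_map <- tibble::tibble(
    accession = c("ACC1", "ACC1", "ACC1", "ACC1"),
    go_id = c("GO:2", "GO:1", "GO:3", "GO:2") # one duplicate
  )
  out <- link_go(rec, go_map)
  expect_identical(out$go_terms[[1]], c("GO:1", "GO:2", "GO:3"))
  expect_identical(out$go_terms[[2]], character(0))
})

test_that("multiplicity classes count UniTags per EST", {
  matches <- tibble::tibble(
    unitag_id = c("a", "b", "c", "d", "a"),
    est_id = c("e1", "e1", "e1", "e2", "e1") # duplicate row collapses
  )
  rep <- multiplicity_report(matches)
  got <- setNames(rep$n_ests, rep$class)
  expect_identical(got[["3"]], 1L)
  expect_identical(got[["1"]], 1L)
  expect_equal(sum(rep$pct), 100)
  per_est <- attr(rep, "per_est")
  expect_identical(per_est$n_unitags[per_est$est_id == "e1"], 3L)
})

test_that("a planted isoform family lands on one EST with its true multiplicity", {
  set.seed(8)
  parent <- paste0("CATG", paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE), collapse = ""))
  kids <- vapply(c(6, 12, 19, 25), function(p) flip_at(parent, p), character(1))
  fam_tags <- setNames(c(parent, kids), paste0("iso", 1:5))
  est <- c(target = paste0(strrep("C", 40), parent, strrep("T", 20)))
  m <- retain_matches(match_tags_to_ests(fam_tags, est))
  expect_identical(sort(unique(m$unitag_id)), paste0("iso", 1:5))
  rep <- multiplicity_report(m)
  expect_identical(rep$n_ests[rep$class == "5"], 1L)
})

test_that("simulated tags match their own ESTs exactly and inherit truth annotation", {
  cfg <- sim_config(
    n_transcripts = 60, depths = c(root = 500),
    saat_fractions = c(singleton = 0.8, one = 0.2, two = 0, three_plus = 0)
  )
  sim <- simulate_transcriptome(cfg, seed = 17)
  pick <- sim$tags[1:25, ]
  m <- match_tags_to_ests(setNames(pick$sequence, pick$tag_id), sim$ests)
  own <- dplyr::inner_join(
    m, pick[, c("tag_id", "est_id")],
    by = c(unitag_id = "tag_id", est_id = "est_id")
  )
  expect_identical(nrow(own), 25L) # every tag hits its own EST
  expect_true(all(own$matched_bases == 26L))
  expect_true(all(own$strand == "+"))
  # offsets agree with an independent text search
  exp_off <- vapply(seq_len(25), function(i) {
    as.integer(regexpr(pick$sequence[i], sim$ests[[pick$est_id[i]]], fixed = TRUE)) - 1L
  }, integer(1))
  expect_identical(own$offset[match(pick$tag_id, own$unitag_id)], exp_off)

  rec <- transfer_annotation(retain_matches(own), sim$tiers)
  annotated <- rec[rec$tier != "anonymous", ]
  expect_true(all(
    annotated$protein_accession ==
      pick$protein_accession[match(annotated$unitag_id, pick$tag_id)]
  ))
})
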