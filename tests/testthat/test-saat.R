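# four AGP-annotated UniTag sequences printed in the study's Table 5
agp <- c(
  `STCa-17544` = "CATGTAATGTAATATCGTTGTGATTT",
  `STCa-17547` = "CATGTAATGTAATATTGTTGAATGAA",
  `STCa-17548` = "CATGTAATGTAATATTGTTGTGAAAA",
  `STCa-17550` = "CATGTAATGTAATATTGTTGTGATTT"
)

test_that("positional identity counts matching bases of anchor-aligned tags", {
  expect_identical(tag_identity(agp[["STCa-17548"]], agp[["STCa-17548"]]), 26L)
  expect_identical(tag_identity(agp[["STCa-17548"]], agp[["STCa-17550"]]), 23L)
  expect_identical(tag_identity(agp[["STCa-17547"]], agp[["STCa-17548"]]), 22L)
  expect_identical(tag_identity(agp[["STCa-17544"]], agp[["STCa-17550"]]), 25L)
  expect_identical(
    tag_identity(agp[["STCa-17547"]], agp[["STCa-17550"]]),
    tag_identity(agp[["STCa-17550"]], agp[["STCa-17547"]])
  )
})

test_that("families form single-linkage components above 22 identical bases", {
  tags <- tibble::tibble(unitag_id = names(agp), sequence = unname(agp))
  fam <- build_saat_families(tags)
  membership <- setNames(fam$family_id, fam$unitag_id)
  # 17544-17550 (25) and 17548-17550 (23) link; 17547 stays apart (max 22)
  expect_identical(membership[["STCa-17544"]], membership[["STCa-17550"]])
  expect_identical(membership[["STCa-17548"]], membership[["STCa-17550"]])
  expect_false(membership[["STCa-17547"]] == membership[["STCa-17550"]])
  # partition: every tag in exactly one family
  expect_identical(sort(fam$unitag_id), sort(names(agp)))

  # per-tag similar-hit counts back the 0/1/2/>=3 histogram
  hits <- setNames(fam$n_similar_hits, fam$unitag_id)
  expect_identical(hits[["STCa-17550"]], 2L)
  expect_identical(hits[["STCa-17544"]], 1L)
  expect_identical(hits[["STCa-17548"]], 1L)
  expect_identical(hits[["STCa-17547"]], 0L)
  h <- hit_histogram(fam)
  expect_equal(h$n, c(1L, 2L, 1L, 0L))
  expect_equal(sum(h$pct), 100)
})

test_that("single linkage chains distant members through intermediates", {
  a <- paste0("CATG", strrep("A", 22))
  b <- paste0("CATG", "CCC", strrep("A", 19)) # 3 mismatches to a -> 23
  c_ <- paste0("CATG", "CCCGGG", strrep("A", 16)) # 23 to b, 20 to a
  expect_identical(tag_identity(a, c_), 20L)
  fam <- build_saat_families(tibble::tibble(
    unitag_id = c("A", "B", "C"), sequence = c(a, b, c_)
  ))
  expect_identical(length(unique(fam$family_id)), 1L)
  expect_error(build_saat_families(tibble::tibble(
    unitag_id = "A", sequence = a
  ), min_identity = 0), "min_identity")
})

test_that("representative is the most abundant member and SNPs are called against it", {
  libs <- tibble::tibble(id = "L1", organ = "root", condition = "control")
  # copies 100 / 10 / 5 for 17550 / 17544 / 17548
  stream <- tibble::tibble(
    library = "L1",
    tag = c(
      rep(agp[["STCa-17550"]], 100), rep(agp[["STCa-17544"]], 10),
      rep(agp[["STCa-17548"]], 5)
    )
  )
  m <- count_tags(stream, libs)
  fam <- build_saat_families(m)
  rep_seq <- fam$sequence[fam$is_representative]
  expect_identical(rep_seq, agp[["STCa-17550"]])
  # 17544 differs from the representative at position 16 only
  expect_identical(fam$snp_positions[fam$sequence == agp[["STCa-17544"]]], "16")
  expect_true(all(fam$snp_positions == "" | !grepl("^[1-4]$", fam$snp_positions)))

  prof <- normalize_counts(m)
  fp <- family_profile(fam, prof)
  expect_equal(fp$n_members, 3)
  expect_equal(fp$representative_share, 100 / 115, tolerance = 1e-12)

  # family of one: share is 1
  m1 <- count_tags(tibble::tibble(library = "L1", tag = idx_tag(9)), libs)
  solo <- build_saat_families(m1)
  fp1 <- family_profile(solo, normalize_counts(m1))
  expect_equal(fp1$representative_share, 1)
})

test_that("family partition is invariant to input order", {
  cfg <- sim_config(
    n_transcripts = 200, depths = c(root = 1000),
    saat_fractions = c(singleton = 0.5, one = 0.3, two = 0.1, three_plus = 0.1)
  )
  sim <- simulate_transcriptome(cfg, seed = 31)
  tags <- tibble::tibble(unitag_id = sim$tags$tag_id, sequence = sim$tags$sequence)
  f1 <- build_saat_families(tags)
  set.seed(1)
  shuffled <- tags[sample.int(nrow(tags)), ]
  f2 <- build_saat_families(shuffled)
  part <- function(f) {
    unname(lapply(
      split(f$unitag_id, f$family_id),
      function(m) paste(sort(m), collapse = "|")
    ))
  }
  expect_setequal(unlist(part(f1)), unlist(part(f2)))
})

test_that("imported tabular hits gate on equivalent matched bases", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "t1\tt2\t96.15\t26\t1\t0\t1\t26\t1\t26\t1e-8\t42", # 25 bases -> link
    "t1\tt1\t100\t26\t0\t0\t1\t26\t1\t26\t1e-12\t50", # self-hit
    "t2\tt3\t84.6\t26\t4\t0\t1\t26\t1\t26\t1e-4\t30" # 22 bases -> dropped
  ), path)
  links <- import_similarity_pairs(path)
  expect_identical(nrow(links), 1L)
  expect_identical(links$matched_bases, 25L)
  expect_setequal(c(links$query, links$subject), c("t1", "t2"))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_identical(nrow(import_similarity_pairs(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("t1\tt2\t96.15\t26", "oops"), bad)
  expect_warning(import_similarity_pairs(bad), "malformed")
  expect_error(
    suppressWarnings(import_similarity_pairs(bad, max_errors = 0)),
    "malformed"
  )

  # external links replace the built-in metric
  tags <- tibble::tibble(
    unitag_id = c("t1", "t2", "t4"),
    sequence = c(idx_tag(1), idx_tag(2), idx_tag(3))
  )
  fam <- build_saat_families(tags, pairs = links)
  membership <- setNames(fam$family_id, fam$unitag_id)
  expect_identical(membership[["t1"]], membership[["t2"]])
  expect_false(membership[["t4"]] == membership[["t1"]])
})
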