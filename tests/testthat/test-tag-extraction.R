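test_that("ditag geometry recovers both anchored tags", {
  t1 <- tag_of(strrep("A", 22))
  t2 <- tag_of(strrep("C", 22))
  read <- paste0(t1, revcomp(t2)) # 52 bp, starts and ends with CATG
  expect_identical(nchar(read), 52L)
  res <- extract_ditag_tags(c(r1 = read))
  expect_identical(res$tag, c(t1, t2))
  expect_identical(res$end, c(1L, 2L))
  rep <- extraction_report(res)
  expect_identical(rep$reads_seen, 1L)
  expect_identical(rep$reads_accepted, 1L)
})

test_that("rejections are tallied by reason and the read ledger balances", {
  t1 <- tag_of(strrep("G", 22))
  reads <- c(
    no_start = paste0("TTTT", strrep("A", 48)),
    half = paste0(t1, strrep("A", 22), "CCCC"), # tag1 ok, no end anchor
    short = strrep("A", 49),
    alien = paste0("CATG", strrep("A", 20), "XX", strrep("T", 22), "CATG"),
    ambig = paste0("CATG", "N", strrep("A", 21), revcomp(t1))
  )
  res <- extract_ditag_tags(reads)
  rep <- extraction_report(res)

  expect_identical(rep$reads_seen, 5L)
  # accepted: "half" (tag1) and "ambig" (tag2 valid, tag1 has N)
  expect_identical(rep$reads_accepted, 2L)
  expect_identical(rep$reads_rejected_by_reason[["no_start_anchor"]], 1L)
  expect_identical(rep$reads_rejected_by_reason[["bad_length"]], 1L)
  expect_identical(rep$reads_rejected_by_reason[["ambiguous_base"]], 1L) # the X read
  expect_identical(
    rep$reads_seen,
    rep$reads_accepted + sum(rep$reads_rejected_by_reason)
  )
  # per-tag reasons inside accepted reads
  expect_identical(rep$tags_rejected_by_reason[["no_end_anchor"]], 1L)
  expect_identical(rep$tags_rejected_by_reason[["ambiguous_base"]], 1L)
  expect_identical(res$tag[res$read_id == "half"], t1)
  expect_identical(res$tag[res$read_id == "ambig"], t1)
})

test_that("extraction is symmetric under reverse complement of the read", {
  set.seed(101)
  for (i in 1:40) {
    suf <- function() paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE), collapse = "")
    t1 <- tag_of(suf())
    t2 <- tag_of(suf())
    read <- paste0(t1, revcomp(t2))
    a <- sort(extract_ditag_tags(read)$tag)
    b <- sort(extract_ditag_tags(revcomp(read))$tag)
    expect_identical(a, b)
  }
})

test_that("count_tags tallies per library with stable first-seen ids", {
  libs <- tibble::tibble(
    id = c("L1", "L2"), organ = "root", condition = c("control", "NaCl")
  )
  t <- tag_of("TTTTTTTTTTTTTTTTTTTTTT")
  u <- tag_of("GGGGGGGGGGGGGGGGGGGGGG")
  m <- count_tags(
    tibble::tibble(library = c("L1", "L1", "L1", "L2"), tag = c(t, t, u, t)), libs
  )
  expect_identical(m$unitag_id, c("STCa-1", "STCa-2"))
  expect_identical(m$L1, c(2L, 1L))
  expect_identical(m$L2, c(1L, 0L))
  expect_identical(tag_libraries(m)$total_tags, c(3L, 1L))
  # shared tag t is one row across libraries
  expect_identical(nrow(m), 2L)
  expect_error(
    count_tags(tibble::tibble(library = "L9", tag = t), libs),
    "undeclared library"
  )
})

test_that("counting agrees with an independent tally on simulated reads", {
  cfg <- sim_config(n_transcripts = 300, depths = c(root = 4000), n_de_tags = 0)
  sim <- simulate_transcriptome(cfg, seed = 5)
  lib <- simulate_libraries(sim, seed = 6)
  stacked <- dplyr::bind_rows(lapply(names(lib$reads), function(l) {
    tibble::tibble(library = l, tag = extract_ditag_tags(lib$reads[[l]])$tag)
  }))
  m <- count_tags(stacked, lib$libraries[, c("id", "organ", "condition")])
  for (l in tag_libraries(m)$id) {
    oracle <- table(stacked$tag[stacked$library == l])
    expect_identical(sum(m[[l]]), sum(oracle))
    expect_identical(
      m[[l]][match(names(oracle), m$sequence)],
      as.integer(oracle)
    )
    # conservation: column sum equals recorded library size
    expect_identical(sum(m[[l]]), tag_libraries(m)$total_tags[tag_libraries(m)$id == l])
  }
})

test_that("singleton filter is organ-wise with its boundary at 2", {
  libs <- tibble::tibble(
    id = c("R1", "R2", "N1", "N2"),
    organ = c("root", "root", "nodule", "nodule"),
    condition = c("control", "NaCl", "control", "NaCl")
  )
  a <- idx_tag(1) # root singleton (1,0); absent in nodule -> dropped
  b <- idx_tag(2) # root (1,1) -> kept
  c_ <- idx_tag(3) # root singleton but abundant in nodule -> zeroed in root only
  stream <- tibble::tibble(
    library = c("R1", "R1", "R2", "R1", "N1", "N1", "N2"),
    tag = c(a, b, b, c_, c_, c_, c_)
  )
  m <- count_tags(stream, libs)
  f <- filter_singletons(m)
  expect_false(a %in% f$sequence)
  expect_true(all(c(b, c_) %in% f$sequence))
  expect_identical(f$R1[f$sequence == c_], 0L)
  expect_identical(f$N1[f$sequence == c_], 2L)
  expect_identical(
    tag_libraries(f)$total_tags,
    c(sum(f$R1), sum(f$R2), sum(f$N1), sum(f$N2))
  )
  expect_setequal(attr(f, "removed")$organ, c("root"))

  empty <- count_tags(tibble::tibble(library = character(), tag = character()), libs)
  expect_identical(nrow(filter_singletons(empty)), 0L)
})

test_that("low-complexity rules drop runs and dinucleotide repeats only", {
  libs <- tibble::tibble(id = "L1", organ = "root", condition = "control")
  mono <- paste0("CATG", strrep("A", 22))
  dinu <- paste0("CATG", strrep("AT", 11))
  keep <- "CATGCTTGTTATAGTTAGCCTTTCTC" # a real annotated UniTag sequence
  m <- count_tags(
    tibble::tibble(library = "L1", tag = c(mono, dinu, keep, keep)), libs
  )
  f <- filter_low_complexity(m)
  expect_identical(f$sequence, keep)
  removed <- attr(f, "removed")
  expect_setequal(removed$sequence, c(mono, dinu))
  expect_identical(removed$rule[removed$sequence == mono], "mononucleotide")
  expect_identical(removed$rule[removed$sequence == dinu], "tandem_repeat")
  expect_identical(tag_libraries(f)$total_tags, sum(f$L1))
})

test_that("simulate-extract-count round trip recovers the generating multiset", {
  cfg <- sim_config(n_transcripts = 500, depths = c(root = 9999), n_de_tags = 10)
  sim <- simulate_transcriptome(cfg, seed = 21)
  lib <- simulate_libraries(sim, seed = 22)
  # odd depth: one extra observation completes the last ditag
  expect_identical(length(lib$reads$root_control), 2500L)
  m <- extract_counts(lib)
  for (l in lib$libraries$id) {
    truth <- lib$counts[[l]]
    names(truth) <- lib$counts$sequence
    truth <- truth[truth > 0]
    got <- m[[l]][match(names(truth), m$sequence)]
    expect_identical(got, unname(truth))
    expect_identical(sum(m[[l]]), sum(lib$counts[[l]]))
  }
})
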