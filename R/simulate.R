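#' Configuration of the synthetic deepSuperSAGE study
#'
#' Bundles the knobs of the generator, with defaults emulating a two-organ
#' (root, nodule) x two-condition (control, NaCl) salt-stress design:
#' heavy-tailed lognormal transcript abundances putting roughly 90% of tags
#' below 10 copies per 100,000 and under 1% above 500; SAAT similar-hit
#' classes of 79/15/4/2% (tags with 0, 1, 2, 3+ similar tags); 200
#' differentially expressed tags with |R(ln)| uniform on \[1.0, 4.3\] and
#' random sign; library depths of 86,919 (root) and 57,281 (nodule) tags
#' split across conditions; and one spiked enriched category whose member
#' genes receive an extra score shift.
#'
#' @param n_transcripts Total number of distinct tags (transcripts).
#' @param abundance_sdlog Lognormal sd (log scale) of transcript weights.
#'   `NULL` (default) solves the sd from `abundance_targets`: with weights
#'   `w ~ lognormal(0, sd)`, the expected fraction of true abundances
#'   `1e5 w / sum(w)` below 10 copies per 100,000 equals the target
#'   (`P(ln w < ln(n/1e4) + sd^2/2) = target`, taking the heavy-tail root).
#' @param abundance_targets Named targets of the true abundance-class
#'   fractions: `below_10` (fraction of tags under 10 copies per 100,000)
#'   and `above_500_max` (cap on the fraction above 500).
#' @param saat_fractions Named fractions of tags with 0/1/2/3+ similar hits.
#' @param n_de_tags Number of DE tags (includes the spiked members).
#' @param rln_range Range of |R(ln)| effect sizes.
#' @param depths Named total tag depths per organ.
#' @param n_categories Number of GO-like categories.
#' @param category_size_range Accessions per category (uniform draw).
#' @param spike_size Members of the spiked enriched category.
#' @param spike_shift Extra |R(ln)| added to spiked members' tags.
#' @param est_prefix_range,est_tail_range EST 5' prefix / 3' tail lengths.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_transcripts = 20000,
                       abundance_sdlog = NULL,
                       abundance_targets = c(below_10 = 0.90, above_500_max = 0.01),
                       saat_fractions = c(singleton = 0.79, one = 0.15, two = 0.04, three_plus = 0.02),
                       n_de_tags = 200,
                       rln_range = c(1.0, 4.3),
                       depths = c(root = 86919, nodule = 57281),
                       n_categories = 40,
                       category_size_range = c(8, 40),
                       spike_size = 20,
                       spike_shift = 1.0,
                       est_prefix_range = c(80, 200),
                       est_tail_range = c(20, 60)) {
  if (is.null(abundance_sdlog)) {
    abundance_sdlog <- solve_sdlog(n_transcripts, abundance_targets[["below_10"]])
  }
  stopifnot(
    n_transcripts > 0, abundance_sdlog > 0,
    all(saat_fractions >= 0), sum(saat_fractions) <= 1 + 1e-9,
    n_de_tags >= 0, all(depths > 0), spike_size >= 0
  )
  structure(
    list(
      n_transcripts = n_transcripts, abundance_sdlog = abundance_sdlog,
      abundance_targets = abundance_targets,
      saat_fractions = saat_fractions, n_de_tags = n_de_tags,
      rln_range = rln_range, depths = depths,
      n_categories = n_categories, category_size_range = category_size_range,
      spike_size = spike_size, spike_shift = spike_shift,
      est_prefix_range = est_prefix_range, est_tail_range = est_tail_range
    ),
    class = "sim_config"
  )
}

# sd of ln(w) such that P(1e5 w / (n E[w]) < 10) = target for w lognormal;
# the larger (heavy-tail) root reproduces SAGE-like abundance dominance
solve_sdlog <- function(n, target_below_10) {
  z <- stats::qnorm(target_below_10)
  disc <- z^2 - 2 * log(n / 1e4)
  if (disc < 0) {
    abort("no lognormal sd meets the abundance-class target at this n_transcripts")
  }
  z + sqrt(disc)
}

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# TRUE when the tag has no CATG other than the anchor (so that the anchor is
# the 3'-most NlaIII site of any EST built as prefix + tag + G-free tail)
anchor_unique <- function(tag) {
  !grepl("CATG", substr(tag, 2L, 26L), fixed = TRUE)
}

gen_tags <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    cand <- vapply(seq_len(n - length(out)), function(i) {
      paste0("CATG", rand_dna(22))
    }, character(1))
    cand <- cand[vapply(cand, anchor_unique, logical(1))]
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

# child isoform: n_snp substitutions at distinct positions within 5..26
mutate_tag <- function(parent, positions) {
  v <- strsplit(parent, "")[[1]]
  for (p in positions) v[p] <- sample(setdiff(BASES, v[p]), 1)
  paste(v, collapse = "")
}

#' Simulate a ground-truthed transcript pool
#'
#' Generates `n_transcripts` CATG-anchored 26 bp tags, organised into SAAT
#' families per the configured similar-hit fractions (families of size 2
#' carry 1--3 SNPs per isoform; larger families carry one SNP per isoform at
#' distinct positions, so every member is within the >22-base homology
#' threshold of every other). Each tag is embedded in its own synthetic EST
#' at the 3'-most CATG site (isoform ESTs are duplicates of the parent's EST
#' with the tag region substituted); lognormal abundance weights make
#' isoforms minor relative to their parent. DE effect sizes, a spiked
#' enriched category, tier annotation tables, a GO map and a slim map are
#' drawn alongside so every pipeline stage can be scored against truth.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the output is a pure function of
#'   `(config, seed)`.
#' @return A `sage_sim` list: `tags` (tibble `tag_id`, `sequence`, `est_id`,
#'   `protein_accession`, `family_id`, `is_parent`, `snp_positions`,
#'   `weight`), `ests` (named character), `de` (`tag_id`, `r_ln`),
#'   `categories`, `spiked_category`, `tiers`, `go_map`, `slim_map`,
#'   `config`.
#' @export
simulate_transcriptome <- function(config = sim_config(), seed) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed)) abort("simulate_transcriptome() requires a seed")
  withr::with_seed(seed, {
    n <- config$n_transcripts
    f <- config$saat_fractions
    n2 <- floor(f[["one"]] * n / 2)
    n3 <- floor(f[["two"]] * n / 3)
    n4 <- floor(f[["three_plus"]] * n / 4)
    n_children <- n2 + 2 * n3 + 3 * n4
    n_parents <- n - n_children
    if (n_parents < n2 + n3 + n4) abort("config requests more families than transcripts")

    parents <- gen_tags(n_parents)
    fam_sizes <- c(rep(2L, n2), rep(3L, n3), rep(4L, n4))
    fam_parent <- seq_along(fam_sizes) # first parents head the families

    tag_seq <- parents
    parent_of <- rep(NA_integer_, n_parents)
    snp_of <- rep("", n_parents)
    for (fi in seq_along(fam_sizes)) {
      p <- parents[fam_parent[fi]]
      k <- fam_sizes[fi] - 1L
      pos_pool <- sample(5:26) # distinct SNP positions within the family
      made <- 0L
      while (made < k) {
        n_snp <- if (fam_sizes[fi] == 2L) sample(1:3, 1) else 1L
        pos <- pos_pool[seq_len(n_snp)]
        child <- mutate_tag(p, pos)
        if (anchor_unique(child) && !child %in% tag_seq) {
          tag_seq <- c(tag_seq, child)
          parent_of <- c(parent_of, fam_parent[fi])
          snp_of <- c(snp_of, paste(sort(pos), collapse = ";"))
          pos_pool <- setdiff(pos_pool, pos)
          made <- made + 1L
        }
      }
    }

    n_all <- length(tag_seq)
    is_parent <- is.na(parent_of)
    fam_id <- ifelse(is_parent, seq_len(n_all), parent_of)
    # abundance: heavy-tailed weights for parents; isoforms minor (1-10%)
    w <- rlnorm(n_all, meanlog = 0, sdlog = config$abundance_sdlog)
    w[!is_parent] <- w[fam_id[!is_parent]] * runif(sum(!is_parent), 0.01, 0.1)

    acc <- sprintf("ACCS%05d", fam_id) # isoforms share the parent's protein
    est_id <- sprintf("ESTsyn%05d", seq_len(n_all))

    # ESTs: prefix + tag + G-free tail, so the anchor is the 3'-most CATG;
    # isoform ESTs duplicate the parent's flanks
    pre_len <- sample(config$est_prefix_range[1]:config$est_prefix_range[2], n_parents, replace = TRUE)
    tail_len <- sample(config$est_tail_range[1]:config$est_tail_range[2], n_parents, replace = TRUE)
    prefixes <- vapply(pre_len, rand_dna, character(1))
    tails <- vapply(tail_len, function(l) {
      paste(sample(c("A", "C", "T"), l, replace = TRUE), collapse = "")
    }, character(1))
    ests <- paste0(prefixes[fam_id], tag_seq, tails[fam_id])
    names(ests) <- est_id

    tags <- tibble(
      tag_id = sprintf("T%05d", seq_len(n_all)),
      sequence = tag_seq, est_id = est_id, protein_accession = acc,
      family_id = sprintf("FAM%05d", fam_id), is_parent = is_parent,
      snp_positions = snp_of, weight = w
    )

    # categories over the parent accession universe
    acc_universe <- unique(acc[is_parent])
    spiked_acc <- sample(acc_universe, min(config$spike_size, length(acc_universe)))
    cat_ids <- sprintf("GO:%07d", seq_len(config$n_categories))
    categories <- bind_rows(lapply(cat_ids, function(cid) {
      sz <- sample(config$category_size_range[1]:config$category_size_range[2], 1)
      sz <- min(sz, length(acc_universe))
      tibble(category = cid, protein_accession = sample(acc_universe, sz), is_custom = FALSE)
    }))
    spiked_category <- "GO:9999999"
    categories <- bind_rows(
      categories,
      tibble(category = spiked_category, protein_accession = spiked_acc, is_custom = FALSE)
    )

    # DE truth: spiked members' tags always DE, topped up with random parents
    spiked_tags <- tags$tag_id[is_parent & acc %in% spiked_acc]
    extra <- setdiff(tags$tag_id[is_parent], spiked_tags)
    n_extra <- max(0L, config$n_de_tags - length(spiked_tags))
    de_ids <- c(spiked_tags, sample(extra, min(n_extra, length(extra))))
    mag <- runif(length(de_ids), config$rln_range[1], config$rln_range[2])
    mag[seq_along(spiked_tags)] <- mag[seq_along(spiked_tags)] + config$spike_shift
    de <- tibble(
      tag_id = de_ids,
      r_ln = mag * sample(c(-1, 1), length(de_ids), replace = TRUE)
    )

    # tiered annotation tables: every parent EST gets a passing entry in one
    # tier (priority 1/2/3 with prob .5/.3/.2) plus occasional decoys below
    tier_names <- c("Cicer/Fabaceae", "Arabidopsis", "rice/maize")
    home <- sample(1:3, n_parents, replace = TRUE, prob = c(.5, .3, .2))
    anon <- runif(n_parents) < 0.1 # ESTs with no characterized homolog
    tiers <- lapply(1:3, function(k) {
      rows <- which(!anon & home == k)
      fam_rows <- match(fam_id, seq_len(n_parents)) # tag row -> parent index
      members <- which(fam_rows %in% rows)
      tibble(
        est_id = est_id[members],
        protein_accession = acc[members],
        protein_name = paste0("synthetic protein ", acc[members]),
        evalue = 10^runif(length(members), -120, -55),
        is_anonymous = FALSE,
        is_weak_similarity = FALSE
      )
    })
    names(tiers) <- tier_names

    go_map <- categories[, c("protein_accession", "category")]
    names(go_map) <- c("protein_accession", "go_id")
    slim_ids <- sprintf("SLIM:%02d", 1:8)
    slim_map <- tibble(
      go_id = c(cat_ids, spiked_category),
      slim_id = sample(slim_ids, config$n_categories + 1, replace = TRUE)
    )

    structure(
      list(
        tags = tags, ests = ests, de = de, categories = categories,
        spiked_category = spiked_category, tiers = tiers,
        go_map = go_map, slim_map = slim_map, config = config
      ),
      class = "sage_sim"
    )
  })
}

#' Canonical tag of an EST sequence
#'
#' The 26 bp tag anchored at the 3'-most CATG site that still leaves 22 bases
#' downstream; `NA` when no such site exists.
#'
#' @param est Character vector of EST sequences.
#' @return Character vector of tags (or `NA`).
#' @export
canonical_tag <- function(est) {
  vapply(est, function(s) {
    hits <- gregexpr("CATG", s, fixed = TRUE)[[1]]
    hits <- hits[hits > 0 & hits + 25 <= nchar(s)]
    if (length(hits) == 0) return(NA_character_)
    substr(s, max(hits), max(hits) + 25)
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate ditag libraries from a transcript pool
#'
#' Draws each library's tag observations multinomially from the pool's
#' abundance weights -- NaCl libraries scale DE tags' weights by
#' `exp(R_ln)` -- and pairs observations uniformly at random into ditag reads
#' (`tag1 + revcomp(tag2)`, 52 bp). When a depth is odd one extra observation
#' is drawn to complete the last ditag, so the realized count table (the
#' round-trip truth) always matches what is embedded in the reads.
#'
#' @param sim A `sage_sim` from [simulate_transcriptome()].
#' @param seed Integer seed.
#' @return List: `reads` (named list of named read vectors per library),
#'   `counts` (tibble `tag_id`, `sequence`, one realized-count column per
#'   library), `libraries` (tibble `id`, `organ`, `condition`, `depth`).
#' @export
simulate_libraries <- function(sim, seed) {
  stopifnot(inherits(sim, "sage_sim"))
  if (missing(seed)) abort("simulate_libraries() requires a seed")
  config <- sim$config
  libs <- bind_rows(lapply(names(config$depths), function(org) {
    d <- config$depths[[org]]
    tibble(
      id = paste0(org, c("_control", "_nacl")),
      organ = org, condition = c("control", "NaCl"),
      depth = c(ceiling(d / 2), floor(d / 2))
    )
  }))

  w_base <- sim$tags$weight
  de_idx <- match(sim$de$tag_id, sim$tags$tag_id)
  w_nacl <- w_base
  w_nacl[de_idx] <- w_nacl[de_idx] * exp(sim$de$r_ln)

  withr::with_seed(seed, {
    reads <- list()
    counts <- tibble(tag_id = sim$tags$tag_id, sequence = sim$tags$sequence)
    for (i in seq_len(nrow(libs))) {
      w <- if (libs$condition[i] == "NaCl") w_nacl else w_base
      depth <- libs$depth[i]
      obs <- sample.int(length(w), depth, replace = TRUE, prob = w)
      if (length(obs) %% 2 == 1) {
        obs <- c(obs, sample.int(length(w), 1, prob = w))
      }
      counts[[libs$id[i]]] <- tabulate(obs, nbins = length(w))
      t1 <- obs[seq(1, length(obs), by = 2)]
      t2 <- obs[seq(2, length(obs), by = 2)]
      rd <- paste0(sim$tags$sequence[t1], revcomp(sim$tags$sequence[t2]))
      names(rd) <- sprintf("%s_r%06d", libs$id[i], seq_along(rd))
      reads[[libs$id[i]]] <- rd
    }
    list(reads = reads, counts = counts, libraries = libs)
  })
}

#' Design mismatch probe variants of a tag
#'
#' Microarray cross-hybridization controls for a spotted 26 bp tag: three
#' oligo variants carrying the complement of the original base at position 7;
#' at positions 7 and 13; and at positions 7, 13 and 20. The CATG anchor
#' (positions 1--4) is never altered.
#'
#' @param tag A valid 26 bp tag.
#' @return Tibble `variant` (`mm7`, `mm7_13`, `mm7_13_20`), `sequence`.
#' @export
design_mismatch_probes <- function(tag) {
  assert_valid_tags(tag)
  stopifnot(length(tag) == 1)
  flip <- function(positions) {
    v <- strsplit(tag, "")[[1]]
    v[positions] <- chartr("ACGT", "TGCA", v[positions])
    paste(v, collapse = "")
  }
  tibble(
    variant = c("mm7", "mm7_13", "mm7_13_20"),
    sequence = c(flip(7), flip(c(7, 13)), flip(c(7, 13, 20)))
  )
}
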