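test_that("zero divergence gives identical references; conserved blocks always match", {
  flat <- make_references(divergence_rates = c(species = 0, genus = 0,
                                               family = 0, phylum = 0),
                          seed = 2)
  expect_equal(length(unique(flat$references$sequence)), 1L)

  made <- make_references(seed = 2)
  plan <- default_block_plan()
  cons <- unlist(lapply(which(plan$type == "conserved"), function(i)
    (plan$start[i] + 1L):plan$end[i]))
  mats <- lapply(made$references$sequence,
                 function(s) strsplit(s, "")[[1]][cons])
  for (m in mats[-1]) expect_identical(m, mats[[1]])
})

test_that("two species of one genus differ only in hypervariable blocks", {
  made <- make_references(n_phyla = 1, genera_per_phylum = 1,
                          species_per_genus = 2, seed = 5)
  a <- strsplit(made$references$sequence[1], "")[[1]]
  b <- strsplit(made$references$sequence[2], "")[[1]]
  plan <- default_block_plan()
  vpos <- unlist(lapply(which(plan$type == "variable"), function(i)
    (plan$start[i] + 1L):plan$end[i]))
  diff_pos <- which(a != b)
  expect_true(all(diff_pos %in% vpos))
  # two independent species branches at rate 0.02 over 900 variable bases
  expect_gt(length(diff_pos), 5)
  expect_lt(length(diff_pos) / length(vpos), 0.1)
})

test_that("reference generation is deterministic and validates divergence order", {
  a <- make_references(seed = 9)
  b <- make_references(seed = 9)
  expect_identical(a, b)
  expect_error(make_references(divergence_rates = c(species = 0.1,
                                                    genus = 0.05,
                                                    family = 0.08,
                                                    phylum = 0.15)),
               "non-decreasing")
})

test_that("pairwise identity decreases with taxonomic distance", {
  made <- make_references(n_phyla = 2, genera_per_phylum = 2,
                          species_per_genus = 2, seed = 13)
  tx <- build_taxonomy(made$taxonomy)
  seqs <- lapply(made$references$sequence, function(s) strsplit(s, "")[[1]])
  ident <- function(i, j) mean(seqs[[i]] == seqs[[j]])
  taxa <- tx$seq_to_taxon[made$references$sequence_id]
  lev <- function(i, j) {
    l <- taxa_lca(tx$tree, taxa[[i]], taxa[[j]])
    tx$tree$nodes$rank[l]
  }
  pairs <- t(utils::combn(length(seqs), 2))
  sims <- vapply(seq_len(nrow(pairs)), function(r)
    ident(pairs[r, 1], pairs[r, 2]), numeric(1))
  levs <- vapply(seq_len(nrow(pairs)), function(r)
    lev(pairs[r, 1], pairs[r, 2]), character(1))
  expect_gt(mean(sims[levs == "genus"]), mean(sims[levs == "family"]))
  expect_gt(mean(sims[levs == "family"]), mean(sims[levs == "domain"]))
})

test_that("amplicon extraction is an exact half-open substring with nested windows", {
  made <- make_references(n_phyla = 1, genera_per_phylum = 1,
                          species_per_genus = 1, seed = 3)
  g <- made$references$sequence[1]
  expect_equal(extract_amplicon(g, list(start = 0, end = nchar(g))), g)
  v34 <- extract_amplicon(g, "V34")
  v4 <- extract_amplicon(g, "V4")
  expect_true(grepl(v4, v34, fixed = TRUE))
  pw <- primer_windows()
  expect_equal(nchar(v34), pw$end[pw$name == "V34"] - pw$start[pw$name == "V34"])
  expect_error(extract_amplicon(g, list(start = 5, end = 5)), "out of range")
  expect_error(extract_amplicon(g, list(start = 0, end = nchar(g) + 1)),
               "out of range")
  expect_error(extract_amplicon(g, "V99"), "unknown primer")
})

test_that("mutation-free reads are exact amplicon substrings; mate 2 is the 3' revcomp", {
  made <- make_references(seed = 17)
  tx <- build_taxonomy(made$taxonomy)
  prof <- community_profile(made$taxonomy, "gut")
  sim <- simulate_reads(made$references, prof, "V12", 200, tx$seq_to_taxon,
                        mut_rate = 0, seed = 31)
  ref_by_id <- stats::setNames(made$references$sequence,
                               made$references$sequence_id)
  for (i in sample(200, 30)) {
    src <- sim$truth$source_id[i]
    amp <- extract_amplicon(ref_by_id[[src]], "V12")
    expect_equal(sim$reads1[[sim$truth$read_id[i]]], substr(amp, 1, 250))
    expect_equal(rc_chr(sim$reads2[[sim$truth$read_id[i]]]),
                 substr(amp, nchar(amp) - 249, nchar(amp)))
  }
})

test_that("a single-taxon profile yields a single-taxon truth table", {
  made <- make_references(n_phyla = 1, genera_per_phylum = 1,
                          species_per_genus = 1, seed = 19)
  tx <- build_taxonomy(made$taxonomy)
  prof <- data.frame(genus = "Genus_001",
                     sequence_id = made$references$sequence_id,
                     abundance = 1)
  sim <- simulate_reads(made$references, prof, "V34", 100, tx$seq_to_taxon,
                        seed = 23)
  expect_equal(nrow(sim$truth), 100L)
  expect_equal(unique(sim$truth$taxon),
               unname(tx$seq_to_taxon[[made$references$sequence_id[1]]]))
  expect_equal(anyDuplicated(sim$truth$read_id), 0L)
})

test_that("observed per-base mismatch rate matches the substitution rate", {
  made <- make_references(seed = 29)
  tx <- build_taxonomy(made$taxonomy)
  prof <- community_profile(made$taxonomy, "ocean")
  n <- 1000
  sim <- simulate_reads(made$references, prof, "V34", n, tx$seq_to_taxon,
                        mut_rate = 0.02, seed = 37)
  ref_by_id <- stats::setNames(made$references$sequence,
                               made$references$sequence_id)
  mism <- 0L; tot <- 0L
  for (i in seq_len(n)) {
    amp <- extract_amplicon(ref_by_id[[sim$truth$source_id[i]]], "V34")
    tmpl <- strsplit(substr(amp, 1, 250), "")[[1]]
    got <- strsplit(sim$reads1[[sim$truth$read_id[i]]], "")[[1]]
    mism <- mism + sum(tmpl != got)
    tot <- tot + 250L
  }
  p_hat <- mism / tot
  se <- sqrt(0.02 * 0.98 / tot)
  expect_lt(abs(p_hat - 0.02), 3 * se)
})

test_that("genus truth counts follow the profile multinomial", {
  made <- make_references(seed = 41)
  tx <- build_taxonomy(made$taxonomy)
  prof <- community_profile(made$taxonomy, "gut")
  sim <- simulate_reads(made$references, prof, "V34", 10000, tx$seq_to_taxon,
                        seed = 43)
  by_seq <- table(factor(sim$truth$source_id, levels = prof$sequence_id))
  gt <- stats::chisq.test(as.integer(by_seq), p = prof$abundance)
  expect_gt(gt$p.value, 0.001)
})

test_that("simulation outputs are byte-identical across runs with one seed", {
  made <- make_references(seed = 47)
  tx <- build_taxonomy(made$taxonomy)
  prof <- community_profile(made$taxonomy, "soil")
  d1 <- tempfile(); d2 <- tempfile()
  for (d in c(d1, d2)) {
    sim <- simulate_reads(made$references, prof, "V45", 150, tx$seq_to_taxon,
                          seed = 53)
    write_simulation(sim, d, references = made$references,
                     taxonomy = made$taxonomy)
  }
  for (f in c("reads_1.fq", "reads_2.fq", "truth.tsv", "refs.fa",
              "taxonomy.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("amplicons shorter than the read length are rejected by name", {
  made <- make_references(seed = 59)
  tx <- build_taxonomy(made$taxonomy)
  prof <- community_profile(made$taxonomy, "gut")
  expect_error(simulate_reads(made$references, prof,
                              list(start = 0, end = 100), 10,
                              tx$seq_to_taxon, read_len = 250),
               "seq_0001")
})

test_that("community profiles are normalized and steeper for gut than soil", {
  made <- make_references(seed = 61)
  gut <- community_profile(made$taxonomy, "gut")
  soil <- community_profile(made$taxonomy, "soil")
  expect_equal(sum(gut$abundance), 1)
  expect_equal(sum(soil$abundance), 1)
  gsum <- function(p) sort(tapply(p$abundance, p$genus, sum), decreasing = TRUE)
  expect_gt(gsum(gut)[1], gsum(soil)[1])
  expect_error(community_profile(made$taxonomy, "desert"), "unknown profile")
})
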