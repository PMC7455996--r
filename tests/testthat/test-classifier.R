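test_that("classify_read follows the hit profile: unanimous, tied, and weighted cases", {
  tx <- tiny_tree()
  tr <- tx$tree
  s1 <- tid(tr, "S1"); s2 <- tid(tr, "S2"); s3 <- tid(tr, "S3")
  g1 <- tid(tr, "G1")
  set.seed(21)

  # all k-mers map to S1 -> S1
  pl <- plant_read(stats::setNames(4L, s1))
  got <- classify_read(pl$index, tr, pl$read)
  expect_true(got$classified)
  expect_equal(got$taxon, s1)
  expect_equal(sum(got$hit_groups$length), nchar(pl$read) - pl$index$k + 1L)

  # equal hits on two species of one genus, plus hits on the genus -> genus
  pl <- plant_read(stats::setNames(c(3L, 3L, 2L), c(s1, s2, g1)))
  expect_equal(classify_read(pl$index, tr, pl$read)$taxon, g1)

  # S1:5 + G1:2 out-scores S3:3 because path scores add along lineages
  pl <- plant_read(stats::setNames(c(5L, 2L, 3L), c(s1, g1, s3)))
  expect_equal(classify_read(pl$index, tr, pl$read)$taxon, s1)

  # zero hits -> unclassified
  none <- classify_read(pl$index, tr, strrep("A", 30))
  expect_false(none$classified)
  expect_equal(none$taxon, 0L)
})

test_that("classify_read agrees with exhaustive path enumeration on random cases", {
  set.seed(77)
  for (rep in 1:12) {
    recs <- random_lineage_records(sample(4:10, 1))
    tr <- build_taxonomy(recs)$tree
    expect_lte(nrow(tr$nodes), 50)
    n_hit <- sample(1:4, 1)
    taxa <- sample(nrow(tr$nodes), n_hit)
    counts <- stats::setNames(sample(1:5, n_hit, replace = TRUE), taxa)
    pl <- plant_read(counts)
    got <- classify_read(pl$index, tr, pl$read)$taxon
    expect_equal(got, bf_assign(tr, counts))
  }
})

test_that("the assigned taxon is ancestral-or-equal to some hit taxon", {
  cm <- small_community(seed = 19, n_reads = 300)
  cls <- classify_reads(cm$index, cm$tx$tree, cm$sim$reads1, cm$sim$reads2)
  for (i in sample(nrow(cls), 50)) {
    if (!cls$classified[i]) next
    hit_taxa <- unique(as.integer(sub(":.*", "", strsplit(
      gsub(" \\|:\\| ", " ", cls$hits[i]), " ")[[1]])))
    hit_taxa <- hit_taxa[hit_taxa > 0]
    ok <- any(vapply(hit_taxa, function(h)
      cls$taxon[i] %in% lineage_of(cm$tx$tree, h), logical(1)))
    expect_true(ok)
  }
})

test_that("mutation-free reads from species-unique references classify to that species", {
  cm <- small_community(seed = 23, n_reads = 400, mut_rate = 0)
  cls <- classify_reads(cm$index, cm$tx$tree, cm$sim$reads1, cm$sim$reads2)
  expect_true(all(cls$classified))
  truth <- cm$sim$truth
  hit <- match(cls$read_id, truth$read_id)
  # each assignment sits on the true species' lineage (species when the
  # window carries species-specific sites, an ancestor when it does not)
  ok <- vapply(seq_len(nrow(cls)), function(i)
    cls$taxon[i] %in% lineage_of(cm$tx$tree, truth$taxon[hit[i]]) ||
      truth$taxon[hit[i]] %in% lineage_of(cm$tx$tree, cls$taxon[i]),
    logical(1))
  expect_true(all(ok))
  expect_gt(mean(cls$taxon == truth$taxon[hit]), 0.9)
})

test_that("adding unrelated references never flips a correct species call off-lineage", {
  tx <- build_taxonomy(data.frame(
    sequence_id = c("r1", "r2", "u1", "u2"),
    lineage = c("k__B; p__P1; g__G1; s__S1", "k__B; p__P1; g__G1; s__S2",
                "k__B; p__P9; g__G9; s__S9", "k__B; p__P8; g__G8; s__S8")))
  set.seed(41)
  mk <- function() paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                         collapse = "")
  seqs <- c(mk(), mk(), mk(), mk())
  refs <- data.frame(sequence_id = c("r1", "r2", "u1", "u2"), sequence = seqs)
  idx_small <- build_kmer_index(refs[1:2, ], tx$seq_to_taxon, tx$tree, k = 21)
  idx_big <- build_kmer_index(refs, tx$seq_to_taxon, tx$tree, k = 21)
  read <- substr(seqs[1], 30, 130)
  before <- classify_read(idx_small, tx$tree, read)$taxon
  after <- classify_read(idx_big, tx$tree, read)$taxon
  s1 <- tx$seq_to_taxon[["r1"]]
  expect_equal(before, s1)
  expect_true(after %in% lineage_of(tx$tree, s1))
})

test_that("classify_reads preserves order, handles empty input, N-reads, and pairing errors", {
  cm <- small_community(seed = 29, n_reads = 50)
  tr <- cm$tx$tree

  empty_fa <- tempfile(fileext = ".fa")
  file.create(empty_fa)
  got <- classify_reads(cm$index, tr, empty_fa)
  expect_equal(nrow(got), 0L)
  expect_equal(unname(attr(got, "summary")), c(0L, 0L))

  # reads copied verbatim from references are all classified
  verb <- substring(cm$made$references$sequence, 101, 350)
  names(verb) <- cm$made$references$sequence_id
  gv <- classify_reads(cm$index, tr, verb)
  expect_true(all(gv$classified))
  expect_equal(gv$read_id, cm$made$references$sequence_id)

  allN <- c(bad = strrep("N", 250))
  gn <- classify_reads(cm$index, tr, allN)
  expect_false(gn$classified)
  expect_equal(gn$taxon, 0L)

  expect_error(classify_reads(cm$index, tr, verb, verb[1:3]),
               "differ in record count")
})

test_that("reads round-trip through FASTQ/FASTA files", {
  cm <- small_community(seed = 37, n_reads = 40)
  d <- tempfile(); write_simulation(cm$sim, d)
  via_file <- classify_reads(cm$index, cm$tx$tree,
                             file.path(d, "reads_1.fq"),
                             file.path(d, "reads_2.fq"))
  via_mem <- classify_reads(cm$index, cm$tx$tree, cm$sim$reads1,
                            cm$sim$reads2)
  expect_equal(via_file$taxon, via_mem$taxon)
  expect_equal(via_file$read_id, via_mem$read_id)
})

test_that("classification output lines round-trip", {
  cm <- small_community(seed = 43, n_reads = 30)
  cls <- classify_reads(cm$index, cm$tx$tree, cm$sim$reads1, cm$sim$reads2)
  f <- tempfile()
  write_classifications(cls, f, header = "demo")
  back <- read_classifications_file(f)
  expect_equal(back$read_id, cls$read_id)
  expect_equal(back$taxon, cls$taxon)
  expect_equal(back$hits, cls$hits)
})

test_that("report aggregation satisfies the clade-count identity", {
  tx <- tiny_tree()
  tr <- tx$tree
  s1 <- tid(tr, "S1"); g1 <- tid(tr, "G1")

  ten <- data.frame(read_id = sprintf("r%d", 1:10), classified = TRUE,
                    taxon = rep(s1, 10))
  rep1 <- make_report(ten, tr)
  row_s1 <- rep1[rep1$taxon == s1, ]
  row_g1 <- rep1[rep1$taxon == g1, ]
  expect_equal(row_s1$direct_reads, 10L)
  expect_equal(row_s1$clade_reads, 10L)
  expect_equal(row_g1$direct_reads, 0L)
  expect_equal(row_g1$clade_reads, 10L)

  mix <- data.frame(read_id = sprintf("r%d", 1:10), classified = TRUE,
                    taxon = c(rep(g1, 5), rep(s1, 5)))
  rep2 <- make_report(mix, tr)
  expect_equal(rep2$clade_reads[rep2$taxon == g1], 10L)
  expect_equal(rep2$direct_reads[rep2$taxon == g1], 5L)
  expect_equal(rep2$clade_reads[rep2$taxon == 1L], 10L)

  none <- data.frame(read_id = c("a", "b"), classified = FALSE,
                     taxon = c(0L, 0L))
  rep3 <- make_report(none, tr)
  expect_equal(rep3$rank_code, "U")
  expect_equal(rep3$clade_reads, 2L)
})

test_that("clade counts equal direct + children clade counts on random assignments", {
  set.seed(53)
  recs <- random_lineage_records(25)
  tr <- build_taxonomy(recs)$tree
  n <- 200
  taxa <- sample(c(0L, seq_len(nrow(tr$nodes))), n, replace = TRUE)
  cls <- data.frame(read_id = sprintf("r%d", 1:n), classified = taxa > 0,
                    taxon = taxa)
  rep <- make_report(cls, tr)
  for (i in which(rep$taxon > 0)) {
    id <- rep$taxon[i]
    kids <- tr$children[[id]]
    kid_clades <- rep$clade_reads[match(kids, rep$taxon)]
    expect_equal(rep$clade_reads[i],
                 rep$direct_reads[i] + sum(kid_clades, na.rm = TRUE))
  }
  expect_equal(rep$clade_reads[rep$taxon == 1L], sum(taxa > 0))
  # report percentages are clade counts over all reads
  expect_equal(rep$percent, round(100 * rep$clade_reads / n, 2))
})

test_that("report serialization round-trips", {
  cm <- small_community(seed = 59, n_reads = 60)
  cls <- classify_reads(cm$index, cm$tx$tree, cm$sim$reads1, cm$sim$reads2)
  rep <- make_report(cls, cm$tx$tree)
  f <- tempfile()
  write_report(rep, f, header = "demo")
  back <- read_report(f)
  expect_equal(back$taxon, rep$taxon)
  expect_equal(back$clade_reads, rep$clade_reads)
  expect_equal(back$direct_reads, rep$direct_reads)
})
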