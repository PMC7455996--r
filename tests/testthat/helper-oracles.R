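# Independent brute-force oracles and random fixture generators. These
# deliberately avoid the package's internal code paths: reverse
# complements are done with chartr, LCAs by intersecting full ancestor
# sets, and classification by scoring every root-to-leaf path of the
# whole tree.

# -- independent reverse complement ------------------------------------
rc_chr <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

canon_chr <- function(s) {
  r <- rc_chr(s)
  ifelse(s <= r, s, r)
}

# -- random taxonomy fixtures ------------------------------------------
# Random Greengenes-style records; small name pools force shared prefixes
# so trees have real internal structure.
random_lineage_records <- function(n, max_depth = 7, pool = 3) {
  ranks <- c("k", "p", "c", "o", "f", "g", "s")
  recs <- vapply(seq_len(n), function(i) {
    d <- sample(seq_len(max_depth), 1)
    parts <- vapply(seq_len(d), function(j) {
      paste0(ranks[j], "__", ranks[j], sample(pool, 1))
    }, character(1))
    paste(parts, collapse = "; ")
  }, character(1))
  data.frame(sequence_id = sprintf("sq%03d", seq_len(n)), lineage = recs,
             stringsAsFactors = FALSE)
}

# -- brute-force LCA ----------------------------------------------------
bf_lca <- function(tree, a, b) {
  common <- intersect(lineage_of(tree, a), lineage_of(tree, b))
  common[which.max(tree$depth[common])]
}

bf_lca_set <- function(tree, ids) Reduce(function(a, b) bf_lca(tree, a, b), unique(ids))

# -- brute-force k-mer -> LCA index ------------------------------------
# Enumerates windows of every sequence on both strands by hand.
bf_kmer_lca <- function(refs, seq_to_taxon, tree, k) {
  acc <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(refs))) {
    s <- toupper(refs$sequence[r])
    taxon <- seq_to_taxon[[refs$sequence_id[r]]]
    for (strand in c(s, rc_chr(s))) {
      n <- nchar(strand)
      if (n < k) next
      for (j in seq_len(n - k + 1)) {
        km <- substr(strand, j, j + k - 1)
        if (grepl("[^ACGT]", km)) next
        km <- canon_chr(km)
        prev <- get0(km, envir = acc)
        assign(km, if (is.null(prev)) taxon else bf_lca(tree, prev, taxon),
               envir = acc)
      }
    }
  }
  keys <- sort(ls(acc))
  stats::setNames(vapply(keys, get, integer(1), envir = acc), keys)
}

# -- brute-force classifier --------------------------------------------
# Scores every root-to-leaf path of the tree by the sum of hits on its
# nodes; the candidate per maximal path is its deepest hit node; ties
# resolve to the LCA of all candidates.
bf_assign <- function(tree, hit_counts) {
  hit_counts <- hit_counts[hit_counts > 0]
  if (length(hit_counts) == 0L) return(0L)
  hit_ids <- as.integer(names(hit_counts))
  is_leaf <- lengths(tree$children) == 0
  leaves <- which(is_leaf)
  score <- vapply(leaves, function(l) {
    sum(hit_counts[as.character(intersect(lineage_of(tree, l), hit_ids))])
  }, numeric(1))
  best_leaves <- leaves[score == max(score)]
  cands <- unique(vapply(best_leaves, function(l) {
    on_path <- intersect(lineage_of(tree, l), hit_ids)
    on_path[which.max(tree$depth[on_path])]
  }, integer(1)))
  if (length(cands) == 1L) cands else bf_lca_set(tree, cands)
}

# -- planted-k-mer reads -----------------------------------------------
# Builds a read whose index hits are known by construction: `taxa[i]`
# copies of a dedicated canonical k-mer per taxon, concatenated. Verifies
# that every planted k-mer occurs exactly the intended number of times
# among the read's windows and no junction window collides with a planted
# k-mer; resamples otherwise.
plant_read <- function(hit_counts, k = 9, max_tries = 50) {
  taxa <- as.integer(names(hit_counts))
  for (try in seq_len(max_tries)) {
    kmers <- unique(canon_chr(vapply(seq_along(taxa), function(i) {
      paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
    }, character(1))))
    if (length(kmers) != length(taxa)) next
    read <- paste(rep(kmers, hit_counts), collapse = "")
    wins <- canon_chr(substring(read, seq_len(nchar(read) - k + 1),
                                seq_len(nchar(read) - k + 1) + k - 1))
    counts_seen <- vapply(kmers, function(km) sum(wins == km), integer(1))
    if (all(counts_seen == hit_counts)) {
      index <- structure(list(k = as.integer(k),
                              entries = stats::setNames(taxa, kmers),
                              n_sequences = 0L, tree_hash = "planted"),
                         class = "kmer_index")
      return(list(read = read, index = index,
                  hit_counts = stats::setNames(hit_counts, taxa)))
    }
  }
  stop("could not plant a collision-free read")
}

# -- small shared tree --------------------------------------------------
# root - Bacteria - {P1 -> C1 -> O1 -> F1 -> {G1 -> {S1, S2}, G2 -> S3},
#                    P2 -> G3 -> S4}
tiny_tree <- function() {
  build_taxonomy(data.frame(
    sequence_id = c("r1", "r2", "r3", "r4"),
    lineage = c(
      "k__Bacteria; p__P1; c__C1; o__O1; f__F1; g__G1; s__S1",
      "k__Bacteria; p__P1; c__C1; o__O1; f__F1; g__G1; s__S2",
      "k__Bacteria; p__P1; c__C1; o__O1; f__F1; g__G2; s__S3",
      "k__Bacteria; p__P2; g__G3; s__S4"),
    stringsAsFactors = FALSE))
}

tid <- function(tree, name) {
  hit <- which(tree$nodes$name == name)
  stopifnot(length(hit) == 1L)
  hit
}

# -- small end-to-end community ----------------------------------------
small_community <- function(seed = 3, n_reads = 1500, mut_rate = 0.02,
                            divergence_rates = c(species = 0.02,
                                                 genus = 0.05,
                                                 family = 0.08,
                                                 phylum = 0.15),
                            genera_per_phylum = 3, profile = "gut",
                            k = 35, window = "V34") {
  made <- make_references(genera_per_phylum = genera_per_phylum,
                          divergence_rates = divergence_rates, seed = seed)
  tx <- build_taxonomy(made$taxonomy)
  index <- build_kmer_index(made$references, tx$seq_to_taxon, tx$tree, k = k)
  prof <- community_profile(made$taxonomy, profile)
  sim <- simulate_reads(made$references, prof, window, n_reads,
                        tx$seq_to_taxon, mut_rate = mut_rate,
                        seed = seed + 1000)
  list(made = made, tx = tx, index = index, prof = prof, sim = sim)
}
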