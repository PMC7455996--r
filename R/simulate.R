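# Synthetic 16S communities and paired-end amplicon reads with ground
# truth.
#
# The synthetic gene alternates conserved blocks (identical in every
# reference, standing in for the universal-primer regions of the real
# gene) with hypervariable blocks that diverge progressively along the
# taxonomy: two species of one genus differ only by the per-species
# substitution rate, two genera of one family additionally by the
# per-genus rate, and so on. Primer windows are fixed coordinate presets
# over this layout, and reads are drawn amplicon-style: mate 1 from the
# 5' end of the window, mate 2 reverse-complemented from the 3' end, with
# independent per-base substitution noise.

#' Default synthetic 16S gene layout
#'
#' A 1,600-bp gene: a 70-bp conserved block followed by nine repeats of
#' (100-bp hypervariable block + 70-bp conserved block). No 250-bp read
#' can sit entirely inside conserved sequence under this layout.
#'
#' @return data.frame with columns `start`, `end` (0-based half-open) and
#'   `type` (`"conserved"` or `"variable"`).
#' @export
default_block_plan <- function() {
  starts <- integer(0); ends <- integer(0); type <- character(0)
  pos <- 0L
  add <- function(len, ty) {
    starts <<- c(starts, pos); ends <<- c(ends, pos + len)
    type <<- c(type, ty); pos <<- pos + len
  }
  add(70L, "conserved")
  for (i in 1:9) { add(100L, "variable"); add(70L, "conserved") }
  data.frame(start = starts, end = ends, type = type,
             stringsAsFactors = FALSE)
}

#' Primer window presets
#'
#' Fixed coordinate windows over the default gene layout, named after the
#' hypervariable regions they bracket. They are presets for the synthetic
#' layout, not real primer coordinates (which are database-specific).
#'
#' @return data.frame with columns `name`, `start`, `end` (0-based
#'   half-open on the synthetic gene).
#' @export
primer_windows <- function() {
  data.frame(name = c("V12", "V34", "V4", "V45"),
             start = c(0L, 340L, 480L, 480L),
             end = c(410L, 780L, 760L, 920L),
             stringsAsFactors = FALSE)
}

.get_window <- function(window) {
  if (is.character(window)) {
    pw <- primer_windows()
    i <- match(window, pw$name)
    if (is.na(i)) stop("unknown primer window: ", window)
    return(list(name = pw$name[i], start = pw$start[i], end = pw$end[i]))
  }
  stopifnot(is.list(window), all(c("start", "end") %in% names(window)))
  if (is.null(window$name)) window$name <- "custom"
  window
}

.rand_base <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# Substitute bases at `positions` of a character vector, each with
# probability `rate`, to a uniformly chosen *different* base.
.diverge <- function(chars, positions, rate) {
  if (rate <= 0 || length(positions) == 0L) return(chars)
  hit <- positions[stats::runif(length(positions)) < rate]
  if (length(hit) == 0L) return(chars)
  cur <- chars[hit]
  repl <- .rand_base(length(hit))
  while (any(same <- repl == cur))
    repl[same] <- .rand_base(sum(same))
  chars[hit] <- repl
  chars
}

#' Generate a hierarchy of synthetic 16S reference sequences
#'
#' Builds a random root gene on the block layout, then derives phylum,
#' family, genus and species sequences by mutating only the hypervariable
#' blocks at the corresponding per-rank rate, so that expected pairwise
#' identity decreases with taxonomic distance. Each phylum holds one
#' class and one order; genera are grouped pairwise into families. All
#' references share identical conserved blocks.
#'
#' @param n_phyla,genera_per_phylum,species_per_genus Community shape
#'   (all at least 1).
#' @param block_plan Gene layout as from [default_block_plan()].
#' @param divergence_rates Named numeric vector with entries `species`,
#'   `genus`, `family`, `phylum`: per-base substitution probability applied
#'   at each branching step, required non-decreasing from species to
#'   phylum.
#' @param seed Integer seed; the same seed always yields byte-identical
#'   references.
#' @return List with `references` (data.frame `sequence_id`, `sequence`)
#'   and `taxonomy` (data.frame `sequence_id`, `lineage` with full
#'   Greengenes-style strings).
#' @export
make_references <- function(n_phyla = 4, genera_per_phylum = 3,
                            species_per_genus = 2,
                            block_plan = default_block_plan(),
                            divergence_rates = c(species = 0.02,
                                                 genus = 0.05,
                                                 family = 0.08,
                                                 phylum = 0.15),
                            seed = 1) {
  stopifnot(n_phyla >= 1, genera_per_phylum >= 1, species_per_genus >= 1)
  need <- c("species", "genus", "family", "phylum")
  if (!all(need %in% names(divergence_rates)))
    stop("divergence_rates must name species, genus, family and phylum")
  dr <- divergence_rates[need]
  if (any(dr < 0) || any(dr > 1))
    stop("divergence rates must lie in [0, 1]")
  if (is.unsorted(dr))
    stop("divergence rates must be non-decreasing from species to phylum")
  if (!is.null(seed)) set.seed(seed)

  gene_len <- max(block_plan$end)
  vpos <- unlist(lapply(which(block_plan$type == "variable"), function(i)
    (block_plan$start[i] + 1L):block_plan$end[i]))
  root <- .rand_base(gene_len)

  ids <- character(0); seqs <- character(0); lineages <- character(0)
  g_counter <- 0L; f_counter <- 0L; s_counter <- 0L
  for (p in seq_len(n_phyla)) {
    phy <- .diverge(root, vpos, dr[["phylum"]])
    fam_of_genus <- ceiling(seq_len(genera_per_phylum) / 2)
    fam_seqs <- list()
    for (g in seq_len(genera_per_phylum)) {
      fi <- fam_of_genus[g]
      if (is.null(fam_seqs[paste0("f", fi)][[1]])) {
        f_counter <- f_counter + 1L
        fam_seqs[[paste0("f", fi)]] <- list(
          seq = .diverge(phy, vpos, dr[["family"]]),
          name = sprintf("Family_%03d", f_counter))
      }
      fam <- fam_seqs[[paste0("f", fi)]]
      g_counter <- g_counter + 1L
      gen <- .diverge(fam$seq, vpos, dr[["genus"]])
      for (s in seq_len(species_per_genus)) {
        s_counter <- s_counter + 1L
        sp <- .diverge(gen, vpos, dr[["species"]])
        ids <- c(ids, sprintf("seq_%04d", s_counter))
        seqs <- c(seqs, paste(sp, collapse = ""))
        lineages <- c(lineages, paste0(
          "k__Bacteria; ",
          sprintf("p__Phylum_%02d; ", p),
          sprintf("c__Class_%02d; ", p),
          sprintf("o__Order_%02d; ", p),
          sprintf("f__%s; ", fam$name),
          sprintf("g__Genus_%03d; ", g_counter),
          sprintf("s__Species_%04d", s_counter)))
      }
    }
  }
  list(references = data.frame(sequence_id = ids, sequence = seqs,
                               stringsAsFactors = FALSE),
       taxonomy = data.frame(sequence_id = ids, lineage = lineages,
                             stringsAsFactors = FALSE))
}

#' Extract an amplicon from a reference gene
#'
#' @param ref A single nucleotide string (full synthetic gene).
#' @param window A primer window name (see [primer_windows()]) or a list
#'   with `start`, `end` (0-based half-open).
#' @return The amplicon substring.
#' @export
extract_amplicon <- function(ref, window) {
  w <- .get_window(window)
  L <- nchar(ref)
  if (w$start < 0L || w$end > L || w$start >= w$end)
    stop("primer window [", w$start, ",", w$end,
         ") is out of range for a ", L, "-bp gene")
  substr(ref, w$start + 1L, w$end)
}

#' Community abundance profiles
#'
#' Builds a rank-abundance profile over the genera of a reference set
#' using a deterministic log-normal curve: abundances are log-normal
#' quantiles over genus ranks, steep for the gut-like profile
#' (sigma = 1.6), intermediate for ocean-like (1.0) and flat for
#' soil-like (0.4). Within a genus the abundance is split evenly across
#' its species/sequences. Genus ranks follow the order of first
#' appearance in the taxonomy, so profiles are fully reproducible.
#'
#' @param taxonomy data.frame (`sequence_id`, `lineage`) as from
#'   [make_references()].
#' @param profile `"gut"`, `"ocean"`, `"soil"`, or a numeric sigma for a
#'   custom log-normal steepness.
#' @return A `community_profile` data.frame with columns `genus`,
#'   `sequence_id`, `abundance` (abundances sum to 1).
#' @export
community_profile <- function(taxonomy, profile = "gut") {
  sigma <- if (is.numeric(profile)) profile
           else switch(profile, gut = 1.6, ocean = 1.0, soil = 0.4,
                       stop("unknown profile: ", profile))
  genus <- vapply(taxonomy$lineage, function(l) {
    p <- parse_lineage(l); v <- p$name[p$rank == "genus"]
    if (length(v)) v else NA_character_
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(genus))
    stop("every reference lineage must name a genus")
  ug <- unique(genus)
  G <- length(ug)
  gab <- stats::qlnorm((G - seq_len(G) + 0.5) / G, meanlog = 0,
                       sdlog = sigma)
  gab <- gab / sum(gab)
  per_seq <- numeric(nrow(taxonomy))
  for (i in seq_len(G)) {
    members <- which(genus == ug[i])
    per_seq[members] <- gab[i] / length(members)
  }
  out <- data.frame(genus = genus, sequence_id = taxonomy$sequence_id,
                    abundance = per_seq, stringsAsFactors = FALSE)
  class(out) <- c("community_profile", "data.frame")
  out
}

#' Simulate paired-end amplicon reads with ground truth
#'
#' Draws source sequences from the community profile (multinomially),
#' takes mate 1 from the 5' end of each amplicon and mate 2 as the
#' reverse complement of its 3' end, and substitutes every base
#' independently with probability `mut_rate` to a uniformly chosen
#' different base. Read order is shuffled. The truth table records the
#' source taxon and sequence of every read exactly once.
#'
#' @param references data.frame (`sequence_id`, `sequence`).
#' @param profile A `community_profile`.
#' @param window Primer window name or list (`start`, `end`).
#' @param n_reads Number of reads (pairs).
#' @param seq_to_taxon Named integer vector, sequence id -> taxon id, used
#'   to fill the truth table.
#' @param read_len Read length in bases (default 250).
#' @param mut_rate Per-base substitution probability in `[0, 1)`
#'   (default 0.02).
#' @param paired Produce mate pairs (default) or single-end reads.
#' @param seed Integer seed; identical seeds give identical reads and
#'   truth.
#' @return List with `reads1` (named character vector), `reads2` (or
#'   `NULL` for single-end) and `truth` (data.frame `read_id`, `taxon`,
#'   `source_id`).
#' @export
simulate_reads <- function(references, profile, window, n_reads,
                           seq_to_taxon, read_len = 250, mut_rate = 0.02,
                           paired = TRUE, seed = NULL) {
  stopifnot(n_reads >= 1, mut_rate >= 0, mut_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  w <- .get_window(window)
  prof <- profile[profile$abundance > 0, , drop = FALSE]
  ref_seq <- stats::setNames(references$sequence, references$sequence_id)
  missing <- setdiff(prof$sequence_id, names(ref_seq))
  if (length(missing))
    stop("profile names a sequence not in references: ", sQuote(missing[1]))
  amps <- vapply(ref_seq[prof$sequence_id], extract_amplicon, character(1),
                 window = w)
  short <- nchar(amps) < read_len
  if (any(short))
    stop("amplicon of ", sQuote(prof$sequence_id[which(short)[1]]),
         " is shorter than read_len (", read_len, ")")
  counts <- as.vector(stats::rmultinom(1, n_reads, prof$abundance))

  src <- rep(seq_len(nrow(prof)), counts)
  t1 <- substr(amps, 1L, read_len)
  t2 <- .revcomp(substring(amps, nchar(amps) - read_len + 1L, nchar(amps)))

  expand <- function(templates) {
    chars <- strsplit(templates, "", fixed = TRUE)
    big <- unlist(chars[src], use.names = FALSE)
    if (mut_rate > 0) {
      hit <- which(stats::runif(length(big)) < mut_rate)
      if (length(hit)) {
        cur <- big[hit]
        repl <- .rand_base(length(hit))
        while (any(same <- repl == cur))
          repl[same] <- .rand_base(sum(same))
        big[hit] <- repl
      }
    }
    m <- matrix(big, nrow = n_reads, ncol = read_len, byrow = TRUE)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  r1 <- expand(t1)
  r2 <- if (paired) expand(t2) else NULL

  perm <- sample.int(n_reads)
  ids <- sprintf("read_%06d", seq_len(n_reads))
  r1 <- stats::setNames(r1[perm], ids)
  if (!is.null(r2)) r2 <- stats::setNames(r2[perm], ids)
  source_id <- prof$sequence_id[src][perm]
  truth <- data.frame(read_id = ids,
                      taxon = unname(seq_to_taxon[source_id]),
                      source_id = source_id, stringsAsFactors = FALSE)
  list(reads1 = r1, reads2 = r2, truth = truth,
       window = w$name, read_len = read_len, mut_rate = mut_rate)
}

#' Write simulated reads, references and truth to a directory
#'
#' Produces `reads_1.fq`/`reads_2.fq` (or `reads.fq` for single-end,
#' constant Q40 quality), `refs.fa`, `taxonomy.tsv` (sequence id, lineage)
#' and `truth.tsv` (read id, taxon id, source sequence id).
#'
#' @param sim Result of [simulate_reads()].
#' @param outdir Output directory (created if needed).
#' @param references,taxonomy Optional data.frames from
#'   [make_references()]; written alongside the reads when given.
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir, references = NULL,
                             taxonomy = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fq <- function(reads, path) {
    x <- Biostrings::DNAStringSet(reads)
    q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  if (is.null(sim$reads2)) {
    write_fq(sim$reads1, file.path(outdir, "reads.fq"))
  } else {
    write_fq(sim$reads1, file.path(outdir, "reads_1.fq"))
    write_fq(sim$reads2, file.path(outdir, "reads_2.fq"))
  }
  utils::write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(references)) {
    x <- Biostrings::DNAStringSet(stats::setNames(references$sequence,
                                                  references$sequence_id))
    Biostrings::writeXStringSet(x, file.path(outdir, "refs.fa"))
  }
  if (!is.null(taxonomy))
    utils::write.table(taxonomy, file.path(outdir, "taxonomy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  invisible(outdir)
}
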