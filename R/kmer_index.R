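# Canonical k-mer -> LCA database construction.
#
# Classification semantics are defined entirely at the k-mer -> LCA level:
# every k-mer of every reference sequence is recorded under the lowest
# common ancestor of all taxa whose sequences contain it (on either
# strand). The index is a plain sorted map, serialized as TSV, so builds
# are inspectable and bit-reproducible.

.revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Enumerate canonical k-mers of a sequence
#'
#' Slides a window of width `k` over the sequence and reports, for every
#' window free of non-ACGT characters, the canonical form of the k-mer: the
#' lexicographic minimum of the k-mer and its reverse complement, so that a
#' sequence and its reverse complement yield the same k-mer set.
#'
#' @param seq A single nucleotide string (case-insensitive). Characters
#'   outside ACGT (e.g. N) break windows: any window containing one is
#'   skipped.
#' @param k Window width, a positive integer.
#' @return data.frame with columns `position` (0-based window start) and
#'   `kmer` (canonical k-mer). Zero rows when the sequence is shorter than
#'   `k` or fully ambiguous.
#' @examples
#' canonical_kmers("AAAAT", 4)  # revcomp("AAAT") = "ATTT" sorts after it
#' @export
canonical_kmers <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k)
    return(data.frame(position = integer(0), kmer = character(0)))
  nwin <- n - k + 1L
  ok <- .valid_windows(seq, k)
  pos <- which(ok)
  if (length(pos) == 0L)
    return(data.frame(position = integer(0), kmer = character(0)))
  fwd <- substring(seq, pos, pos + k - 1L)
  rcseq <- .revcomp(seq)
  # window j of seq corresponds to window nwin - j + 1 of the revcomp
  rev <- substring(rcseq, nwin - pos + 1L, nwin - pos + k)
  data.frame(position = pos - 1L, kmer = .str_pmin(fwd, rev),
             stringsAsFactors = FALSE)
}

# Logical vector over windows: TRUE where the window is pure ACGT.
.valid_windows <- function(seq, k) {
  n <- nchar(seq)
  nwin <- n - k + 1L
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- cumsum(!(chars %in% c("A", "C", "G", "T")))
  bad[seq_len(nwin) + k - 1L] - c(0L, bad)[seq_len(nwin)] == 0L
}

# Locale-independent elementwise minimum of two character vectors.
.str_pmin <- function(a, b) {
  lt <- .str_lt(a, b)
  a[!lt] <- b[!lt]
  a
}

.str_lt <- function(a, b) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  a <= b
}

#' Build a canonical k-mer to LCA index
#'
#' Enumerates the canonical k-mers of every reference sequence and stores
#' each distinct k-mer under the lowest common ancestor of all taxa whose
#' sequences contain it. A k-mer unique to one species maps to that
#' species; one shared by two species of a genus maps to the genus; one
#' shared across phyla maps near the root. The result is independent of the
#' order of the reference sequences.
#'
#' @param refs data.frame with columns `sequence_id` and `sequence`.
#' @param seq_to_taxon Named integer vector (sequence id -> taxon id), as
#'   returned by [build_taxonomy()].
#' @param tree The `taxonomy_tree` the taxa belong to.
#' @param k K-mer width (default 35, the classical nucleotide default of
#'   the k-mer classifier lineage; small k is fine for small references).
#' @return A `kmer_index`: list with `k`, `entries` (named integer vector,
#'   canonical k-mer -> taxon id, sorted by k-mer), `n_sequences`, and
#'   `tree_hash`.
#' @export
build_kmer_index <- function(refs, seq_to_taxon, tree, k = 35) {
  stopifnot(is.data.frame(refs),
            all(c("sequence_id", "sequence") %in% names(refs)))
  k <- as.integer(k)
  missing <- setdiff(refs$sequence_id, names(seq_to_taxon))
  if (length(missing))
    stop("sequence with unknown taxon: ", sQuote(missing[1]))
  per_seq <- lapply(refs$sequence, function(s) unique(canonical_kmers(s, k)$kmer))
  kmers <- unlist(per_seq, use.names = FALSE)
  taxa <- rep(unname(seq_to_taxon[refs$sequence_id]), lengths(per_seq))
  if (length(kmers) == 0L) {
    entries <- integer(0)
  } else {
    o <- order(kmers, taxa, method = "radix")
    ks <- kmers[o]; ts <- taxa[o]
    # dedupe exact (kmer, taxon) pairs first
    pair_dup <- duplicated(paste0(ks, "\x1f", ts))
    ks <- ks[!pair_dup]; ts <- ts[!pair_dup]
    grp_start <- which(!duplicated(ks))
    grp_end <- c(grp_start[-1] - 1L, length(ks))
    uniq <- ks[grp_start]
    vals <- ts[grp_start]
    multi <- which(grp_end > grp_start)
    for (i in multi)
      vals[i] <- .lca_set(tree, ts[grp_start[i]:grp_end[i]])
    entries <- vals
    names(entries) <- uniq
  }
  structure(list(k = k, entries = entries, n_sequences = nrow(refs),
                 tree_hash = tree_hash(tree)),
            class = "kmer_index")
}

#' Summarize a k-mer index
#'
#' @param index A `kmer_index`.
#' @param tree The `taxonomy_tree` the index was built against (needed to
#'   resolve the rank of each stored LCA taxon).
#' @return List with `k`, `n_sequences`, `n_kmers` and `per_rank` (named
#'   integer vector of distinct-k-mer counts by the rank of their stored
#'   LCA taxon); the per-rank counts sum to `n_kmers`.
#' @export
index_stats <- function(index, tree) {
  stopifnot(inherits(index, "kmer_index"))
  if (length(index$entries)) {
    rk <- tree$nodes$rank[index$entries]
  } else {
    rk <- character(0)
  }
  tab <- table(factor(rk, levels = c(TAX_RANKS, "no_rank")))
  per_rank <- as.integer(tab)
  names(per_rank) <- c(TAX_RANKS, "no_rank")
  list(k = index$k, n_sequences = index$n_sequences,
       n_kmers = length(index$entries), per_rank = per_rank)
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("kmer_index: k =", x$k, "|", length(x$entries), "distinct k-mers from",
      x$n_sequences, "sequences\n")
  invisible(x)
}

#' Serialize / load a k-mer index as TSV
#'
#' Two tab-separated columns (`kmer`, `taxon id`) sorted by k-mer, preceded
#' by a comment header recording `k`, the taxonomy hash, and the sequence
#' count, so a mismatched taxonomy can be detected at load/classify time.
#'
#' @param index A `kmer_index`.
#' @param path File path.
#' @return `write_kmer_index` returns `path` invisibly; `read_kmer_index`
#'   returns a `kmer_index`.
#' @export
write_kmer_index <- function(index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#kmertax_index\tk=", index$k,
           "\ttree=", index$tree_hash,
           "\tn_sequences=", index$n_sequences)), con)
  if (length(index$entries))
    writeLines(paste0(names(index$entries), "\t", index$entries), con)
  invisible(path)
}

#' @rdname write_kmer_index
#' @export
read_kmer_index <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#kmertax_index"))
    stop("not a kmertax index file: ", path)
  fields <- strsplit(header, "\t", fixed = TRUE)[[1]][-1]
  kv <- strsplit(fields, "=", fixed = TRUE)
  vals <- vapply(kv, `[`, character(1), 2)
  names(vals) <- vapply(kv, `[`, character(1), 1)
  body <- utils::read.table(path, sep = "\t", header = FALSE, skip = 1L,
                            quote = "", comment.char = "",
                            col.names = c("kmer", "taxon"),
                            colClasses = c("character", "integer"))
  entries <- body$taxon
  names(entries) <- body$kmer
  structure(list(k = as.integer(vals[["k"]]), entries = entries,
                 n_sequences = as.integer(vals[["n_sequences"]]),
                 tree_hash = unname(vals[["tree"]])),
            class = "kmer_index")
}
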