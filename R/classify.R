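# Per-read classification by k-mer lookup and root-to-leaf path scoring.
#
# Every k-mer window of a read (both mates pooled for a pair) is looked up
# in the index, giving a per-window taxon verdict (0 = no hit). Hits are
# accumulated per taxon, each root-to-leaf path of the hit-induced subtree
# is scored by the sum of hits on its nodes, and the read is assigned to
# the leaf of the maximal path; ties resolve to the LCA of all tied
# leaves. A read with no hits at all is unclassified (taxon 0).

# Window-by-window taxon verdicts for a batch of sequences.
# Returns a list (one integer vector per sequence) of taxon ids, 0 for
# windows with no index hit (including windows containing non-ACGT).
.window_taxa <- function(seqs, index) {
  k <- index$k
  keys <- names(index$entries)
  n <- length(seqs)
  out <- vector("list", n)
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    if (L < k) { out[idx] <- list(integer(0)); next }
    nwin <- L - k + 1L
    ss <- seqs[idx]
    rc <- .revcomp(ss)
    can <- matrix("", length(idx), nwin)
    for (j in seq_len(nwin)) {
      fwd <- substr(ss, j, j + k - 1L)
      rev <- substr(rc, nwin - j + 1L, nwin - j + k - 1L + 1L)
      can[, j] <- .str_pmin(fwd, rev)
    }
    hit <- match(as.vector(can), keys)
    v <- unname(index$entries[hit])
    v[is.na(v)] <- 0L
    vm <- matrix(v, length(idx), nwin)
    for (ii in seq_along(idx)) out[[idx[ii]]] <- vm[ii, ]
  }
  out
}

# Assign a taxon from pooled per-window verdicts. 0 = unclassified.
.assign_taxon <- function(hit_vec, tree) {
  h <- hit_vec[hit_vec > 0L]
  if (length(h) == 0L) return(0L)
  ut <- unique(h)
  cnt <- tabulate(match(h, ut), nbins = length(ut))
  sc <- numeric(length(ut))
  for (i in seq_along(ut)) {
    m <- match(tree$paths[[ut[i]]], ut, nomatch = 0L)
    sc[i] <- sum(cnt[m])
  }
  best <- ut[sc == max(sc)]
  if (length(best) == 1L) best else .lca_set(tree, best)
}

# Kraken-dialect hit string: "taxid:runlength ..." with "|:|" between mates.
.hit_string <- function(groups1, groups2 = NULL) {
  enc <- function(v) {
    if (length(v) == 0L) return("")
    r <- rle(v)
    paste(paste0(r$values, ":", r$lengths), collapse = " ")
  }
  if (is.null(groups2)) enc(groups1)
  else paste(enc(groups1), "|:|", enc(groups2))
}

#' Classify a single read or read pair
#'
#' @param index A `kmer_index`.
#' @param tree The matching `taxonomy_tree`.
#' @param seq Nucleotide string (mate 1).
#' @param seq2 Optional mate-2 string; when given, both mates' k-mer hits
#'   are pooled into one score and a single joint verdict is produced.
#' @param read_id Identifier recorded in the result.
#' @return A `read_classification`: list with `read_id`, `classified`,
#'   `taxon` (0 when unclassified), `read_length` (total bases over both
#'   mates), and `hit_groups` (data.frame of consecutive identical window
#'   verdicts: `taxon`, `length`; run lengths sum to the number of k-mer
#'   windows).
#' @export
classify_read <- function(index, tree, seq, seq2 = NULL, read_id = "read") {
  v1 <- .window_taxa(seq, index)[[1]]
  v2 <- if (is.null(seq2)) integer(0) else .window_taxa(seq2, index)[[1]]
  pooled <- c(v1, v2)
  taxon <- .assign_taxon(pooled, tree)
  groups <- if (length(pooled)) {
    r <- rle(pooled)
    data.frame(taxon = r$values, length = r$lengths)
  } else {
    data.frame(taxon = integer(0), length = integer(0))
  }
  structure(list(read_id = read_id, classified = taxon > 0L, taxon = taxon,
                 read_length = nchar(seq) + if (is.null(seq2)) 0L else nchar(seq2),
                 hit_groups = groups),
            class = "read_classification")
}

#' @export
print.read_classification <- function(x, ...) {
  cat(if (x$classified) "C" else "U", x$read_id, x$taxon, x$read_length, "\n")
  invisible(x)
}

.read_seqs <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    s <- as.character(x)
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", x, ignore.case = TRUE))
      "fastq" else "fasta"
    s <- as.character(Biostrings::readDNAStringSet(x, format = fmt))
  } else if (is.character(x)) {
    s <- x
  } else {
    stop("reads must be a file path, character vector, or DNAStringSet")
  }
  if (!is.null(names(s)))
    names(s) <- sub("\\s.*$", "", names(s))
  s
}

#' Classify a file (or vector) of reads
#'
#' Streams reads through the classifier in batches, preserving input order.
#' Paired inputs must have the same number of records, aligned by order.
#'
#' @param index A `kmer_index`.
#' @param tree The matching `taxonomy_tree`.
#' @param reads FASTA/FASTQ path, named character vector, or DNAStringSet.
#' @param reads2 Optional mate-2 input of the same length as `reads`.
#' @param batch_size Reads per processing batch (memory/speed trade-off).
#' @return A data.frame of class `read_classifications` with columns
#'   `read_id`, `classified`, `taxon`, `length`, `hits` (Kraken-dialect
#'   taxid:runlength string), plus attribute `summary` (named vector with
#'   `classified` / `unclassified` totals).
#' @export
classify_reads <- function(index, tree, reads, reads2 = NULL,
                           batch_size = 2000L) {
  s1 <- .read_seqs(reads)
  s2 <- if (is.null(reads2)) NULL else .read_seqs(reads2)
  if (!is.null(s2) && length(s2) != length(s1))
    stop("paired read files differ in record count: ",
         length(s1), " vs ", length(s2))
  n <- length(s1)
  ids <- names(s1)
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_len(n))
  taxon <- integer(n); len <- integer(n); hits <- character(n)
  for (start in seq.int(1L, max(n, 1L), by = batch_size)) {
    if (n == 0L) break
    iv <- start:min(start + batch_size - 1L, n)
    v1 <- .window_taxa(s1[iv], index)
    v2 <- if (is.null(s2)) NULL else .window_taxa(s2[iv], index)
    for (j in seq_along(iv)) {
      i <- iv[j]
      pooled <- if (is.null(v2)) v1[[j]] else c(v1[[j]], v2[[j]])
      taxon[i] <- .assign_taxon(pooled, tree)
      len[i] <- nchar(s1[i]) + if (is.null(s2)) 0L else nchar(s2[i])
      hits[i] <- if (is.null(v2)) .hit_string(v1[[j]])
                 else .hit_string(v1[[j]], v2[[j]])
    }
  }
  out <- data.frame(read_id = ids, classified = taxon > 0L, taxon = taxon,
                    length = len, hits = hits, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "summary") <- c(classified = sum(out$classified),
                            unclassified = sum(!out$classified))
  class(out) <- c("read_classifications", "data.frame")
  out
}

#' Write / read per-read classifications (Kraken dialect)
#'
#' Tab-delimited, one line per read (pair):
#' `C|U<TAB>read_id<TAB>taxid<TAB>length<TAB>taxid:runlength pairs`.
#'
#' @param x A `read_classifications` data.frame.
#' @param path File path.
#' @param header Optional comment lines (without `#`) written atop the file.
#' @return `write_classifications` returns `path` invisibly;
#'   `read_classifications_file` returns a `read_classifications` data.frame.
#' @export
write_classifications <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (nrow(x))
    writeLines(paste(ifelse(x$classified, "C", "U"), x$read_id, x$taxon,
                     x$length, x$hits, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_classifications
#' @export
read_classifications_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) {
    out <- data.frame(read_id = character(0), classified = logical(0),
                      taxon = integer(0), length = integer(0),
                      hits = character(0))
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 4L)
    if (length(bad))
      stop("malformed classification record at line ", bad[1])
    out <- data.frame(
      read_id = vapply(parts, `[`, character(1), 2),
      classified = vapply(parts, `[`, character(1), 1) == "C",
      taxon = as.integer(vapply(parts, `[`, character(1), 3)),
      length = as.integer(vapply(parts, `[`, character(1), 4)),
      hits = vapply(parts, function(p) if (length(p) >= 5L) p[5] else "",
                    character(1)),
      stringsAsFactors = FALSE)
  }
  class(out) <- c("read_classifications", "data.frame")
  out
}

#' Build a hierarchical classification report
#'
#' Aggregates per-read assignments into the Kraken-style report: for every
#' taxon with any reads in its clade, the percentage of all reads, the
#' clade count (reads at the node or any descendant), the direct count,
#' a one-letter rank code (U,R,D,P,C,O,F,G,S), the taxon id, and the name
#' indented two spaces per tree depth. Rows are in depth-first order with
#' children sorted by decreasing clade count; an unclassified row leads
#' when any read is unclassified.
#'
#' @param classifications A `read_classifications` data.frame (or any
#'   data.frame with `classified` and `taxon` columns).
#' @param tree The `taxonomy_tree` classified against.
#' @return A data.frame of class `classification_report` with columns
#'   `percent`, `clade_reads`, `direct_reads`, `rank_code`, `taxon`, `name`.
#' @export
make_report <- function(classifications, tree) {
  n_nodes <- nrow(tree$nodes)
  total <- nrow(classifications)
  cls <- classifications$taxon[classifications$classified]
  if (any(cls < 1L | cls > n_nodes))
    stop("classification refers to a taxon not in the tree")
  direct <- tabulate(cls, nbins = n_nodes)
  clade <- direct
  for (i in rev(seq_len(n_nodes))) {
    p <- tree$nodes$parent_id[i]
    if (p != i) clade[p] <- clade[p] + clade[i]
  }
  rank_code <- c(root = "R", domain = "D", phylum = "P", class = "C",
                 order = "O", family = "F", genus = "G", species = "S",
                 no_rank = "-")
  rows <- list()
  n_uncl <- total - length(cls)
  if (n_uncl > 0L || total == 0L)
    rows[[length(rows) + 1L]] <- data.frame(
      percent = if (total) round(100 * n_uncl / total, 2) else 0,
      clade_reads = n_uncl, direct_reads = n_uncl, rank_code = "U",
      taxon = 0L, name = "unclassified", stringsAsFactors = FALSE)
  emit <- function(id) {
    if (clade[id] == 0L) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      percent = round(100 * clade[id] / total, 2),
      clade_reads = clade[id], direct_reads = direct[id],
      rank_code = unname(rank_code[tree$nodes$rank[id]]),
      taxon = id,
      name = paste0(strrep("  ", tree$depth[id]), tree$nodes$name[id]),
      stringsAsFactors = FALSE)
    kids <- tree$children[[id]]
    if (length(kids)) {
      kids <- kids[order(-clade[kids], kids)]
      for (kid in kids) emit(kid)
    }
  }
  if (total > 0L) emit(1L)
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(percent = numeric(0), clade_reads = integer(0),
                      direct_reads = integer(0), rank_code = character(0),
                      taxon = integer(0), name = character(0))
  class(out) <- c("classification_report", "data.frame")
  out
}

#' Write / read a classification report
#'
#' Six tab-separated columns, no column header (the conventional report
#' layout); comment lines starting with `#` are permitted and skipped on
#' read.
#'
#' @param report A `classification_report`.
#' @param path File path.
#' @param header Optional comment lines (without `#`).
#' @return `write_report` returns `path` invisibly; `read_report` a
#'   `classification_report` data.frame.
#' @export
write_report <- function(report, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (nrow(report))
    writeLines(paste(sprintf("%6.2f", report$percent), report$clade_reads,
                     report$direct_reads, report$rank_code, report$taxon,
                     report$name, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "#",
                           col.names = c("percent", "clade_reads",
                                         "direct_reads", "rank_code",
                                         "taxon", "name"),
                           colClasses = c("numeric", "integer", "integer",
                                          "character", "integer", "character"))
  class(out) <- c("classification_report", "data.frame")
  out
}

#' Direct per-node read counts
#'
#' Extracts the directly-assigned read count of every taxon (not clade
#' counts) from either a `read_classifications` data.frame or a
#' `classification_report`, in the named-vector form [redistribute()]
#' expects.
#'
#' @param x A `read_classifications` or `classification_report`.
#' @return Named numeric vector, taxon id -> directly assigned reads.
#' @export
direct_counts <- function(x) {
  if (inherits(x, "classification_report")) {
    v <- x$direct_reads[x$taxon > 0L]
    names(v) <- x$taxon[x$taxon > 0L]
  } else {
    t <- x$taxon[x$classified]
    tab <- table(t)
    v <- as.integer(tab)
    names(v) <- names(tab)
  }
  v[v > 0]
}
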