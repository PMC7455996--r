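# Abundance re-estimation: redistribute reads classified above a target
# rank (genus or species) down to target-rank taxa.
#
# The classifier deliberately places ambiguous reads at internal nodes, so
# raw per-genus roll-ups systematically undercount genera whose reads land
# at family level or above. The redistribution model captures, for each
# target-rank taxon, where reads drawn from its reference sequences tend
# to be classified; counts sitting above the target rank are then pushed
# back down in proportion to those empirical probabilities.

# Ancestor-or-self at `rank` for every node; NA where the lineage has no
# node of that rank.
.rank_ancestor <- function(tree, rank) {
  n <- nrow(tree$nodes)
  anc <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p <- tree$paths[[i]]
    hit <- p[tree$nodes$rank[p] == rank]
    if (length(hit)) anc[i] <- hit[length(hit)]
  }
  anc
}

#' Estimate the read-redistribution model from the reference sequences
#'
#' Re-classifies read-length windows of every reference sequence with the
#' same index the reads will be classified against, and records the
#' empirical probability that a read drawn from each target-rank taxon is
#' assigned to each node of the tree. This is the "prior knowledge of the
#' database sequences" that drives redistribution: a window landing at
#' family level, say, is evidence that reads of that genus routinely
#' classify at that family node.
#'
#' @param index A `kmer_index`.
#' @param tree The matching `taxonomy_tree`.
#' @param refs data.frame (`sequence_id`, `sequence`) -- the same reference
#'   set the index was built from.
#' @param seq_to_taxon Named integer vector, sequence id -> taxon id.
#' @param read_length Window width in bases; must be at least `index$k`.
#' @param stride Distance between consecutive window starts (1 = every
#'   position; larger strides trade resolution for speed).
#' @param target_rank Rank the model redistributes to (`"genus"` or
#'   `"species"`).
#' @return A `redistribution_model`: list with `target_rank`, `read_length`,
#'   `stride`, `P` (data.frame `node`, `target`, `prob`), and `tree_hash`.
#'   For each target taxon the probabilities over nodes sum to 1 (every
#'   window of an indexed sequence classifies somewhere in its own
#'   lineage's tree).
#' @export
estimate_distribution <- function(index, tree, refs, seq_to_taxon,
                                  read_length, stride = 1L,
                                  target_rank = "genus") {
  if (read_length < index$k)
    stop("read_length (", read_length, ") must be >= k (", index$k, ")")
  if (!target_rank %in% TAX_RANKS[-1])
    stop("target_rank must be a canonical rank")
  stride <- max(1L, as.integer(stride))
  tanc <- .rank_ancestor(tree, target_rank)
  win_seq <- character(0); win_target <- integer(0)
  for (r in seq_len(nrow(refs))) {
    sid <- refs$sequence_id[r]
    taxon <- seq_to_taxon[[sid]]
    tgt <- tanc[taxon]
    if (is.na(tgt)) next  # reference lineage has no node at the target rank
    L <- nchar(refs$sequence[r])
    if (L < read_length) next
    starts <- seq.int(1L, L - read_length + 1L, by = stride)
    win_seq <- c(win_seq, substring(refs$sequence[r], starts,
                                    starts + read_length - 1L))
    win_target <- c(win_target, rep(tgt, length(starts)))
  }
  if (length(win_seq) == 0L)
    stop("no reference windows available at read_length ", read_length)
  verdicts <- .window_taxa(win_seq, index)
  assigned <- vapply(verdicts, .assign_taxon, integer(1), tree = tree)
  keep <- assigned > 0L
  agg <- stats::aggregate(list(n = rep(1L, sum(keep))),
                          by = list(node = assigned[keep],
                                    target = win_target[keep]), FUN = sum)
  tot <- tapply(agg$n, agg$target, sum)
  agg$prob <- agg$n / as.numeric(tot[as.character(agg$target)])
  structure(list(target_rank = target_rank,
                 read_length = as.integer(read_length), stride = stride,
                 P = agg[, c("node", "target", "prob")],
                 tree_hash = index$tree_hash),
            class = "redistribution_model")
}

#' @export
print.redistribution_model <- function(x, ...) {
  cat("redistribution_model: target rank", x$target_rank,
      "| read_length", x$read_length, "| stride", x$stride, "|",
      length(unique(x$P$target)), "target taxa\n")
  invisible(x)
}

#' Redistribute classified read counts to a single target rank
#'
#' Counts at or below the target rank roll up into their target-rank
#' ancestor unchanged. A count at a node above the target rank is split
#' among the target-rank descendants of that node in proportion to the
#' model probabilities `P(node, target)`, renormalized over that node's
#' own descendants. Counts at nodes with no supported target-rank
#' descendant (e.g. reads at the root that no reference window ever
#' reproduces, or a family containing no genera) are reported as
#' `unassigned`. Total reads are conserved:
#' `sum(counts) + unassigned = sum(direct_counts)`.
#'
#' @param direct_counts Named numeric vector, taxon id -> directly assigned
#'   reads (as from [direct_counts()] on a report or classifications).
#' @param model A `redistribution_model`.
#' @param tree The `taxonomy_tree` both were built against.
#' @return An `abundance_profile`: list with `counts` (named numeric,
#'   target-rank taxon id -> estimated reads), `unassigned`, and
#'   `target_rank`.
#' @export
redistribute <- function(direct_counts, model, tree) {
  nodes <- as.integer(names(direct_counts))
  if (any(is.na(nodes)) || any(nodes < 1L) || any(nodes > nrow(tree$nodes)))
    stop("direct_counts contains a node not in the tree")
  tanc <- .rank_ancestor(tree, model$target_rank)
  targets <- which(tree$nodes$rank == model$target_rank)
  counts <- stats::setNames(numeric(length(targets)), targets)
  unassigned <- 0
  for (i in seq_along(nodes)) {
    nd <- nodes[i]; cval <- as.numeric(direct_counts[[i]])
    if (cval == 0) next
    if (!is.na(tanc[nd])) {
      counts[as.character(tanc[nd])] <- counts[as.character(tanc[nd])] + cval
    } else {
      rows <- model$P[model$P$node == nd & model$P$prob > 0, , drop = FALSE]
      if (nrow(rows)) {
        # restrict to target taxa inside this node's clade
        in_clade <- vapply(rows$target,
                           function(x) nd %in% tree$paths[[x]], logical(1))
        rows <- rows[in_clade, , drop = FALSE]
      }
      if (nrow(rows) == 0L) {
        unassigned <- unassigned + cval
      } else {
        w <- rows$prob / sum(rows$prob)
        key <- as.character(rows$target)
        counts[key] <- counts[key] + cval * w
      }
    }
  }
  structure(list(counts = counts[counts > 0],
                 unassigned = unassigned,
                 target_rank = model$target_rank),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat("abundance_profile at", x$target_rank, "rank:",
      length(x$counts), "taxa,", round(sum(x$counts), 1), "reads (",
      round(x$unassigned, 1), "unassigned )\n")
  invisible(x)
}

# Integer rounding that preserves the (rounded) column sum: round down,
# then hand out the remaining units to the largest remainders.
.round_preserve_sum <- function(x) {
  total <- round(sum(x))
  fl <- floor(x)
  rem <- x - fl
  short <- as.integer(round(total - sum(fl)))
  if (short > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(short)]
    fl[give] <- fl[give] + 1
  }
  fl
}

#' Tabulate an abundance profile (Bracken-style table)
#'
#' @param profile An `abundance_profile` from [redistribute()].
#' @param direct A named numeric vector of direct per-node counts (the same
#'   one passed to [redistribute()]), used to report how many reads each
#'   target taxon had before redistribution.
#' @param tree The `taxonomy_tree`.
#' @param integer_counts Round estimated reads to integers with
#'   largest-remainder correction so the column total is preserved.
#' @return data.frame with columns `name`, `taxon`, `rank`,
#'   `reads_assigned` (direct roll-up at/below the taxon),
#'   `reads_added`, `reads_estimated`, `fraction_total`.
#' @export
abundance_table <- function(profile, direct, tree, integer_counts = TRUE) {
  tanc <- .rank_ancestor(tree, profile$target_rank)
  ids <- as.integer(names(profile$counts))
  rolled <- stats::setNames(numeric(length(ids)), ids)
  dn <- as.integer(names(direct))
  for (i in seq_along(dn)) {
    a <- tanc[dn[i]]
    if (!is.na(a) && as.character(a) %in% names(rolled))
      rolled[as.character(a)] <- rolled[as.character(a)] + direct[[i]]
  }
  est <- profile$counts
  if (integer_counts) est <- .round_preserve_sum(est)
  out <- data.frame(
    name = tree$nodes$name[ids],
    taxon = ids,
    rank = tree$nodes$rank[ids],
    reads_assigned = unname(rolled),
    reads_added = unname(est - rolled),
    reads_estimated = unname(est),
    fraction_total = unname(if (sum(est) > 0) est / sum(est) else est),
    stringsAsFactors = FALSE)
  out[order(-out$reads_estimated), , drop = FALSE]
}

#' Write an abundance table as TSV
#'
#' @param tab data.frame from [abundance_table()].
#' @param path File path.
#' @param header Optional comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_abundance <- function(tab, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
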