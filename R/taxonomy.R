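# Canonical rank hierarchy, broadest first. "no_rank" is allowed on nodes but
# never produced by the Greengenes-style lineage parser.
TAX_RANKS <- c("root", "domain", "phylum", "class", "order", "family",
               "genus", "species")

LINEAGE_PREFIXES <- c(k = "domain", p = "phylum", c = "class", o = "order",
                      f = "family", g = "genus", s = "species")

#' Parse a Greengenes-style lineage string
#'
#' Splits a semicolon-delimited lineage of the form
#' `"k__Bacteria; p__Firmicutes; c__; ..."` into its named ranks. Fields with
#' an empty suffix after the rank prefix (e.g. `"c__"`) denote an unnamed
#' rank and are dropped, so the result contains only the ranks the lineage
#' actually names, ordered domain to species.
#'
#' @param raw A single lineage string. Prefixes must come from
#'   `k__,p__,c__,o__,f__,g__,s__` and appear in canonical (broad-to-narrow)
#'   order.
#' @return A data.frame with columns `rank` (character) and `name`
#'   (character), one row per named rank.
#' @examples
#' parse_lineage("k__Bacteria; p__Proteobacteria; g__Escherichia")
#' @export
parse_lineage <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(trimws(raw)))
    stop("lineage string must be a single non-empty character value")
  fields <- trimws(strsplit(raw, ";", fixed = TRUE)[[1]])
  fields <- fields[nzchar(fields)]
  if (length(fields) == 0L)
    stop("lineage string contains no fields: ", sQuote(raw))
  prefix <- substr(fields, 1L, 3L)
  letter <- substr(fields, 1L, 1L)
  bad <- !(letter %in% names(LINEAGE_PREFIXES)) | substr(prefix, 2L, 3L) != "__"
  if (any(bad))
    stop("malformed lineage field ", sQuote(fields[which(bad)[1]]),
         ": expected a prefix from k__,p__,c__,o__,f__,g__,s__")
  rank <- unname(LINEAGE_PREFIXES[letter])
  idx <- match(rank, TAX_RANKS)
  if (is.unsorted(idx, strictly = TRUE))
    stop("lineage rank prefixes out of canonical order in ", sQuote(raw))
  name <- trimws(substr(fields, 4L, nchar(fields)))
  keep <- nzchar(name)
  data.frame(rank = rank[keep], name = name[keep], stringsAsFactors = FALSE)
}

# Internal constructor: finalize a taxonomy_tree from a parent/rank/name table.
.new_taxonomy_tree <- function(nodes) {
  n <- nrow(nodes)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- nodes$parent_id[i]
    if (p != nodes$id[i])
      children[[p]] <- c(children[[p]], nodes$id[i])
  }
  depth <- integer(n)
  paths <- vector("list", n)
  # nodes are created parents-first, so a single pass suffices
  for (i in seq_len(n)) {
    p <- nodes$parent_id[i]
    if (p == nodes$id[i]) {
      depth[i] <- 0L
      paths[[i]] <- i
    } else {
      depth[i] <- depth[p] + 1L
      paths[[i]] <- c(paths[[p]], nodes$id[i])
    }
  }
  structure(list(nodes = nodes, children = children, depth = depth,
                 paths = paths),
            class = "taxonomy_tree")
}

#' Build a taxonomy tree from per-sequence lineage strings
#'
#' Constructs a rooted, ranked tree in which identical lineage prefixes share
#' a single node, and maps every input sequence to its most specific named
#' node. Internal ids are dense integers assigned in first-encounter order
#' with the root fixed at id 1, so the same input order always yields the
#' same tree. Unnamed ranks (empty fields such as `"c__"`) are skipped
#' rather than materialized, so a node's parent may sit several canonical
#' ranks above it. Taxa with the same name under different parents are kept
#' distinct (homonyms are keyed by their full lineage).
#'
#' @param records A data.frame with columns `sequence_id` and `lineage`
#'   (Greengenes-style strings), one row per reference sequence.
#' @return A list with elements `tree` (a `taxonomy_tree`) and
#'   `seq_to_taxon` (named integer vector, sequence id to taxon id).
#' @examples
#' recs <- data.frame(
#'   sequence_id = c("s1", "s2"),
#'   lineage = c("k__B; p__P; g__G; s__X", "k__B; p__P; g__G; s__Y"))
#' tx <- build_taxonomy(recs)
#' summarize_ranks(tx$tree)
#' @export
build_taxonomy <- function(records) {
  if (!is.data.frame(records) || !all(c("sequence_id", "lineage") %in% names(records)))
    stop("records must be a data.frame with columns sequence_id and lineage")
  if (nrow(records) == 0L)
    stop("at least one record is required")
  dup <- duplicated(records$sequence_id)
  if (any(dup)) {
    first <- records$lineage[match(records$sequence_id, records$sequence_id)]
    if (any(first != records$lineage))
      stop("duplicate sequence_id with conflicting lineage: ",
           sQuote(records$sequence_id[which(first != records$lineage)[1]]))
    records <- records[!dup, , drop = FALSE]
  }

  ids <- new.env(parent = emptyenv())   # lineage-path key -> node id
  parent_id <- 1L; rank <- "root"; name <- "root"
  n_nodes <- 1L
  assign("\x1froot", 1L, envir = ids)

  seq_taxon <- integer(nrow(records))
  for (r in seq_len(nrow(records))) {
    lin <- parse_lineage(records$lineage[r])
    key <- "\x1froot"
    node <- 1L
    if (nrow(lin) > 0L) {
      for (j in seq_len(nrow(lin))) {
        key <- paste0(key, "\x1f", lin$rank[j], ":", lin$name[j])
        hit <- get0(key, envir = ids)
        if (is.null(hit)) {
          n_nodes <- n_nodes + 1L
          parent_id[n_nodes] <- node
          rank[n_nodes] <- lin$rank[j]
          name[n_nodes] <- lin$name[j]
          assign(key, n_nodes, envir = ids)
          node <- n_nodes
        } else {
          node <- hit
        }
      }
    }
    seq_taxon[r] <- node
  }
  nodes <- data.frame(id = seq_len(n_nodes), parent_id = parent_id,
                      rank = rank, name = name, stringsAsFactors = FALSE)
  names(seq_taxon) <- records$sequence_id
  list(tree = .new_taxonomy_tree(nodes), seq_to_taxon = seq_taxon)
}

.check_taxon_id <- function(tree, id) {
  if (!is.numeric(id) || length(id) != 1L || is.na(id) ||
      id < 1L || id > nrow(tree$nodes))
    stop("unknown taxon id: ", paste(id, collapse = ","))
  as.integer(id)
}

#' Lowest common ancestor of two taxa
#'
#' Returns the deepest node that is ancestral to (or equal to) both
#' arguments. `taxa_lca(t, x, x)` is `x`, and the operation is symmetric.
#'
#' @param tree A `taxonomy_tree`.
#' @param a,b Taxon ids.
#' @return A taxon id (integer).
#' @export
taxa_lca <- function(tree, a, b) {
  a <- .check_taxon_id(tree, a)
  b <- .check_taxon_id(tree, b)
  pa <- tree$paths[[a]]
  pb <- tree$paths[[b]]
  m <- min(length(pa), length(pb))
  same <- pa[seq_len(m)] == pb[seq_len(m)]
  pa[max(which(same))]
}

# LCA of a set of taxon ids (used by index construction and tie-breaking).
.lca_set <- function(tree, ids) {
  ids <- unique(ids)
  if (length(ids) == 1L) return(ids)
  Reduce(function(a, b) taxa_lca(tree, a, b), ids)
}

#' Root-to-taxon lineage
#'
#' @param tree A `taxonomy_tree`.
#' @param id A taxon id.
#' @return Integer vector of taxon ids from the root (first) to `id` (last);
#'   consecutive elements are parent and child.
#' @export
lineage_of <- function(tree, id) {
  id <- .check_taxon_id(tree, id)
  tree$paths[[id]]
}

#' Count named taxa per canonical rank
#'
#' Tallies the distinct named nodes at each canonical rank of the tree, the
#' way reference databases are usually summarized (so many phyla, so many
#' genera, ...). Nodes with rank `no_rank` are excluded.
#'
#' @param tree A `taxonomy_tree`.
#' @return Named integer vector over ranks domain..species.
#' @export
summarize_ranks <- function(tree) {
  ranks <- TAX_RANKS[-1]
  counts <- vapply(ranks, function(rk) sum(tree$nodes$rank == rk), integer(1))
  names(counts) <- ranks
  counts
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree:", nrow(x$nodes), "nodes\n")
  s <- summarize_ranks(x)
  s <- s[s > 0]
  if (length(s))
    cat(paste0("  ", names(s), ": ", s, collapse = "\n"), "\n", sep = "")
  invisible(x)
}

#' Serialize / load a taxonomy tree as TSV
#'
#' The on-disk format is a four-column tab-separated table
#' (`id`, `parent_id`, `rank`, `name`) with a header line; the root has
#' `parent_id` equal to its own id.
#'
#' @param tree A `taxonomy_tree`.
#' @param path Output (input) file path.
#' @return `write_tree` returns `path` invisibly; `read_tree` returns a
#'   `taxonomy_tree`.
#' @export
write_tree <- function(tree, path) {
  utils::write.table(tree$nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  nodes <- utils::read.table(path, sep = "\t", header = TRUE,
                             colClasses = c("integer", "integer",
                                            "character", "character"),
                             quote = "", comment.char = "#")
  if (!identical(names(nodes), c("id", "parent_id", "rank", "name")))
    stop("not a taxonomy tree table: ", path)
  .new_taxonomy_tree(nodes)
}

# Stable content hash of a tree, used to detect index/taxonomy mismatches.
tree_hash <- function(tree) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(tree$nodes$id, tree$nodes$parent_id, tree$nodes$rank,
                   tree$nodes$name, sep = "\t"), tf)
  unname(tools::md5sum(tf))
}

#' Read a sequence-id to lineage table
#'
#' Expects a two-column tab-separated file, `sequence_id<TAB>lineage`,
#' without a header (the Greengenes taxonomy dump convention).
#'
#' @param path Input path.
#' @return data.frame with columns `sequence_id`, `lineage`.
#' @export
read_lineage_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                         comment.char = "#",
                         col.names = c("sequence_id", "lineage"),
                         colClasses = "character")
  x
}
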