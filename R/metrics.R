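# Evaluation metrics: abundance-weighted mean absolute proportion error,
# Bray-Curtis dissimilarity, and per-read confusion with vague-positive
# accounting.

.as_count_vector <- function(x, what) {
  if (is.null(x) || length(x) == 0L) return(numeric(0))
  if (!is.numeric(x) || is.null(names(x)))
    stop(what, " must be a named numeric vector (taxon name -> reads)")
  tapply(unname(x), names(x), sum)
}

#' Modified mean absolute proportion error (MAPE)
#'
#' Abundance-weighted mean, over the *true* taxa only, of each taxon's
#' relative count error:
#' `sum_g (T_g / sum(T)) * |A_g - T_g| / T_g`.
#' Taxa absent from the estimate contribute `A_g = 0`; taxa present only
#' in the estimate contribute nothing directly (they inflate other taxa's
#' errors instead). The weighting makes the statistic equal to
#' `sum_g |A_g - T_g| / sum(T)`, so it can exceed 1 when one taxon is
#' grossly over-counted; no clipping is applied.
#'
#' @param true_counts Named numeric vector, taxon -> true read count; all
#'   values must be positive.
#' @param est_counts Named numeric vector, taxon -> estimated read count.
#' @return Non-negative numeric scalar; 0 for a perfect estimate.
#' @examples
#' mape(c(G1 = 50, G2 = 50), c(G1 = 40, G2 = 50))  # 0.1
#' @export
mape <- function(true_counts, est_counts) {
  Tg <- .as_count_vector(true_counts, "true_counts")
  Ag <- .as_count_vector(est_counts, "est_counts")
  if (length(Tg) == 0L) stop("true_counts is empty")
  if (any(Tg <= 0)) stop("all true counts must be positive")
  A <- rep(0, length(Tg))
  hit <- match(names(Tg), names(Ag))
  A[!is.na(hit)] <- Ag[hit[!is.na(hit)]]
  sum((Tg / sum(Tg)) * abs(A - Tg) / Tg)
}

#' Bray-Curtis dissimilarity between two count profiles
#'
#' `BC = 1 - 2C / (S_i + S_j)` where `C` is the sum over taxa present in
#' both profiles of the smaller of the two counts, and `S_i`, `S_j` are
#' the profile totals. Symmetric; 0 for identical profiles, 1 for
#' disjoint taxon sets.
#'
#' @param true_counts,est_counts Named numeric vectors (taxon -> reads).
#'   At least one must be non-empty.
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' bray_curtis(c(G1 = 50, G2 = 50), c(G1 = 40, G2 = 60))  # 0.1
#' @export
bray_curtis <- function(true_counts, est_counts) {
  Tg <- .as_count_vector(true_counts, "true_counts")
  Ag <- .as_count_vector(est_counts, "est_counts")
  if (length(Tg) == 0L && length(Ag) == 0L)
    stop("both profiles are empty")
  common <- intersect(names(Tg), names(Ag))
  C <- if (length(common)) sum(pmin(Tg[common], Ag[common])) else 0
  1 - 2 * C / (sum(Tg) + sum(Ag))
}

#' Per-read confusion counts at a taxonomic level
#'
#' Scores every truth read against its assignment at the chosen level. Let
#' `L` be the true taxon's ancestor at `level`. The read is a true
#' positive (TP) when the assignment lies inside `L`'s clade (at `L` or
#' any descendant -- e.g. assigned to any species of the true genus); a
#' vague positive (VP) when assigned to a strict ancestor of `L` (correct
#' but less specific); a false negative (FN) when unclassified; and a
#' false positive (FP) otherwise (classified outside the true lineage).
#' The four counts partition the evaluated reads. Truth reads whose
#' lineage has no node at `level` are excluded from the tally.
#'
#' VP here excludes TP reads, so `sensitivity = TP / total`; see
#' [sensitivity()].
#'
#' @param assignments Named integer vector (read id -> taxon id, 0 for
#'   unclassified) or a `read_classifications` data.frame.
#' @param truth data.frame with columns `read_id` and `taxon` (true,
#'   most-specific taxon id).
#' @param tree The `taxonomy_tree`.
#' @param level Canonical rank at which to evaluate (e.g. `"genus"`).
#' @return A `confusion_counts` object: list with `level`, `TP`, `VP`,
#'   `FP`, `FN`, `n` (evaluated reads).
#' @export
per_read_confusion <- function(assignments, truth, tree, level) {
  if (!level %in% TAX_RANKS[-1]) stop("level must be a canonical rank")
  if (is.data.frame(assignments))
    assignments <- stats::setNames(assignments$taxon, assignments$read_id)
  hit <- match(truth$read_id, names(assignments))
  if (anyNA(hit))
    stop("assignment missing for read ", sQuote(truth$read_id[which(is.na(hit))[1]]))
  a <- unname(assignments[hit])
  n_nodes <- nrow(tree$nodes)
  if (any(a < 0L | a > n_nodes, na.rm = TRUE) || anyNA(a))
    stop("assignment refers to a taxon not in the tree")
  if (any(truth$taxon < 1L | truth$taxon > n_nodes))
    stop("truth refers to a taxon not in the tree")
  lvl_anc <- .rank_ancestor(tree, level)
  lt <- lvl_anc[truth$taxon]
  keep <- !is.na(lt)
  a <- a[keep]; lt <- lt[keep]
  n <- length(a)
  fn <- a == 0L
  la <- rep(NA_integer_, n)
  la[!fn] <- lvl_anc[a[!fn]]
  tp <- !fn & !is.na(la) & la == lt
  rest <- which(!fn & !tp)
  vp <- logical(n)
  for (i in rest) {
    if (lt[i] %in% tree$paths[[a[i]]]) {
      tp[i] <- TRUE            # below `level` via a lineage that skips it
    } else if (a[i] %in% tree$paths[[lt[i]]] && a[i] != lt[i]) {
      vp[i] <- TRUE            # strict ancestor of the true level taxon
    }
  }
  TP <- sum(tp); VP <- sum(vp); FN <- sum(fn)
  structure(list(level = level, TP = TP, VP = VP,
                 FP = n - TP - VP - FN, FN = FN, n = n),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion at %s: TP=%d VP=%d FP=%d FN=%d (n=%d)\n",
              x$level, x$TP, x$VP, x$FP, x$FN, x$n))
  invisible(x)
}

#' Per-read sensitivity
#'
#' `TP / (TP + VP + FP + FN)`, i.e. the fraction of all evaluated reads
#' confidently placed at (or below, within the correct clade) the
#' evaluation level. Vague positives count against sensitivity but are
#' not errors.
#'
#' @param c A `confusion_counts` object.
#' @return Numeric in `[0, 1]`.
#' @export
sensitivity <- function(c) {
  total <- c$TP + c$VP + c$FP + c$FN
  if (total == 0L) stop("no reads evaluated")
  c$TP / total
}

#' Per-read precision (positive predictive value)
#'
#' `TP / (TP + FP)`: among reads placed confidently (not vaguely, not
#' unclassified), the fraction placed correctly. Undefined (NA) when no
#' read is confidently placed.
#'
#' @param c A `confusion_counts` object.
#' @return Numeric in `[0, 1]`, or `NA_real_` when `TP + FP == 0`.
#' @export
ppv <- function(c) {
  if (c$TP + c$FP == 0L) return(NA_real_)
  c$TP / (c$TP + c$FP)
}

# Genus-name counts from a truth table or an abundance profile, with
# harmonized names.
.named_genus_counts <- function(ids, weights, tree, map) {
  ganc <- .rank_ancestor(tree, "genus")
  g <- ganc[ids]
  keep <- !is.na(g)
  nm <- harmonize_genus(tree$nodes$name[g[keep]], map)
  tapply(weights[keep], nm, sum)
}

#' Evaluate one classified sample against its truth
#'
#' Computes the full metric panel for a single sample: genus-level MAPE
#' and Bray-Curtis dissimilarity between the true genus distribution and
#' the estimated abundance profile (genus names harmonized first), plus
#' per-read sensitivity and PPV at species, genus, family, order, class
#' and phylum level.
#'
#' @param assignments Named integer vector or `read_classifications`
#'   data.frame of per-read assignments.
#' @param abundance An `abundance_profile` at genus rank (from
#'   [redistribute()]), or a named numeric vector of genus-taxon-id ->
#'   reads; `NULL` to fall back to the raw roll-up of `assignments`.
#' @param truth data.frame (`read_id`, `taxon`).
#' @param tree The `taxonomy_tree`.
#' @param map A `harmonization_map` applied to genus names before the
#'   distribution comparison.
#' @param levels Ranks at which to compute per-read metrics.
#' @return data.frame with columns `metric`, `level`, `value`.
#' @export
evaluate_run <- function(assignments, abundance, truth, tree,
                         map = default_harmonization_map(),
                         levels = c("species", "genus", "family", "order",
                                    "class", "phylum")) {
  if (is.data.frame(assignments))
    assignments <- stats::setNames(assignments$taxon, assignments$read_id)
  true_genus <- .named_genus_counts(truth$taxon, rep(1, nrow(truth)),
                                    tree, map)
  if (is.null(abundance)) {
    cls <- assignments[assignments > 0]
    est <- .named_genus_counts(unname(cls), rep(1, length(cls)), tree, map)
  } else {
    counts <- if (inherits(abundance, "abundance_profile"))
      abundance$counts else abundance
    ids <- as.integer(names(counts))
    est <- .named_genus_counts(ids, unname(counts), tree, map)
  }
  rows <- data.frame(metric = c("mape", "bray_curtis"), level = "genus",
                     value = c(mape(true_genus, est),
                               bray_curtis(true_genus, est)),
                     stringsAsFactors = FALSE)
  for (lv in levels) {
    cc <- per_read_confusion(assignments, truth, tree, lv)
    vals <- if (cc$n == 0L) c(NA_real_, NA_real_)  # rank absent from the tree
            else c(sensitivity(cc), ppv(cc))
    rows <- rbind(rows,
                  data.frame(metric = c("sensitivity", "ppv"), level = lv,
                             value = vals, stringsAsFactors = FALSE))
  }
  rows
}

#' Average metric tables across samples
#'
#' Unweighted mean of each (metric, level) cell across a list of
#' [evaluate_run()] results.
#'
#' @param runs List of data.frames as returned by [evaluate_run()].
#' @return data.frame with columns `metric`, `level`, `value`.
#' @export
average_metrics <- function(runs) {
  all <- do.call(rbind, runs)
  agg <- stats::aggregate(value ~ metric + level, data = all, FUN = mean)
  agg[order(agg$metric, agg$level), , drop = FALSE]
}
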