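# Genus-name harmonization across 16S database dialects.
#
# The three major 16S taxonomies disagree on genus naming: SILVA merges
# several rhizobial genera into one hyphen-joined composite, merges
# Escherichia and Shigella, and splits Clostridium into numbered
# "Clostridium sensu stricto" groups. Comparing a profile built on one
# dialect against a truth set named in another therefore needs an explicit,
# curated mapping from database-specific names onto canonical genus names.
# There is deliberately no fuzzy matching here: the map is configuration.

#' Build a genus harmonization map
#'
#' @param entries Named list: canonical genus name to character vector of
#'   database-specific variant names. A variant may appear under only one
#'   canonical name.
#' @return A `harmonization_map` object.
#' @examples
#' m <- harmonization_map(list(Escherichia = "Escherichia-Shigella"))
#' harmonize_genus("Escherichia-Shigella", m)
#' @export
harmonization_map <- function(entries) {
  if (length(entries) == 0L) {
    lookup <- character(0)
  } else {
    if (is.null(names(entries)) || any(!nzchar(names(entries))))
      stop("entries must be a named list (canonical genus -> variants)")
    variants <- unlist(entries, use.names = FALSE)
    canonical <- rep(names(entries), lengths(entries))
    dup <- duplicated(variants)
    for (clash in unique(variants[dup]))
      if (length(unique(canonical[variants == clash])) > 1L)
        stop("variant ", sQuote(clash), " maps to more than one canonical genus")
    lookup <- canonical[!dup]
    names(lookup) <- variants[!dup]
  }
  structure(list(lookup = lookup), class = "harmonization_map")
}

#' Default harmonization map
#'
#' Covers the merge/split patterns documented for the SILVA and RDP genus
#' dialects: the hyphen-joined rhizobium composite, the Escherichia-Shigella
#' merge, and the numbered "Clostridium sensu stricto 1".."19" split.
#'
#' @return A `harmonization_map`.
#' @export
default_harmonization_map <- function() {
  harmonization_map(list(
    Rhizobium = "Allorhizobium-Neorhizobium-Pararhizobium-Rhizobium",
    Escherichia = "Escherichia-Shigella",
    Clostridium = c("Clostridium sensu stricto",
                    paste("Clostridium sensu stricto", 1:19))
  ))
}

#' Map database-specific genus names onto canonical names
#'
#' Vectorized lookup: names present in the map are replaced by their
#' canonical genus; unmapped names pass through unchanged.
#'
#' @param name Character vector of genus names.
#' @param map A `harmonization_map` (default: [default_harmonization_map()]).
#' @return Character vector of canonical genus names.
#' @export
harmonize_genus <- function(name, map = default_harmonization_map()) {
  if (!inherits(map, "harmonization_map"))
    stop("map must be a harmonization_map")
  hit <- match(name, names(map$lookup))
  out <- name
  out[!is.na(hit)] <- unname(map$lookup[hit[!is.na(hit)]])
  out
}

#' Read a harmonization map from TSV or YAML
#'
#' TSV input is two columns, `canonical<TAB>variant`, no header. YAML input
#' is a mapping from canonical name to a list of variants.
#'
#' @param path Input path; format chosen by extension (`.yml`/`.yaml` vs
#'   anything else as TSV).
#' @return A `harmonization_map`.
#' @export
read_harmonization_map <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    entries <- yaml::read_yaml(path)
    entries <- lapply(entries, as.character)
  } else {
    x <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "#",
                           col.names = c("canonical", "variant"),
                           colClasses = "character")
    entries <- split(x$variant, x$canonical)
  }
  harmonization_map(entries)
}
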