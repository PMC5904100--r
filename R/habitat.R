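#' @name habitat_profiles
#' @title Hierarchical habitat profiling
#'
#' @description
#' Maps per-sequence environmental annotations onto a category hierarchy
#' (a forest rooted at broad habitats such as marine, soils-sediments,
#' freshwater, estuarine-coastal, salt lakes, hot springs, host-associated)
#' and computes level-wise habitat fractions per OTU or clade, excluding
#' sequences assigned only to the broader category above, with Krona-style
#' hierarchical count export.
NULL

#' Default broad-habitat category tree
#'
#' Roots named in the curation scheme plus common subdivisions (marine water
#' versus sediment with depth zones at the 200 m breakpoint; soil pH classes
#' at pH 6.5 / 7.5, including the explicit range categories).
#'
#' @return Character vector of slash-separated category paths.
#' @export
defaultHabitatPaths <- function() {
  c("marine", "marine/water", "marine/water/epipelagic", "marine/water/deep",
    "marine/sediment",
    "soils-sediments", "soils-sediments/acidic", "soils-sediments/neutral",
    "soils-sediments/alkaline", "soils-sediments/acidic-neutral",
    "soils-sediments/neutral-alkaline",
    "freshwater", "estuarine-coastal", "salt-lakes", "hot-springs",
    "host-associated")
}

# expand every prefix of a set of paths
.allPrefixes <- function(paths) {
  unique(unlist(lapply(strsplit(paths, "/", fixed = TRUE), function(p)
    vapply(seq_along(p), function(k) paste(p[1:k], collapse = "/"),
           character(1)))))
}

#' Build a habitat category tree from paths
#'
#' @param paths Character vector of slash-separated category paths; every
#'   prefix becomes a node.
#' @return data.frame with columns path, name, parent, level (a forest).
#' @export
habitatTree <- function(paths = defaultHabitatPaths()) {
  paths <- .allPrefixes(paths)
  parts <- strsplit(paths, "/", fixed = TRUE)
  df <- data.frame(
    path = paths,
    name = vapply(parts, function(p) p[length(p)], character(1)),
    parent = vapply(parts, function(p)
      if (length(p) == 1) NA_character_
      else paste(p[-length(p)], collapse = "/"), character(1)),
    level = lengths(parts))
  df[order(df$path), ]
}

#' Load and validate sequence habitat assignments
#'
#' @param table data.frame (or TSV path) with columns \code{seq_id} and
#'   \code{habitat} (slash-separated path, possibly stopping at any level).
#' @param tree Optional \code{\link{habitatTree}}; when given, every path
#'   must be a known node and unknown categories raise an error listing the
#'   offenders. When \code{NULL} the tree is built from the data.
#' @return List with \code{tree}, \code{assignments} (named character
#'   seq_id -> path) and \code{conflicts} (duplicate annotations resolved
#'   first-wins).
#' @export
loadCategories <- function(table, tree = NULL) {
  if (is.character(table) && length(table) == 1)
    table <- utils::read.table(table, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("seq_id", "habitat") %in% colnames(table)))
  if (is.null(tree)) tree <- habitatTree(unique(table$habitat))
  unknown <- setdiff(unique(table$habitat), tree$path)
  if (length(unknown))
    stop("unknown categories: ", paste(unknown, collapse = ", "))
  dup <- duplicated(table$seq_id)
  conflicts <- data.frame(seq_id = character(0), kept = character(0),
                          dropped = character(0))
  if (any(dup)) {
    for (id in unique(table$seq_id[dup])) {
      vals <- table$habitat[table$seq_id == id]
      if (length(unique(vals)) > 1)
        conflicts <- rbind(conflicts,
                           data.frame(seq_id = id, kept = vals[1],
                                      dropped = paste(vals[-1],
                                                      collapse = ";")))
    }
    table <- table[!dup, , drop = FALSE]
  }
  list(tree = tree,
       assignments = stats::setNames(table$habitat, table$seq_id),
       conflicts = conflicts)
}

#' Bin numeric depth / pH metadata into category nodes
#'
#' Depth: epipelagic above 200 m, deep otherwise. pH: acidic below 6.5,
#' neutral 6.5-7.5, alkaline above 7.5.
#'
#' @param depth_m,ph Numeric vectors.
#' @return Character vector of category names.
#' @export
binDepth <- function(depth_m) ifelse(depth_m <= 200, "epipelagic", "deep")

#' @rdname binDepth
#' @export
binPh <- function(ph) ifelse(ph < 6.5, "acidic",
                             ifelse(ph <= 7.5, "neutral", "alkaline"))

#' Level-wise habitat fractions under one category node
#'
#' The denominator is the number of group sequences assigned at or below any
#' child of \code{at_node}; sequences whose path stops exactly at
#' \code{at_node} are excluded (the broader-category exclusion rule).
#' Fractions over the children sum to 1 when the denominator is positive;
#' a zero denominator yields an undefined (flagged) result rather than
#' zeros.
#'
#' @param group Character vector of sequence ids (an OTU or clade).
#' @param assignments Named character vector seq_id -> path.
#' @param at_node Category path whose children are profiled; \code{NULL} or
#'   \code{""} profiles the root level.
#' @return Named numeric vector of fractions per observed child, with
#'   attributes \code{n} (denominator) and \code{undefined}.
#' @export
levelFractions <- function(group, assignments, at_node = NULL) {
  paths <- assignments[intersect(group, names(assignments))]
  if (is.null(at_node) || !nzchar(at_node)) {
    child <- vapply(strsplit(paths, "/", fixed = TRUE), `[`, character(1), 1)
  } else {
    pre <- paste0(at_node, "/")
    below <- startsWith(paths, pre)
    rest <- substring(paths[below], nchar(pre) + 1L)
    child <- paste0(at_node, "/",
                    vapply(strsplit(rest, "/", fixed = TRUE), `[`,
                           character(1), 1), recycle0 = TRUE)
  }
  n <- length(child)
  if (n == 0) {
    out <- numeric(0)
    attr(out, "n") <- 0L
    attr(out, "undefined") <- TRUE
    return(out)
  }
  tab <- table(child)
  out <- as.numeric(tab) / n
  names(out) <- names(tab)
  attr(out, "n") <- n
  attr(out, "undefined") <- FALSE
  out
}

#' Hierarchical taxon-by-habitat count table
#'
#' Counts sequences (multiplicity-weighted) per named taxon and habitat
#' path. Because taxon member sets nest, parent counts equal the sum over
#' children plus direct members by construction.
#'
#' @param taxonomy A \code{Taxonomy}.
#' @param otu_of_seq Named character vector seq_id -> OTU (tree leaf) id.
#' @param assignments Named character vector seq_id -> habitat path.
#' @param multiplicity Optional named numeric weights per seq_id (default 1).
#' @return data.frame: taxon, habitat, count.
#' @export
cladeFrequencyTable <- function(taxonomy, otu_of_seq, assignments,
                                multiplicity = NULL) {
  tx <- taxaTable(taxonomy)
  ids <- intersect(names(otu_of_seq), names(assignments))
  if (is.null(multiplicity))
    multiplicity <- stats::setNames(rep(1, length(ids)), ids)
  out <- list()
  for (i in seq_len(nrow(tx))) {
    inTaxon <- ids[otu_of_seq[ids] %in% tx$members[[i]]]
    if (length(inTaxon) == 0) next
    cnt <- tapply(multiplicity[inTaxon], assignments[inTaxon], sum)
    out[[length(out) + 1L]] <- data.frame(taxon = tx$name[i],
                                          habitat = names(cnt),
                                          count = as.numeric(cnt))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(taxon = character(0), habitat = character(0),
               count = numeric(0))
  rownames(res) <- NULL
  res
}

#' Fraction of a lineage found in a habitat
#'
#' @param table Output of \code{\link{cladeFrequencyTable}}.
#' @param taxon Taxon name.
#' @param habitat Habitat path (counted with all its descendants).
#' @return Fraction of the taxon's annotated sequences in that habitat.
#' @export
habitatFraction <- function(table, taxon, habitat) {
  sub <- table[table$taxon == taxon, , drop = FALSE]
  if (nrow(sub) == 0) return(NA_real_)
  inH <- sub$habitat == habitat | startsWith(sub$habitat, paste0(habitat, "/"))
  sum(sub$count[inH]) / sum(sub$count)
}

#' Krona-style hierarchical text export
#'
#' One row per leaf path: count, then the path components, tab-separated
#' with a header. \code{readKrona} reproduces the aggregated counts.
#'
#' @param counts data.frame with columns \code{habitat} (path) and
#'   \code{count} (e.g. one taxon's rows of \code{cladeFrequencyTable}).
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
exportKrona <- function(counts, file) {
  if (nrow(counts) == 0) {
    writeLines("count\tlevel1", file)
    return(invisible(file))
  }
  agg <- stats::aggregate(count ~ habitat, data = counts, FUN = sum)
  parts <- strsplit(agg$habitat, "/", fixed = TRUE)
  depth <- max(c(1L, lengths(parts)))
  lines <- vapply(seq_len(nrow(agg)), function(i) {
    p <- c(parts[[i]], rep("", depth - length(parts[[i]])))
    paste(c(format(agg$count[i], scientific = FALSE, trim = TRUE), p),
          collapse = "\t")
  }, character(1))
  header <- paste(c("count", paste0("level", seq_len(depth))), collapse = "\t")
  writeLines(c(header, lines), file)
  invisible(file)
}

#' @rdname exportKrona
#' @export
readKrona <- function(file) {
  lines <- readLines(file)
  if (length(lines) <= 1)
    return(data.frame(habitat = character(0), count = numeric(0)))
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  data.frame(
    habitat = vapply(parts, function(p)
      paste(p[-1][nzchar(p[-1])], collapse = "/"), character(1)),
    count = vapply(parts, function(p) as.numeric(p[1]), numeric(1)))
}
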