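#' Read a rooted tree topology
#'
#' Thin wrapper around \pkg{ape}'s Newick/NEXUS readers that additionally
#' checks balanced parentheses (reporting the character offset of the first
#' imbalance) and rejects duplicate tip labels.  Polytomies are preserved:
#' composite trees assembled from multiple source phylogenies are typically
#' unresolved in places and must be usable as-is.
#'
#' @param path path to a Newick (\code{.nwk}, \code{.tre}) or NEXUS
#'   (\code{.nex}) file.
#' @param format \code{"newick"} or \code{"nexus"}; guessed from the file
#'   extension by default.
#' @return an \pkg{ape} \code{phylo} object.
#' @export
read_tree <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.nex(us)?$", path, ignore.case = TRUE))
      "nexus" else "newick"
  if (format == "newick") {
    txt <- paste(readLines(path, warn = FALSE), collapse = "")
    .check_parens(txt)
    phy <- ape::read.tree(text = txt)
  } else {
    phy <- ape::read.nexus(path)
  }
  if (is.null(phy)) stop("could not parse tree in ", path, call. = FALSE)
  dup <- phy$tip.label[duplicated(phy$tip.label)]
  if (length(dup))
    stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  phy
}

.check_parens <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("unbalanced parenthesis at character ", i, call. = FALSE)
  }
  if (depth != 0L)
    stop("unbalanced parentheses: ", depth, " '(' unclosed at end of input",
         call. = FALSE)
  invisible(TRUE)
}

#' Write a tree to Newick
#'
#' @param phy a \code{phylo} object.
#' @param path output path.
#' @export
write_tree <- function(phy, path) {
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read tip occurrence ages
#'
#' Side table giving, for every tip, its first and last occurrence in Ma
#' before present (larger = older).  Extant tips have first = last = 0.
#'
#' @param path CSV with columns \code{taxon}, \code{first_occurrence},
#'   \code{last_occurrence}.
#' @return data frame with one row per taxon.
#' @export
read_tip_ages <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("taxon", "first_occurrence", "last_occurrence"),
                 "tip age table")
  df <- .as_num(df, c("first_occurrence", "last_occurrence"),
                "tip age table")
  bad <- df$first_occurrence < df$last_occurrence
  if (any(bad))
    stop("tip age table: first_occurrence < last_occurrence for ",
         paste(df$taxon[bad], collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$taxon))
    stop("tip age table: duplicated taxon", call. = FALSE)
  df
}

#' Read node-age calibration constraints
#'
#' @param path CSV with columns \code{mrca_of} (tip labels separated by
#'   \code{";"}), \code{age} (Ma) and \code{kind} (\code{fixed} or
#'   \code{minimum}).
#' @return data frame of constraints; \code{mrca_of} is a list column of
#'   character vectors.
#' @export
read_constraints <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("mrca_of", "age", "kind"), "constraint table")
  df <- .as_num(df, "age", "constraint table")
  if (any(df$age <= 0))
    stop("constraint table: ages must be > 0", call. = FALSE)
  bad <- setdiff(unique(df$kind), c("fixed", "minimum"))
  if (length(bad))
    stop("constraint table: unknown kind ", paste(bad, collapse = ", "),
         call. = FALSE)
  df$mrca_of <- lapply(strsplit(df$mrca_of, ";"), trimws)
  if (any(lengths(df$mrca_of) == 0))
    stop("constraint table: empty mrca_of", call. = FALSE)
  df
}

#' Node ages of a dated tree
#'
#' @param phy a \code{dated_phylo} as returned by [calibrate_tree()] or
#'   [simulate_yule_tree()].
#' @return numeric vector of ages (Ma, larger = older), indexed by node
#'   number (tips first, then internal nodes).
#' @export
node_ages <- function(phy) {
  if (is.null(phy$node.age))
    stop("tree is not dated: run calibrate_tree() first", call. = FALSE)
  phy$node.age
}

#' Branch durations of a dated tree
#'
#' Duration of every branch as parent age minus child age; for fossil tips
#' the child age is the first occurrence, so ghost lineages (the gap
#' between a divergence and the oldest fossil of the lineage) fall out of
#' the arithmetic automatically.
#'
#' @param phy a \code{dated_phylo}.
#' @return data frame with parent and child node numbers, the child label
#'   (tip label or node number) and the duration in Ma.
#' @export
branch_durations <- function(phy) {
  age <- node_ages(phy)
  ntip <- ape::Ntip(phy)
  child <- phy$edge[, 2]
  lab <- ifelse(child <= ntip, phy$tip.label[child], as.character(child))
  data.frame(parent = phy$edge[, 1], child = child, child_label = lab,
             duration = age[phy$edge[, 1]] - age[child])
}

## internal: attach ages, refresh edge lengths, and enforce parent > child
.as_dated <- function(phy, age, strict = TRUE) {
  dur <- age[phy$edge[, 1]] - age[phy$edge[, 2]]
  if (strict && any(dur <= 0)) {
    bad <- which(dur <= 0)[1]
    stop(sprintf(
      "calibration conflict: node %d (%.4g Ma) is not older than child %s (%.4g Ma)",
      phy$edge[bad, 1], age[phy$edge[bad, 1]],
      if (phy$edge[bad, 2] <= ape::Ntip(phy))
        phy$tip.label[phy$edge[bad, 2]] else as.character(phy$edge[bad, 2]),
      age[phy$edge[bad, 2]]), call. = FALSE)
  }
  phy$edge.length <- dur
  phy$node.age <- age
  class(phy) <- unique(c("dated_phylo", class(phy)))
  phy
}
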