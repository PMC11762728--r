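#' Read a time-calibrated chronogram from a Newick file
#'
#' Parses a single rooted Newick tree with branch lengths (interpreted as
#' million years) and validates it as a chronogram: unique tip labels,
#' strictly positive branch lengths, and ultrametricity within a relative
#' tolerance. Trees that fail the ultrametricity check are still returned,
#' flagged via `attr(tree, "ultrametric") == FALSE`, since dated trees from
#' ML pipelines routinely carry rounding error.
#'
#' @param path Path to a Newick file containing one rooted tree.
#' @param ultra_tol Relative ultrametricity tolerance: the spread of tip
#'   depths may not exceed `ultra_tol` times the root depth. Default `1e-6`.
#' @return An object of class `c("chronogram", "phylo")`, with attributes
#'   `ultrametric` (logical) and `depth` (root depth, Ma).
#' @seealso [write_chronogram()], [stem_age()], [prune_to_taxa()]
#' @export
read_chronogram <- function(path, ultra_tol = 1e-6) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  .check_newick_syntax(txt)
  tree <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop("Newick parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: no tree could be read from '",
                          path, "'", call. = FALSE)
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L)
      stop("expected exactly one tree, found ", length(tree))
    tree <- tree[[1L]]
  }
  as_chronogram(tree, ultra_tol = ultra_tol)
}

# Balanced-parenthesis pre-check so malformed input fails with a character
# offset rather than an opaque parser message.
.check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character offset ", i,
             call. = FALSE)
    }
  }
  if (depth > 0L)
    stop("malformed Newick: ", depth, " unclosed '(' (string ends at offset ",
         length(chars), ")", call. = FALSE)
  if (!grepl(";", txt, fixed = TRUE))
    stop("malformed Newick: missing terminating ';' at character offset ",
         nchar(txt), call. = FALSE)
  invisible(TRUE)
}

#' Validate an ape phylo object as a chronogram
#'
#' @param tree An [ape::read.tree()] style `phylo` object with branch lengths.
#' @inheritParams read_chronogram
#' @return The tree with class `chronogram` prepended and validation
#'   attributes set (see [read_chronogram()]).
#' @export
as_chronogram <- function(tree, ultra_tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("chronogram requires branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("tip labels are not unique: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (any(tree$edge.length <= 0))
    stop("all branch lengths must be > 0; found ",
         sum(tree$edge.length <= 0), " zero/negative edge(s)")
  depths <- node_depths(tree)
  root_depth <- max(depths)
  tip_depth_spread <- diff(range(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]))
  ultra <- tip_depth_spread <= ultra_tol * root_depth
  if (!ultra)
    warning("tree is not ultrametric within tolerance (tip depth spread ",
            signif(tip_depth_spread, 4), " vs root depth ",
            signif(root_depth, 4), "); flagged, not fatal", call. = FALSE)
  class(tree) <- unique(c("chronogram", class(tree)))
  attr(tree, "ultrametric") <- ultra
  attr(tree, "depth") <- root_depth
  tree
}

#' Write a chronogram to Newick
#'
#' @param tree A `phylo`/`chronogram` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chronogram <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Node depths (Ma before present)
#'
#' Depth of every node, computed as the maximum node-to-descendant-tip path
#' length. On an ultrametric tree this is the usual node age; on a
#' non-ultrametric tree it is the depth of the deepest descendant path.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Numeric vector of length `Ntip + Nnode`, indexed by ape node
#'   number (tips first).
#' @export
node_depths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n_all <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(n_all)  # tips stay at 0
  # postorder: children before parents
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    par <- po$edge[i, 1L]; chi <- po$edge[i, 2L]
    cand <- depth[chi] + po$edge.length[i]
    if (cand > depth[par]) depth[par] <- cand
  }
  depth
}

#' Stem age of genus tips
#'
#' The stem age of a tip is the depth (Ma before present) of its parent
#' node: the time since the genus diverged from its sister lineage.
#'
#' @param tree A `chronogram`/`phylo` object.
#' @param tips Character vector of tip labels; default all tips.
#' @return Named numeric vector of stem ages (Ma).
#' @export
stem_age <- function(tree, tips = tree$tip.label) {
  stopifnot(inherits(tree, "phylo"))
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx))
    stop("unknown tip(s): ", paste(tips[is.na(idx)], collapse = ", "))
  depths <- node_depths(tree)
  parent <- tree$edge[match(idx, tree$edge[, 2L]), 1L]
  stats::setNames(depths[parent], tips)
}

#' Prune a chronogram to a set of genus names
#'
#' Matches the supplied genus names against the tree tips after synonym
#' substitution and whitespace/case normalization, prunes the tree to the
#' matched tips (degree-2 nodes suppressed, branch lengths summed), and
#' returns an auditable match report. Matching is exact by design: fuzzy
#' matching would make the report untrustworthy.
#'
#' @param tree A `chronogram`/`phylo` object.
#' @param names Character vector of genus names to retain (non-empty).
#' @param synonyms Optional named character vector or two-column data frame
#'   (`from_name`, `to_name`) mapping dataset names to tree tip names.
#' @return A list with elements `tree` (pruned chronogram) and `report`
#'   (a `taxon_match_report`: data frame of `name`, `matched_tip`, `status`
#'   in `matched`/`unmatched`/`synonym`).
#' @export
prune_to_taxa <- function(tree, names, synonyms = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length(names) == 0L) stop("'names' must be non-empty")
  syn_map <- .as_synonym_map(synonyms)
  norm <- function(x) tolower(gsub("\\s+", "", x))
  tip_norm <- norm(tree$tip.label)

  resolved <- names
  used_syn <- rep(FALSE, length(names))
  if (length(syn_map)) {
    hit <- match(norm(names), norm(names(syn_map)))
    used_syn <- !is.na(hit)
    resolved[used_syn] <- syn_map[hit[used_syn]]
  }
  tip_idx <- match(norm(resolved), tip_norm)
  matched <- !is.na(tip_idx)
  if (!any(matched)) stop("no supplied genus names match the tree tips")

  report <- data.frame(
    name = names,
    matched_tip = ifelse(matched, tree$tip.label[tip_idx], NA_character_),
    status = ifelse(!matched, "unmatched",
                    ifelse(used_syn, "synonym", "matched")),
    stringsAsFactors = FALSE
  )
  class(report) <- c("taxon_match_report", class(report))

  keep <- unique(tree$tip.label[tip_idx[matched]])
  pruned <- ape::keep.tip(tree, keep)
  pruned <- as_chronogram(pruned)
  list(tree = pruned, report = report)
}

.as_synonym_map <- function(synonyms) {
  if (is.null(synonyms)) return(character(0))
  if (is.data.frame(synonyms)) {
    if (ncol(synonyms) < 2L)
      stop("synonym table needs two columns (from_name, to_name)")
    return(stats::setNames(as.character(synonyms[[2L]]),
                           as.character(synonyms[[1L]])))
  }
  if (is.character(synonyms) && !is.null(names(synonyms))) return(synonyms)
  stop("'synonyms' must be a named character vector or a 2-column data frame")
}

#' Read a synonym map from CSV
#'
#' @param path CSV with columns `from_name,to_name`.
#' @return Named character vector mapping dataset names to tip names.
#' @export
read_synonym_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .as_synonym_map(df[, c("from_name", "to_name")])
}

#' @export
print.taxon_match_report <- function(x, ...) {
  cat("Taxon match report:", sum(x$status != "unmatched"), "matched (",
      sum(x$status == "synonym"), "via synonyms ),",
      sum(x$status == "unmatched"), "unmatched\n")
  if (any(x$status == "unmatched"))
    cat("  unmatched:", paste(x$name[x$status == "unmatched"],
                              collapse = ", "), "\n")
  invisible(x)
}
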