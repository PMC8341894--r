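#' @title Tree and regime-painting input/output
#' @name treeio
#' @description
#' Trees are `ape::phylo` objects; regime-painted trees are `phytools`-style
#' `simmap` objects, i.e. a `phylo` with a per-edge `maps` list of named
#' durations (names are regime states, order is rootward to tipward).
#' Every function here enforces the conventions the model-fitting code
#' assumes: rooted binary topology, branch lengths present and non-negative,
#' unique tip labels, and per-edge segment durations that sum to the edge
#' length.
NULL

#' Validate a phylogeny
#'
#' Checks the structural invariants assumed throughout the package: exactly
#' one root, binary topology (polytomies are rejected; the OU weight algebra
#' assumes binary merges), branch lengths present and non-negative, and
#' unique tip labels.
#'
#' @param tree an `ape::phylo` object.
#' @return `tree`, invisibly, if valid; otherwise an error.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (!ape::is.rooted(tree)) stop("tree is not rooted")
  if (!ape::is.binary(tree)) stop("tree contains polytomies; resolve before use")
  invisible(tree)
}

#' Parse a newick string into a validated phylogeny
#'
#' @param text a newick string; all non-root edges must carry branch lengths.
#' @return a validated `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2):0;")
#' node_depths(tr)
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("newick parse error: unbalanced parentheses in ",
                          substr(text, 1, 60))
  validate_tree(tree)
  tree
}

#' Serialize a phylogeny to newick
#'
#' @param tree a `phylo`.
#' @return a newick string.
#' @export
write_newick <- function(tree) {
  validate_tree(tree)
  ape::write.tree(tree)
}

#' Node depths measured from the root
#'
#' @param tree a `phylo`.
#' @return numeric vector over all nodes (tips first, then internal nodes)
#'   of the distance from the root, in the tree's time units.
#' @export
node_depths <- function(tree) {
  n <- length(tree$tip.label)
  depth <- numeric(n + tree$Nnode)
  # preorder: parents visited before children
  ord <- reorder(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    depth[ord$edge[i, 2]] <- depth[ord$edge[i, 1]] + ord$edge.length[i]
  }
  depth
}

#' Test whether a tree is ultrametric within a relative tolerance
#'
#' @param tree a `phylo`.
#' @param tol relative tolerance on root-to-tip depth spread.
#' @return list with elements `ultrametric` (logical) and `max_deviation`
#'   (largest pairwise depth difference divided by the maximum depth).
#' @export
check_ultrametric <- function(tree, tol = 1e-8) {
  validate_tree(tree)
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  dev <- if (max(d) > 0) (max(d) - min(d)) / max(d) else 0
  list(ultrametric = dev <= tol, max_deviation = dev)
}

## ---- regime paintings (simmap objects) -------------------------------------

#' Construct a regime-painted tree from per-edge segment maps
#'
#' @param tree a validated `phylo`.
#' @param maps list, one element per edge (rows of `tree$edge`), each a named
#'   numeric vector of segment durations in rootward-to-tipward order, names
#'   being regime states.
#' @param alphabet optional character vector of allowed states.
#' @return a `simmap` object (classes `simmap`, `phylo`).
#' @export
make_painting <- function(tree, maps, alphabet = NULL) {
  validate_tree(tree)
  if (length(maps) != nrow(tree$edge))
    stop("maps must have one element per edge")
  tree$maps <- maps
  states <- sort(unique(unlist(lapply(maps, names))))
  if (!is.null(alphabet)) {
    bad <- setdiff(states, alphabet)
    if (length(bad))
      stop("unknown state symbol(s): ", paste(bad, collapse = ", "))
    states <- alphabet
  }
  tree$mapped.edge <- mapped_edge(maps, states, tree)
  class(tree) <- c("simmap", "phylo")
  validate_painting(tree, alphabet = states)
  tree
}

mapped_edge <- function(maps, states, tree) {
  me <- matrix(0, nrow(tree$edge), length(states),
               dimnames = list(apply(tree$edge, 1, paste, collapse = ","),
                               states))
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    for (s in unique(names(m))) me[i, s] <- sum(m[names(m) == s])
  }
  me
}

#' Validate a regime-painted tree
#'
#' Checks that per-edge segment durations sum to the edge length (relative
#' tolerance `tol`), that segment states come from `alphabet` when given,
#' and that the underlying tree is valid.
#'
#' @param pt a `simmap` object.
#' @param alphabet optional allowed state set.
#' @param tol relative tolerance on segment sums.
#' @return `pt`, invisibly.
#' @export
validate_painting <- function(pt, alphabet = NULL, tol = 1e-9) {
  if (!inherits(pt, "phylo") || is.null(pt$maps))
    stop("not a regime-painted tree (no 'maps' element)")
  validate_tree(structure(pt[names(pt) != "maps"], class = "phylo"))
  if (!is.null(alphabet)) {
    bad <- setdiff(unique(unlist(lapply(pt$maps, names))), alphabet)
    if (length(bad))
      stop("unknown state symbol(s): ", paste(bad, collapse = ", "))
  }
  sums <- vapply(pt$maps, sum, 0)
  scale <- pmax(pt$edge.length, max(pt$edge.length))
  off <- abs(sums - pt$edge.length) / ifelse(scale > 0, scale, 1)
  if (any(off > tol))
    stop("segment durations do not sum to edge length on edge(s) ",
         paste(which(off > tol), collapse = ", "))
  invisible(pt)
}

#' Parse a brace-annotated simmap newick string
#'
#' The dialect annotates every branch as `{state,dur:state,dur:...}` with
#' segments in rootward-to-tipward order (the orientation used throughout
#' this package).
#'
#' @param text a simmap newick string.
#' @param alphabet optional allowed state set; unknown symbols are an error.
#' @return a validated `simmap` object.
#' @examples
#' pt <- parse_simmap("(A:{bi,1.0},B:{bi,0.5:zp,0.5}):0;")
#' time_in_state(pt)
#' @export
parse_simmap <- function(text, alphabet = NULL) {
  # tolerate (and drop) a plain un-annotated root branch length, ")...:0;"
  text <- sub("\\)\\s*:\\s*[0-9eE.+-]+\\s*;\\s*$", ");", text)
  pt <- tryCatch(
    phytools::read.simmap(text = text, format = "phylip",
                          rev.order = FALSE, version = 1),
    error = function(e) stop("simmap parse error: ", conditionMessage(e)))
  class(pt) <- c("simmap", "phylo")
  validate_painting(pt, alphabet = alphabet)
  pt
}

#' Serialize a regime-painted tree to the brace-annotated simmap dialect
#'
#' Output is canonical: children are ordered by the lexicographically
#' smallest tip label in their subtree, segments are printed rootward to
#' tipward, and durations use 17 significant digits so that
#' parse-and-rewrite is bit-identical.
#'
#' @param pt a validated `simmap` object.
#' @return a single simmap newick string.
#' @export
write_simmap_text <- function(pt) {
  validate_painting(pt)
  n <- length(pt$tip.label)
  root <- n + 1L
  kids <- split(seq_len(nrow(pt$edge)), pt$edge[, 1])
  min_label <- character(n + pt$Nnode)
  po <- rev(reorder(pt, "cladewise")$edge[, 2])  # postorder-ish node sweep
  min_label[seq_len(n)] <- pt$tip.label
  for (v in po) if (v > n) {
    ch <- pt$edge[kids[[as.character(v)]], 2]
    min_label[v] <- min(min_label[ch])
  }
  ch <- pt$edge[kids[[as.character(root)]], 2]
  min_label[root] <- min(min_label[ch])
  brace <- function(m)
    paste0("{", paste(sprintf("%s,%.17g", names(m), m), collapse = ":"), "}")
  rec <- function(v) {
    e <- kids[[as.character(v)]]
    if (is.null(e)) return(pt$tip.label[v])
    e <- e[order(min_label[pt$edge[e, 2]])]
    inner <- vapply(pt$edge[e, 2], rec, "")
    paste0("(", paste0(inner, ":",
                       vapply(pt$maps[e], brace, ""), collapse = ","), ")")
  }
  paste0(rec(root), ":0;")
}

#' Total time spent in each regime over a painted tree
#'
#' @param pt a `simmap` object.
#' @return named numeric vector of summed segment durations per state.
#' @export
time_in_state <- function(pt) {
  validate_painting(pt)
  colSums(pt$mapped.edge)
}

#' Count regime transitions on a painted tree
#'
#' Transitions occur at segment boundaries within branches; passing through a
#' node does not change state.
#'
#' @param pt a `simmap` object.
#' @return k x k matrix of ordered transition counts (from row to column).
#' @export
count_transitions <- function(pt) {
  states <- colnames(pt$mapped.edge)
  k <- length(states)
  cnt <- matrix(0L, k, k, dimnames = list(states, states))
  for (m in pt$maps) {
    s <- names(m)
    if (length(s) > 1)
      for (i in seq_len(length(s) - 1))
        cnt[s[i], s[i + 1]] <- cnt[s[i], s[i + 1]] + 1L
  }
  cnt
}

#' Regime at each node of a painted tree
#'
#' The state at a node is the rootward state of its child edges (equivalently
#' the tipward state of its parent edge); the root takes the rootmost segment
#' state of its child edges.
#'
#' @param pt a `simmap` object.
#' @return character vector over all nodes (tips then internals).
#' @export
painting_node_states <- function(pt) {
  n <- length(pt$tip.label)
  st <- character(n + pt$Nnode)
  for (i in seq_len(nrow(pt$edge))) {
    m <- pt$maps[[i]]
    st[pt$edge[i, 2]] <- names(m)[length(m)]
    v <- pt$edge[i, 1]
    if (st[v] == "") st[v] <- names(m)[1]
  }
  st
}

#' Observed tip states of a painted tree
#'
#' @param pt a `simmap` object.
#' @return named character vector (names are tip labels).
#' @export
painting_tip_states <- function(pt) {
  st <- painting_node_states(pt)
  stats::setNames(st[seq_along(pt$tip.label)], pt$tip.label)
}

#' Read a species-to-regime table
#'
#' @param path CSV file with columns `species` and `regime`.
#' @return named character vector of regimes, names being species.
#' @export
read_states_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "regime") %in% names(d)))
    stop("states CSV must have columns 'species' and 'regime'")
  if (anyDuplicated(d$species)) stop("duplicated species in states CSV")
  stats::setNames(as.character(d$regime), d$species)
}

#' Prune a tree to the species present in a data table
#'
#' @param tree a `phylo`.
#' @param species character vector of species to keep.
#' @return the pruned, validated tree; a message reports dropped tips.
#' @export
prune_to_species <- function(tree, species) {
  drop <- setdiff(tree$tip.label, species)
  miss <- setdiff(species, tree$tip.label)
  if (length(miss))
    stop("species absent from tree: ", paste(miss, collapse = ", "))
  if (length(drop)) {
    message("pruning ", length(drop), " tip(s) absent from trait table")
    tree <- ape::drop.tip(tree, drop)
  }
  validate_tree(tree)
  tree
}
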