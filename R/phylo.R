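#' @importFrom stats optim optimize pnorm qchisq qnorm rbinom rexp rnorm runif sd setNames uniroot dnorm
#' @importFrom utils head read.delim write.table
NULL

#' Parse a rooted Newick string into a validated phylogeny
#'
#' Wraps [ape::read.tree()] and enforces the invariants the rest of the
#' package relies on: a single root, unique leaf labels, and finite,
#' non-negative branch lengths.  Zero-length branches are permitted (their
#' transition matrix is the identity).
#'
#' @param text A single Newick string describing a rooted tree with branch
#'   lengths.
#' @return An object of class `"phylo"` (see \pkg{ape}).
#' @examples
#' tr <- parse_newick("((A:1,B:1):2,C:3);")
#' ape::Ntip(tr)   # 3
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed Newick string")
  }
  validate_phylogeny(tree)
  tree
}

#' Validate a phylogeny object
#'
#' @param tree A `"phylo"` object.
#' @param require_lengths Require branch lengths to be present.
#' @return The tree, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_phylogeny <- function(tree, require_lengths = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  if (require_lengths) {
    if (is.null(tree$edge.length)) stop("branch lengths are required")
    if (any(!is.finite(tree$edge.length))) stop("non-finite branch length")
    if (any(tree$edge.length < 0)) stop("negative branch length")
  }
  ## exactly one root: one node that never appears as a child
  children <- tree$edge[, 2]
  parents <- unique(tree$edge[, 1])
  roots <- setdiff(parents, children)
  if (length(roots) != 1L) stop("tree must have exactly one root")
  if (anyDuplicated(children)) stop("a node has more than one parent")
  invisible(tree)
}

#' Serialize a phylogeny to Newick
#'
#' @param tree A `"phylo"` object.
#' @return A Newick string with full-precision branch lengths.
#' @export
write_newick <- function(tree) {
  validate_phylogeny(tree)
  ape::write.tree(tree, digits = 12)
}

root_node <- function(tree) ape::Ntip(tree) + 1L

#' Label branches by lineage class
#'
#' Assigns a class label to every branch of the tree: branches inside the
#' clade spanned by `leaves` (terminal and internal branches and, by
#' default, the clade's stem branch) receive `label`; every other branch
#' receives `default`.  Lineage rate heterogeneity is expressed through this
#' map: each class gets its own rate set under a shared model form, the
#' approach familiar from lineage-specific birth-death analyses such as
#' CAFE's.
#'
#' @param tree A `"phylo"` object.
#' @param leaves Character vector of tip labels forming a monophyletic
#'   group.
#' @param label Class label for the clade (canonically `"Hominini"`).
#' @param default Class label for all remaining branches (canonically
#'   `"OWM"`).
#' @param include_stem Include the clade's stem branch (the branch leading
#'   to the clade's MRCA) in `label`.  Default `TRUE`: a rate shift is
#'   modeled from the clade's origin.
#' @return A branch class map: character vector of length `Nedge(tree)`,
#'   ordered as `tree$edge`, named by the child node id of each branch.
#' @examples
#' tr <- parse_newick("((H:6,C:6):24,M:30);")
#' assign_clade_class(tr, c("H", "C"), "Hominini", "OWM")
#' @export
assign_clade_class <- function(tree, leaves, label, default,
                               include_stem = TRUE) {
  validate_phylogeny(tree)
  if (!all(leaves %in% tree$tip.label)) stop("leaves not in tree")
  tips <- match(leaves, tree$tip.label)
  if (length(tips) < ape::Ntip(tree)) {
    if (!ape::is.monophyletic(tree, leaves)) stop("leaves are not monophyletic")
  }
  classes <- rep(default, nrow(tree$edge))
  if (length(tips) == ape::Ntip(tree)) {
    classes[] <- label
  } else {
    mrca <- if (length(tips) == 1L) tips else ape::getMRCA(tree, tips)
    desc <- clade_nodes(tree, mrca)
    in_clade <- tree$edge[, 2] %in% desc
    if (include_stem) in_clade <- in_clade | tree$edge[, 2] == mrca
    classes[in_clade] <- label
  }
  names(classes) <- tree$edge[, 2]
  classes
}

## all nodes strictly below `node` (children, grandchildren, ...)
clade_nodes <- function(tree, node) {
  out <- integer(0)
  stack <- tree$edge[tree$edge[, 1] == node, 2]
  while (length(stack)) {
    out <- c(out, stack)
    stack <- tree$edge[tree$edge[, 1] %in% stack, 2]
  }
  out
}

#' Uniform branch class map
#'
#' @param tree A `"phylo"` object.
#' @param label Class applied to every branch.
#' @return A branch class map (see [assign_clade_class()]).
#' @export
uniform_classes <- function(tree, label = "all") {
  validate_phylogeny(tree)
  setNames(rep(label, nrow(tree$edge)), tree$edge[, 2])
}

#' Convert branch lengths from millions of years to millions of generations
#'
#' Rates in this package default to "per My"; when an analysis is run per
#' generation instead, branch lengths are rescaled by an assumed generation
#' time (five years for all primates in the motivating study).  A branch of
#' 6 My at 5 years/generation becomes 1.2 million generations.
#'
#' @param tree A `"phylo"` object with branch lengths in My.
#' @param generation_time Generation time in years (> 0).
#' @return The tree with branch lengths in millions of generations.
#' @export
convert_time_units <- function(tree, generation_time) {
  validate_phylogeny(tree)
  if (!is.numeric(generation_time) || length(generation_time) != 1L ||
      !is.finite(generation_time) || generation_time <= 0) {
    stop("generation time must be a positive number")
  }
  tree$edge.length <- tree$edge.length / generation_time
  tree
}

#' Build an ultrametric tree from a topology and node-age calibrations
#'
#' Node ages for calibrated clades are honored exactly; leaves sit at age
#' 0.  Uncalibrated internal nodes are assigned ages by proportional-depth
#' interpolation: along the path from the nearest calibrated ancestor down
#' to the oldest constrained descendant, uncalibrated nodes are spaced
#' evenly in age.  The rule is deterministic, so a fixture tree is fully
#' reproducible.
#'
#' @param topology A `"phylo"` object or Newick string; branch lengths, if
#'   present, are ignored.
#' @param calibrations A list of calibrations, each a list with elements
#'   `leaves` (character vector identifying the clade by its tip set) and
#'   `age` (node age in My, > 0).  The root must be calibrated.
#' @return An ultrametric `"phylo"` object whose calibrated node ages equal
#'   the calibrations exactly.
#' @examples
#' tr <- build_calibrated_tree("((H,C),M);",
#'   list(list(leaves = c("H", "C"), age = 6),
#'        list(leaves = c("H", "C", "M"), age = 30)))
#' @export
build_calibrated_tree <- function(topology, calibrations) {
  tree <- if (is.character(topology)) {
    t0 <- tryCatch(suppressWarnings(ape::read.tree(text = topology)),
                   error = function(e) NULL)
    if (is.null(t0)) stop("malformed Newick topology")
    t0
  } else topology
  if (!inherits(tree, "phylo")) stop("topology must be a phylo or Newick string")
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  age <- rep(NA_real_, nnode)
  age[seq_len(ntip)] <- 0
  for (cal in calibrations) {
    if (is.null(cal$leaves) || is.null(cal$age)) {
      stop("each calibration needs 'leaves' and 'age'")
    }
    if (cal$age <= 0) stop("calibration ages must be positive")
    if (!all(cal$leaves %in% tree$tip.label)) stop("calibration leaves not in tree")
    tips <- match(cal$leaves, tree$tip.label)
    node <- if (length(tips) == 1L) tips else ape::getMRCA(tree, tips)
    if (node <= ntip) stop("calibrations must identify internal nodes")
    if (!is.na(age[node]) && age[node] != cal$age) {
      stop("conflicting calibrations for one node")
    }
    age[node] <- cal$age
  }
  root <- root_node(tree)
  if (is.na(age[root])) stop("the root must be calibrated")
  parent_of <- integer(nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  ## check calibration consistency before interpolating
  for (v in which(!is.na(age))) {
    if (v == root) next
    a <- parent_of[v]
    while (a != 0L && is.na(age[a])) a <- if (a == root) 0L else parent_of[a]
    if (a != 0L && age[a] <= age[v] && v > ntip) {
      stop("inconsistent ages: child clade older than (or equal to) parent")
    }
    if (a != 0L && age[a] < age[v]) stop("inconsistent ages: child older than parent")
  }
  ## preorder assignment with even interpolation along maximal-age paths
  children_of <- split(tree$edge[, 2], tree$edge[, 1])
  preorder <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    preorder <- c(preorder, v)
    kids <- children_of[[as.character(v)]]
    if (!is.null(kids)) stack <- c(kids, stack)
  }
  ## deepest constrained age below an uncalibrated node, and the number of
  ## consecutive uncalibrated nodes from it down to that constraint
  max_desc <- function(v) {
    if (!is.na(age[v])) return(c(age[v], 0L))
    kids <- children_of[[as.character(v)]]
    best <- c(-Inf, 0L)
    for (k in kids) {
      r <- max_desc(k)
      if (r[1] > best[1]) best <- r
    }
    c(best[1], best[2] + 1L)
  }
  for (v in preorder) {
    if (!is.na(age[v])) next
    a <- parent_of[v]  # already assigned (preorder)
    r <- max_desc(v)
    d <- r[1]; m <- r[2]  # m uncalibrated nodes between age[a] and d, v first
    age[v] <- age[a] - (age[a] - d) / (m + 1)
  }
  tree$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  if (any(tree$edge.length < 0)) stop("inconsistent ages produced a negative branch")
  validate_phylogeny(tree)
  tree
}

#' Node ages of an ultrametric tree
#'
#' @param tree An ultrametric `"phylo"` object.
#' @return Numeric vector of ages (time before present) indexed by node id.
#' @export
node_ages <- function(tree) {
  validate_phylogeny(tree)
  nnode <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(nnode)
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in rev(seq_len(nrow(ord$edge)))) {  # preorder over edges
    depth[ord$edge[e, 2]] <- depth[ord$edge[e, 1]] + ord$edge.length[e]
  }
  max(depth) - depth
}

#' Write a branch class map as TSV
#'
#' Two columns: `branch` (the child node's tip label, or `node<id>` for
#' internal nodes) and `class`.
#'
#' @param classes A branch class map (see [assign_clade_class()]).
#' @param tree The tree the map belongs to.
#' @param path Output file path.
#' @export
write_branch_classes <- function(classes, tree, path) {
  child <- as.integer(names(classes))
  lab <- ifelse(child <= ape::Ntip(tree), tree$tip.label[child],
                paste0("node", child))
  write.table(data.frame(branch = lab, class = unname(classes)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
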