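#' Mutation-annotated rooted trees
#'
#' A `mutation_tree` is a rooted phylogeny (stored as an [ape::read.tree()]
#' `phylo` object) whose branch lengths are interpreted as *mutation counts*
#' on the whole molecule, not per-site distances.  Counts may be fractional
#' (e.g. after apportioning mutations of branches that span several
#' coalescent periods) but must be non-negative.
#'
#' @param phy an object of class `phylo` with branch lengths.
#' @return an object of class `mutation_tree`: a list with elements
#'   `phy` (the validated `phylo`) and `n_tips`.
#' @seealso [read_mutation_tree()], [decompose_periods()]
#' @export
mutation_tree <- function(phy) {
  if (!inherits(phy, "phylo"))
    stop("'phy' must be a 'phylo' object (see ape::read.tree)")
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths; mutation counts are required on every branch")
  if (anyNA(phy$edge.length))
    stop("one or more branches have missing mutation counts")
  if (any(phy$edge.length < 0))
    stop("negative branch mutation counts are not allowed: ",
         paste(signif(phy$edge.length[phy$edge.length < 0], 4), collapse = ", "))
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (length(phy$tip.label) < 2)
    stop("a mutation tree needs at least 2 tips")
  if (!is.null(phy$root.edge)) {
    warning("root branch length present in input; ignored")
    phy$root.edge <- NULL
  }
  # unifurcations carry no coalescent information; merge them into their
  # parent branch so every internal node is a genuine coalescent event
  phy <- ape::collapse.singles(phy)
  structure(list(phy = phy, n_tips = length(phy$tip.label)),
            class = "mutation_tree")
}

#' Read a Newick tree whose branch lengths are mutation counts
#'
#' @param x a file path, or a Newick string (recognised by the presence of
#'   parentheses).
#' @param per_site if `TRUE`, branch lengths are per-site distances and are
#'   converted to whole-molecule mutation counts by multiplying with
#'   `sequence_length`.
#' @param sequence_length molecule length in bases; defaults to the human
#'   mtDNA genome length ([MTDNA_LENGTH]) and is only used when
#'   `per_site = TRUE`.
#' @return a [mutation_tree()].
#' @examples
#' tr <- read_mutation_tree("((a:1,b:2):3,c:4);")
#' tr$n_tips
#' @export
read_mutation_tree <- function(x, per_site = FALSE,
                               sequence_length = MTDNA_LENGTH) {
  stopifnot(is.character(x), length(x) == 1L)
  is_text <- grepl("(", x, fixed = TRUE)
  if (!is_text && !file.exists(x))
    stop("tree file not found: ", x)
  phy <- tryCatch(
    if (is_text) ape::read.tree(text = x) else ape::read.tree(x),
    error = function(e) stop("failed to parse Newick ",
                             if (is_text) "string" else x, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(phy))
    stop("failed to parse Newick ", if (is_text) "string" else x)
  if (per_site && !is.null(phy$edge.length))
    phy$edge.length <- phy$edge.length * sequence_length
  mutation_tree(phy)
}

#' Human mtDNA genome length in base pairs
#' @export
MTDNA_LENGTH <- 16569L

#' @export
print.mutation_tree <- function(x, ...) {
  cat("Mutation-annotated rooted tree\n")
  cat("  tips:           ", x$n_tips, "\n", sep = "")
  cat("  total mutations:", sum(x$phy$edge.length), "\n")
  invisible(x)
}

# --- internal tree helpers -------------------------------------------------

# list of child node ids for every node (index = node id)
.children <- function(phy) {
  n_nodes <- max(phy$edge)
  out <- vector("list", n_nodes)
  for (k in seq_len(nrow(phy$edge)))
    out[[phy$edge[k, 1L]]] <- c(out[[phy$edge[k, 1L]]], phy$edge[k, 2L])
  out
}

# tip ids descending from every node (tips descend from themselves)
.descendant_tips <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_nodes <- max(phy$edge)
  kids <- .children(phy)
  out <- vector("list", n_nodes)
  # edges are not guaranteed post-ordered; recurse explicitly
  rec <- function(v) {
    if (!is.null(out[[v]])) return(out[[v]])
    res <- if (v <= n_tip) v else
      sort(unlist(lapply(kids[[v]], rec), use.names = FALSE))
    out[[v]] <<- res
    res
  }
  root <- setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]
  rec(root)
  out
}

# mutation-count distance from the root to every node
.node_depths <- function(phy) {
  n_nodes <- max(phy$edge)
  depth <- numeric(n_nodes)
  root <- setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]
  # breadth-first from the root
  queue <- root
  kids <- .children(phy)
  elen <- numeric(n_nodes)
  elen[phy$edge[, 2L]] <- phy$edge.length
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in kids[[v]]) {
      depth[w] <- depth[v] + elen[w]
      queue <- c(queue, w)
    }
  }
  depth
}

.root_node <- function(phy) setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]
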