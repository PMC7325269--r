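#' Coalescent-period tables
#'
#' The canonical intermediate for age estimation: one row per coalescent
#' period, indexed by the number of extant lineages `i` during the period,
#' with the total number of mutations accumulated across all lineages during
#' the period (gamma_i).  Rows are ordered from the root-adjacent period
#' (smallest `i`) to the tip period (`i = n`).  With multifurcations some
#' intermediate lineage counts are never realised and are simply absent.
#'
#' @param lineages integer vector of lineage counts (>= 2), one per period.
#' @param mutations non-negative mutation totals, same length.
#' @param source optional character vector noting how each row was obtained
#'   (`"direct"` or `"apportioned"`).
#' @return a data frame of class `period_table` with columns `period`,
#'   `lineages` and `mutations` (`period` duplicates `lineages`, the
#'   convention used when periods are labelled by their lineage count).
#' @export
period_table <- function(lineages, mutations, source = NULL) {
  lineages <- as.numeric(lineages)
  mutations <- as.numeric(mutations)
  if (length(lineages) != length(mutations))
    stop("'lineages' and 'mutations' must have the same length")
  if (length(lineages) == 0L)
    stop("a period table needs at least one period")
  if (anyNA(lineages) || anyNA(mutations))
    stop("period table contains non-numeric cells")
  if (any(lineages < 2) || any(lineages != round(lineages)))
    stop("lineage counts must be integers >= 2")
  if (any(mutations < 0))
    stop("mutation totals must be non-negative")
  if (anyDuplicated(lineages))
    stop("duplicated lineage counts: one row per period is required")
  o <- order(lineages)
  if (is.unsorted(lineages))
    message("period rows reordered by ascending lineage count")
  out <- data.frame(period = lineages[o], lineages = lineages[o],
                    mutations = mutations[o])
  if (!is.null(source)) attr(out, "source") <- source[o]
  class(out) <- c("period_table", "data.frame")
  out
}

#' Read a coalescent-period table from TSV
#'
#' Expects a header with columns `period`, `lineages` and `mutations`
#' (extra columns are ignored).  Because periods are conventionally labelled
#' by their lineage count, the `period` column must equal the `lineages`
#' column; a mismatch raises an error rather than guessing which convention
#' the file uses.
#'
#' @param path path to a tab-separated file.
#' @return a [period_table()].
#' @export
read_period_table <- function(path) {
  if (!file.exists(path)) stop("period table not found: ", path)
  raw <- tryCatch(utils::read.delim(path, check.names = FALSE),
                  error = function(e) stop("cannot read ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  need <- c("period", "lineages", "mutations")
  if (!all(need %in% names(raw)))
    stop("period table must have columns 'period', 'lineages', 'mutations'; found: ",
         paste(names(raw), collapse = ", "))
  if (nrow(raw) == 0L) stop("period table is empty: ", path)
  for (col in need)
    if (!is.numeric(raw[[col]]))
      stop("non-numeric values in column '", col, "'")
  if (any(raw$period != raw$lineages))
    stop("'period' and 'lineages' columns disagree; periods are indexed by ",
         "their lineage count, so the two columns must be identical")
  period_table(raw$lineages, raw$mutations)
}

#' Write a coalescent-period table as TSV
#'
#' @param table a [period_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_period_table <- function(table, path) {
  stopifnot(inherits(table, "period_table"))
  utils::write.table(table[, c("period", "lineages", "mutations")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.period_table <- function(x, ...) {
  cat("Coalescent-period table (", nrow(x), " periods, n = ",
      max(x$lineages), " lineages, ", sum(x$mutations),
      " mutations)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Apportion the mutations of a period-spanning branch
#'
#' A tip branch that attaches directly to a deep ancestral node (an "isolate")
#' spans several coalescent periods, and its mutations must be distributed
#' among them.  The weighting rule multiplies the branch's mutation count by
#' the number of mutations observed on the internodes (branches confined to a
#' single period) of each spanned period and divides by the total internode
#' mutations over all spanned periods.  When no internode mutations exist in
#' any spanned period the mutations are spread uniformly.
#'
#' @param branch_mutations mutation count of the spanning branch (>= 0).
#' @param spanned_periods lineage-count indices of the periods the branch
#'   spans (non-empty).
#' @param internode_gamma named numeric vector of per-period internode
#'   mutation totals; names are period indices.  Periods absent from the
#'   vector count as zero.
#' @return a data frame of class `isolate_assignment` with columns `period`
#'   and `mutations`; the `mutations` column sums exactly to
#'   `branch_mutations`.
#' @examples
#' apportion_spanning_mutations(4, c(3, 2), c(`3` = 6, `2` = 2))
#' @export
apportion_spanning_mutations <- function(branch_mutations, spanned_periods,
                                         internode_gamma = numeric()) {
  if (length(spanned_periods) == 0L)
    stop("'spanned_periods' must not be empty")
  if (branch_mutations < 0)
    stop("'branch_mutations' must be non-negative")
  w <- internode_gamma[as.character(spanned_periods)]
  w[is.na(w)] <- 0
  if (any(w < 0)) stop("internode mutation totals must be non-negative")
  total <- sum(w)
  if (total == 0) {
    message("no internode mutations in spanned periods; apportioning uniformly")
    alloc <- rep(branch_mutations / length(spanned_periods),
                 length(spanned_periods))
  } else {
    alloc <- branch_mutations * as.numeric(w) / total
  }
  # force exact conservation against floating-point drift
  if (length(alloc) > 1L)
    alloc[length(alloc)] <- branch_mutations - sum(alloc[-length(alloc)])
  out <- data.frame(period = as.numeric(spanned_periods), mutations = alloc)
  class(out) <- c("isolate_assignment", "data.frame")
  out
}

#' Decompose a mutation tree into coalescent periods
#'
#' Internal nodes (coalescent events) are totally ordered from most recent to
#' most ancient; during each period between successive events a fixed number
#' of lineages `i` is extant.  Each branch contributes its mutations to the
#' periods it lives through: branches confined to one period contribute
#' directly, while branches spanning several periods are apportioned with
#' [apportion_spanning_mutations()].
#'
#' A cladogram determines only a partial order of coalescences.  Nodes are
#' ranked, subject to the constraint that a node never precedes one of its
#' descendants, by (1) mean mutation-count distance to their descendant tips,
#' ascending; (2) number of descendant tips, ascending; (3) lexicographically
#' smallest descendant tip label.  A multifurcation with c children reduces
#' the lineage count by c - 1 in a single event, so intermediate lineage
#' counts may be skipped.
#'
#' @param tree a [mutation_tree()] (or a `phylo`, which is validated first).
#' @return a [period_table()].  The attribute `"apportioned"` records, for
#'   every period-spanning branch, the per-period allocation of its
#'   mutations.
#' @examples
#' tr <- read_mutation_tree("((((a:2,b:3):2,c:0):6,d:0):3,e:0);")
#' decompose_periods(tr)
#' @export
decompose_periods <- function(tree) {
  if (inherits(tree, "phylo")) tree <- mutation_tree(tree)
  stopifnot(inherits(tree, "mutation_tree"))
  phy <- tree$phy
  n <- tree$n_tips
  kids <- .children(phy)
  desc <- .descendant_tips(phy)
  depth <- .node_depths(phy)
  internal <- sort(unique(phy$edge[, 1L]))

  # ranking keys per internal node
  mean_tip_dist <- vapply(internal, function(v)
    mean(depth[desc[[v]]] - depth[v]), numeric(1))
  n_desc <- vapply(internal, function(v) length(desc[[v]]), numeric(1))
  min_lab <- vapply(internal, function(v)
    min(phy$tip.label[desc[[v]]]), character(1))

  # greedy topological ranking: among nodes whose internal children are all
  # ranked, pick the one with the smallest key
  rank_of <- stats::setNames(rep(NA_integer_, length(internal)), internal)
  key_order <- order(mean_tip_dist, n_desc, min_lab)
  internal_kids <- lapply(internal, function(v)
    kids[[v]][kids[[v]] > n])
  for (r in seq_along(internal)) {
    for (j in key_order) {
      v <- internal[j]
      if (!is.na(rank_of[as.character(v)])) next
      ch <- internal_kids[[j]]
      if (all(!is.na(rank_of[as.character(ch)]))) {
        rank_of[as.character(v)] <- r
        break
      }
    }
  }

  # lineage count during period r (between event r-1 and event r)
  n_children <- vapply(internal, function(v) length(kids[[v]]), numeric(1))
  ord <- internal[order(rank_of[as.character(internal)])]
  drops <- n_children[match(ord, internal)] - 1
  i_of_period <- n - cumsum(c(0, drops[-length(drops)]))  # period r = 1..K
  K <- length(ord)

  # period span of every edge: child-end rank .. parent-end rank
  child_rank <- function(v) if (v <= n) 0L else rank_of[[as.character(v)]]
  spans <- lapply(seq_len(nrow(phy$edge)), function(k) {
    rc <- child_rank(phy$edge[k, 2L])
    rp <- rank_of[[as.character(phy$edge[k, 1L])]]
    seq.int(rc + 1L, rp)
  })
  span_len <- lengths(spans)

  # direct (single-period) contributions define the internode weights
  gamma <- numeric(K)
  for (k in which(span_len == 1L))
    gamma[spans[[k]]] <- gamma[spans[[k]]] + phy$edge.length[k]
  internode_gamma <- stats::setNames(gamma, i_of_period)

  # plausibility check: a tip branch confined to one period rarely carries
  # more than ~5 mutations under a Poisson clock at this time scale
  tip_single <- span_len == 1L & phy$edge[, 2L] <= n
  if (any(tip_single & phy$edge.length > 5))
    warning("tip branch within a single coalescent period carries > 5 ",
            "mutations; check the tree or the mutation-count units")

  assignments <- list()
  for (k in which(span_len > 1L)) {
    spanned_i <- i_of_period[spans[[k]]]
    a <- suppressMessages(apportion_spanning_mutations(
      phy$edge.length[k], spanned_i, internode_gamma))
    lab <- phy$edge[k, 2L]
    name <- if (lab <= n) phy$tip.label[lab] else paste0("node_", lab)
    assignments[[name]] <- a
    gamma[spans[[k]]] <- gamma[spans[[k]]] + a$mutations
  }

  src <- rep("direct", K)
  for (a in assignments)
    src[match(a$period, i_of_period)] <- "apportioned"
  o <- order(i_of_period)
  out <- period_table(i_of_period[o], gamma[o], source = src[o])
  attr(out, "apportioned") <- assignments
  out
}
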