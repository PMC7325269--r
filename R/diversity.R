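#' Classic rho statistic
#'
#' Mean number of mutations separating the sampled sequences from their most
#' recent common ancestral type: the average over tips of the root-to-tip
#' mutation count.
#'
#' @param tree a [mutation_tree()].
#' @return a single non-negative number.
#' @examples
#' classic_rho(read_mutation_tree("((a:1,b:1):2,c:4);"))  # 10/3
#' @export
classic_rho <- function(tree) {
  stopifnot(inherits(tree, "mutation_tree"))
  depth <- .node_depths(tree$phy)
  mean(depth[seq_len(tree$n_tips)])
}

#' Mean pairwise difference (pi)
#'
#' Average number of mutations separating two sampled sequences, over all
#' unordered tip pairs.  Under the no-homoplasy assumption (every branch
#' mutation is a distinct site) the difference between two tips is the
#' mutation count along the path through their most recent common ancestor.
#' Reported per molecule; divide by the sequence length for a per-site value.
#'
#' @inheritParams classic_rho
#' @param sequence_length if supplied, the per-site value is returned.
#' @return a single non-negative number.
#' @export
pairwise_pi <- function(tree, sequence_length = NULL) {
  stopifnot(inherits(tree, "mutation_tree"))
  if (tree$n_tips < 2) stop("pi requires at least 2 tips")
  d <- ape::cophenetic.phylo(tree$phy)
  val <- mean(d[upper.tri(d)])
  if (!is.null(sequence_length)) val <- val / sequence_length
  val
}

#' Per-period rho and the modified rho statistic
#'
#' For each coalescent period, rho_i = gamma_i / i, the classic rho restricted
#' to that period.  Their sum is the modified rho statistic rho_m on which
#' time-dependent age estimation is built.
#'
#' @param table a [period_table()].
#' @return the input table with an extra `rho` column; the attribute
#'   `"rho_m"` holds the total.
#' @examples
#' tab <- period_table(c(2, 3, 4, 5), c(3, 6, 2, 5))
#' per_period_rho(tab)
#' @export
per_period_rho <- function(table) {
  stopifnot(inherits(table, "period_table"))
  table$rho <- table$mutations / table$lineages
  attr(table, "rho_m") <- sum(table$rho)
  table
}

#' Number of segregating sites
#'
#' Under the no-homoplasy assumption each branch mutation is a distinct
#' polymorphic site, so S is the total count of mutations on branches whose
#' descendant tips form a proper non-empty subset of the sample.  (A branch
#' subtending every tip would carry mutations fixed in the whole sample;
#' after dropping any root branch no such branch exists in a valid tree.)
#'
#' @inheritParams classic_rho
#' @param sequence_length if supplied, the per-site value is returned.
#' @return a non-negative count (integer when branch counts are integers).
#' @export
segregating_sites <- function(tree, sequence_length = NULL) {
  stopifnot(inherits(tree, "mutation_tree"))
  phy <- tree$phy
  n <- tree$n_tips
  desc <- .descendant_tips(phy)
  nd <- vapply(phy$edge[, 2L], function(v) length(desc[[v]]), numeric(1))
  s <- sum(phy$edge.length[nd >= 1 & nd <= n - 1])
  if (!is.null(sequence_length)) s <- s / sequence_length
  s
}

#' Diversity statistics of a mutation tree
#'
#' Convenience wrapper computing the classic rho, mean pairwise difference
#' pi, and number of segregating sites S, per molecule and (when a sequence
#' length is given) per site.
#'
#' @inheritParams classic_rho
#' @param sequence_length optional molecule length for per-site values.
#' @return an object of class `diversity_stats`.
#' @export
diversity_stats <- function(tree, sequence_length = NULL) {
  stopifnot(inherits(tree, "mutation_tree"))
  out <- list(n = tree$n_tips,
              rho = classic_rho(tree),
              pi = pairwise_pi(tree),
              s = segregating_sites(tree),
              sequence_length = sequence_length)
  if (!is.null(sequence_length)) {
    out$pi_per_site <- out$pi / sequence_length
    out$s_per_site <- out$s / sequence_length
  }
  structure(out, class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat("Diversity statistics (n =", x$n, "sequences)\n")
  cat(sprintf("  rho (mean distance to root): %.4g\n", x$rho))
  cat(sprintf("  pi  (mean pairwise diff.):   %.4g\n", x$pi))
  cat(sprintf("  S   (segregating sites):     %.4g\n", x$s))
  if (!is.null(x$sequence_length))
    cat(sprintf("  per site (L = %d): pi = %.3g, S = %.3g\n",
                x$sequence_length, x$pi_per_site, x$s_per_site))
  invisible(x)
}
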