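## phylo: in-package gene-tree construction (pairwise distances +
## neighbor-joining + nonparametric bootstrap), Fitch parsimony scoring
## with gaps as a fifth state, and rooting.

#' Pairwise distance matrix from an alignment
#'
#' Raw distances are per-pair mismatch proportions under pairwise deletion:
#' only columns where both sequences carry an unambiguous base (A/C/G/T)
#' are compared, so gaps and N never count as differences. `JC69` applies
#' the Jukes-Cantor transform `-(3/4) log(1 - (4/3) p)` and errors on
#' saturated pairs (`p >= 0.75`).
#'
#' @param aln a `locus_alignment`.
#' @param correction `"raw"` or `"JC69"`.
#' @return symmetric numeric matrix with zero diagonal, dimnames = sample
#'   ids (sorted lexicographically for deterministic downstream ties).
#' @export
p_distance <- function(aln, correction = c("raw", "JC69")) {
  correction <- match.arg(correction)
  ids <- sort(rownames(aln))
  mat <- unclass(aln)[ids, , drop = FALSE]
  n <- length(ids)
  if (n < 2L) abort("distance matrix needs >= 2 sequences")
  ## pairwise comparable-site and matching-site counts via crossproducts
  comp <- matrix(0, n, n)
  match_n <- matrix(0, n, n)
  U <- matrix(0, n, ncol(mat))
  for (b in c("A", "C", "G", "T")) {
    I <- (mat == b) * 1
    match_n <- match_n + tcrossprod(I)
    U <- U + I
  }
  comp <- tcrossprod(U)
  off <- upper.tri(comp)
  if (any(comp[off] == 0)) {
    k <- which(comp == 0 & off, arr.ind = TRUE)[1, ]
    abort("no comparable sites between '", ids[k[1]], "' and '", ids[k[2]], "'")
  }
  P <- 1 - match_n / comp
  diag(P) <- 0
  if (correction == "JC69") {
    if (any(P[off] >= 0.75)) {
      k <- which(P >= 0.75 & off, arr.ind = TRUE)[1, ]
      abort("saturated pair under JC69 (p = ", signif(P[k[1], k[2]], 3),
            "): '", ids[k[1]], "' vs '", ids[k[2]], "'")
    }
    P <- -0.75 * log(1 - 4 * P / 3)
    diag(P) <- 0
  }
  dimnames(P) <- list(ids, ids)
  P
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor-joining via [ape::nj()] on lexicographically sorted
#' taxa (deterministic tie handling), followed by two standard clean-ups:
#' negative branch lengths are clamped to zero with the deficit moved to
#' the sister edge, and internal branches of (near-)zero length are
#' collapsed into polytomies. The collapse matters for sets of identical
#' sequences: without it NJ's arbitrary-but-deterministic resolution of
#' zero-distance ties would recur in every bootstrap replicate and earn
#' spurious 100% support.
#'
#' @param D symmetric distance matrix with dimnames (from [p_distance()]).
#' @param collapse_tol internal branches shorter than this are collapsed
#'   (substitutions/site).
#' @return unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(D, collapse_tol = 1e-10) {
  if (is.null(dim(D)) || nrow(D) < 3L) abort("neighbor-joining needs >= 3 taxa")
  if (max(abs(D - t(D))) > 1e-12) abort("distance matrix must be symmetric")
  ord <- sort(rownames(D))
  tree <- ape::nj(stats::as.dist(D[ord, ord]))
  tree <- clamp_negative_edges(tree)
  tree <- ape::di2multi(tree, tol = collapse_tol)
  tree
}

## move negative edge lengths onto the sister edge, then clamp
clamp_negative_edges <- function(tree) {
  el <- tree$edge.length
  neg <- which(el < 0)
  for (k in neg) {
    parent <- tree$edge[k, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), k)
    if (length(sibs)) el[sibs] <- el[sibs] + el[k] / length(sibs)
    el[k] <- 0
  }
  el[el < 0] <- 0
  tree$edge.length <- el
  tree
}

#' Bootstrap configuration
#'
#' @param n_replicates number of column-resampling replicates (default
#'   1000, the conventional setting for published support values).
#' @param seed integer seed; mandatory so supports are reproducible.
#' @param support_display_threshold percent below which supports are
#'   conventionally not displayed (default 70).
#' @param correction distance correction passed to [p_distance()].
#' @return a `bootstrap_config` list.
#' @export
bootstrap_config <- function(n_replicates = 1000, seed,
                             support_display_threshold = 70,
                             correction = "JC69") {
  if (missing(seed)) abort("bootstrap_config requires an explicit seed")
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  if (support_display_threshold < 0 || support_display_threshold > 100)
    abort("support_display_threshold must lie in [0,100]")
  structure(list(n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 support_display_threshold = support_display_threshold,
                 correction = correction),
            class = "bootstrap_config")
}

#' Neighbor-joining tree with nonparametric bootstrap supports
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_replicates` times, rebuilds NJ per replicate, and maps
#' bipartition recurrence frequencies (percent) onto the full-data tree as
#' internal node labels. Replicates whose distance matrix cannot be
#' computed (e.g. a JC69-saturated or non-comparable pair) are skipped and
#' the denominator adjusted; the number skipped is recorded in
#' `attr(tree, "n_skipped")`.
#'
#' @param aln a `locus_alignment` with >= 4 sequences.
#' @param cfg a [bootstrap_config()].
#' @return unrooted [ape::phylo] with `node.label` holding integer percent
#'   supports ("" at the root/basal node).
#' @export
bootstrap_support <- function(aln, cfg) {
  stopifnot(inherits(cfg, "bootstrap_config"))
  if (nrow(aln) < 4L) abort("bootstrap needs >= 4 sequences")
  main <- nj_tree(p_distance(aln, cfg$correction))
  L <- ncol(aln)
  boot_trees <- vector("list", cfg$n_replicates)
  n_ok <- 0L
  with_seed(cfg$seed, {
    for (b in seq_len(cfg$n_replicates)) {
      idx <- sample.int(L, L, replace = TRUE)
      rep_aln <- locus_alignment(unclass(aln)[, idx, drop = FALSE],
                                 locus_name(aln))
      tr <- tryCatch(nj_tree(p_distance(rep_aln, cfg$correction)),
                     error = function(e) NULL)
      if (!is.null(tr)) {
        n_ok <- n_ok + 1L
        boot_trees[[n_ok]] <- tr
      }
    }
  })
  n_skipped <- cfg$n_replicates - n_ok
  if (n_ok == 0L) abort("all bootstrap replicates degenerate")
  if (n_skipped > 0L)
    message(n_skipped, " degenerate bootstrap replicate(s) skipped")
  counts <- ape::prop.clades(main, boot_trees[seq_len(n_ok)], rooted = FALSE)
  pct <- 100 * counts / n_ok
  lab <- as.character(round_half_up(pct, 0))
  lab[is.na(pct)] <- ""
  lab[1] <- ""  # basal node of the unrooted representation: not a split
  main$node.label <- lab
  attr(main, "n_skipped") <- n_skipped
  attr(main, "n_replicates_used") <- n_ok
  main
}

#' Fitch parsimony score with gaps as a fifth state
#'
#' Small-parsimony (Fitch) length of an alignment on a fixed tree over the
#' state set `{A, C, G, T, -}`; `N` is treated as missing data (the union
#' of all five states). Works on rooted or unrooted (basal multifurcation)
#' binary trees; the score is root-invariant.
#'
#' @param tree an [ape::phylo] whose tips are a subset of the alignment's
#'   samples.
#' @param aln a `locus_alignment`.
#' @return integer: minimum number of state changes summed over sites.
#' @export
fitch_score <- function(tree, aln) {
  miss <- setdiff(tree$tip.label, rownames(aln))
  if (length(miss))
    abort("leaf without sequence: ", paste(miss, collapse = ", "))
  code <- c(A = 1L, C = 2L, G = 4L, T = 8L, "-" = 16L, N = 31L)
  mat <- unclass(aln)[tree$tip.label, , drop = FALSE]
  ntip <- nrow(mat)
  L <- ncol(mat)
  states <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) states[[i]] <- unname(code[mat[i, ]])
  tr <- ape::reorder.phylo(tree, "postorder")
  steps <- 0L
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; chi <- tr$edge[k, 2]
    if (is.null(states[[par]])) {
      states[[par]] <- states[[chi]]
    } else {
      inter <- bitwAnd(states[[par]], states[[chi]])
      empty <- inter == 0L
      steps <- steps + sum(empty)
      inter[empty] <- bitwOr(states[[par]][empty], states[[chi]][empty])
      states[[par]] <- inter
    }
  }
  as.integer(steps)
}

#' Root a tree by outgroup or at its midpoint
#'
#' Outgroup rooting keeps internal labels attached to the correct edges
#' (`edgelabel = TRUE`); if the outgroup is not a clean bipartition of the
#' unrooted tree, the tree is rooted on the edge whose bipartition best
#' separates outgroup from ingroup, with a warning. Midpoint rooting puts
#' the root halfway along the longest leaf-to-leaf path.
#'
#' @param tree unrooted [ape::phylo].
#' @param mode `"outgroup"` or `"midpoint"`.
#' @param outgroup character vector of tip labels (mode = "outgroup").
#' @return rooted [ape::phylo].
#' @export
root_tree <- function(tree, mode = c("outgroup", "midpoint"), outgroup = NULL) {
  mode <- match.arg(mode)
  if (mode == "midpoint") {
    rooted <- phangorn::midpoint(tree, node.labels = "support")
    return(rooted)
  }
  if (is.null(outgroup) || !length(outgroup))
    abort("outgroup rooting requires outgroup tip labels")
  miss <- setdiff(outgroup, tree$tip.label)
  if (length(miss)) abort("outgroup absent from tree: ",
                          paste(miss, collapse = ", "))
  side <- outgroup
  if (length(outgroup) > 1 && length(outgroup) < length(tree$tip.label) - 1) {
    splits <- tree_splits(tree)
    og_is_split <- any(vapply(splits, function(s)
      setequal(s$side, outgroup), logical(1)))
    single_ok <- length(outgroup) == 1
    if (!og_is_split && !single_ok) {
      side <- best_separating_side(tree, splits, outgroup)
      warning("outgroup not monophyletic; rooting on the edge maximizing ",
              "outgroup/ingroup separation", call. = FALSE)
    }
  }
  ape::root(tree, outgroup = side, resolve.root = TRUE, edgelabel = TRUE)
}

## nontrivial bipartitions of an unrooted tree, each as the clade-side tip
## set plus the support label of the corresponding internal node
tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- clade_tip_sets(tree)
  sup <- node_support_values(tree)
  out <- list()
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    if (length(s) >= 2 && length(s) <= ntip - 2)
      out[[length(out) + 1]] <- list(side = s, support = sup[i])
  }
  out
}

## side (tip set) of the split best separating outgroup from ingroup
best_separating_side <- function(tree, splits, outgroup) {
  ingroup <- setdiff(tree$tip.label, outgroup)
  best <- outgroup[1]; best_score <- -Inf
  for (s in splits) {
    for (side in list(s$side, setdiff(tree$tip.label, s$side))) {
      score <- length(intersect(side, outgroup)) / length(outgroup) -
        length(intersect(side, ingroup)) / length(ingroup)
      if (score > best_score ||
          (score == best_score &&
           paste(sort(side), collapse = ",") <
             paste(sort(best), collapse = ","))) {
        best_score <- score
        best <- side
      }
    }
  }
  best
}
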