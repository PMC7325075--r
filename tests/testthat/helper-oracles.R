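## Fixture builders and independent brute-force oracles used across the
## suite. Oracles are deliberately naive re-derivations from definitions,
## kept free of any package internals.

random_alignment <- function(n, L, gap_prob = 0, n_prob = 0,
                             alphabet = c("A", "C", "G", "T")) {
  mat <- matrix(sample(alphabet, n * L, replace = TRUE), n, L)
  if (gap_prob > 0) mat[runif(n * L) < gap_prob] <- "-"
  if (n_prob > 0) mat[runif(n * L) < n_prob] <- "N"
  rownames(mat) <- sprintf("t%02d", seq_len(n))
  locus_alignment(mat, "rand")
}

## pi by definition: double loop over pairs and sites
oracle_pi <- function(aln, ids = rownames(aln)) {
  mat <- unclass(aln)[ids, , drop = FALSE]
  n <- nrow(mat)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- 0; comp <- 0
      for (k in seq_len(ncol(mat))) {
        a <- mat[i, k]; b <- mat[j, k]
        if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T")) {
          comp <- comp + 1
          if (a != b) d <- d + 1
        }
      }
      vals <- c(vals, d / comp)
    }
  }
  mean(vals)
}

## per-column category by direct application of the definitions
oracle_site_category <- function(col) {
  col <- col[col %in% c("A", "C", "G", "T")]
  if (length(unique(col)) <= 1) return("CONSTANT")
  counts <- sort(table(col), decreasing = TRUE)
  if (all(counts >= 2)) return("PARSIMONY_INFORMATIVE")
  if (counts[2] == 1) return("SINGLETON_VARIABLE")
  "OTHER_VARIABLE"
}

## monophyly by exhaustive clade enumeration via ape's own machinery
oracle_monophyletic <- function(tree, samples) {
  if (length(samples) == 1) return(TRUE)
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  for (cl in pp) {
    if (setequal(labels[cl], samples)) return(TRUE)
  }
  FALSE
}

## Fitch length by exhaustive minimization over internal-node states
oracle_fitch <- function(tree, aln) {
  states <- c("A", "C", "G", "T", "-")
  mat <- unclass(aln)[tree$tip.label, , drop = FALSE]
  nnode <- tree$Nnode
  ntip <- nrow(mat)
  grids <- rep(list(seq_along(states)), nnode)
  assigns <- expand.grid(grids)
  total <- 0
  for (site in seq_len(ncol(mat))) {
    obs <- mat[, site]
    best <- Inf
    for (r in seq_len(nrow(assigns))) {
      cost <- 0
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        pst <- states[assigns[r, p - ntip]]
        cst <- if (ch <= ntip) obs[ch] else states[assigns[r, ch - ntip]]
        if (cst == "N") next  # missing: free
        if (pst != cst) cost <- cost + 1
      }
      if (cost < best) best <- cost
    }
    total <- total + best
  }
  total
}

## split compatibility from first principles: two bipartitions of one leaf
## set can coexist in a tree iff some pair of their sides is disjoint
oracle_splits_compatible <- function(sideA, sideB, universe) {
  aa <- universe %in% sideA
  bb <- universe %in% sideB
  n11 <- sum(aa & bb); n10 <- sum(aa & !bb)
  n01 <- sum(!aa & bb); n00 <- sum(!aa & !bb)
  min(n11, n10, n01, n00) == 0
}

## a random rooted tree with integer supports on internal nodes
random_supported_tree <- function(n) {
  tree <- ape::rtree(n, rooted = TRUE)
  tree$node.label <- as.character(sample(0:100, tree$Nnode, replace = TRUE))
  tree
}

## deterministic well-separated two-cluster alignment for bootstrap tests
two_cluster_alignment <- function(L = 200) {
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  flip <- function(x, idx) {
    x[idx] <- vapply(x[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    x
  }
  cluster_sites <- seq_len(floor(L / 4))
  other <- flip(base, cluster_sites)
  mat <- rbind(a1 = flip(base, sample(L, 2)),
               a2 = flip(base, sample(L, 2)),
               b1 = flip(other, sample(L, 2)),
               b2 = flip(other, sample(L, 2)))
  locus_alignment(mat, "twoclust")
}
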