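## concord: per-species monophyly scoring against a species phylogeny,
## the conflict matrix with per-locus conflict percentages, sample-level
## hybrid flagging, and pairwise genealogy comparison.

CONFLICT_STATES <- c("CONFLICT", "NO_CONFLICT", "SINGLE_SAMPLE", "NO_DATA")

#' Is a set of samples monophyletic in a rooted tree?
#'
#' A sample set is monophyletic when some clade's leaf set equals the set
#' exactly. A single sample is monophyletic by definition (support
#' absent). The support returned is the bootstrap label of the matching
#' clade, `NA` if the tree carries none.
#'
#' @param tree rooted [ape::phylo] with supports in `node.label`.
#' @param samples character vector of tip labels (non-empty).
#' @return list with `is_monophyletic` (logical) and `support` (numeric
#'   percent or `NA`).
#' @export
monophyly_status <- function(tree, samples) {
  if (!length(samples)) abort("empty sample set")
  miss <- setdiff(samples, tree$tip.label)
  if (length(miss)) abort("sample not in tree: ", paste(miss, collapse = ", "))
  if (length(samples) == 1L)
    return(list(is_monophyletic = TRUE, support = NA_real_))
  target <- sort(unique(samples))
  sets <- clade_tip_sets(tree)
  sup <- node_support_values(tree)
  for (i in seq_along(sets)) {
    if (length(sets[[i]]) == length(target) && all(sets[[i]] == target))
      return(list(is_monophyletic = TRUE, support = sup[i]))
  }
  list(is_monophyletic = FALSE, support = NA_real_)
}

#' Construct a conflict matrix from a state matrix
#'
#' Mostly used to wrap an externally transcribed species-by-locus state
#' table (cells `CONFLICT`/`NO_CONFLICT`/`SINGLE_SAMPLE`/`NO_DATA`, or the
#' compact `C`/`X`/`O`/`N` encoding) so that [conflict_percentages()] and
#' [render_conflict_table()] can be applied to it.
#'
#' @param states character matrix, rows = species, columns = loci.
#' @return a `conflict_matrix`.
#' @export
conflict_matrix <- function(states) {
  compact <- c(C = "CONFLICT", X = "NO_CONFLICT", O = "SINGLE_SAMPLE",
               N = "NO_DATA")
  if (all(states %in% names(compact)))
    states[] <- compact[states]
  if (!all(states %in% CONFLICT_STATES))
    abort("invalid conflict state(s): ",
          paste(setdiff(unique(as.vector(states)), CONFLICT_STATES),
                collapse = ", "))
  if (is.null(rownames(states)) || is.null(colnames(states)))
    abort("state matrix needs species rownames and locus colnames")
  structure(states, class = c("conflict_matrix", class(states)))
}

#' @export
print.conflict_matrix <- function(x, ...) {
  cat("Conflict matrix:", nrow(x), "species x", ncol(x), "loci\n")
  print(render_conflict_table(x), row.names = FALSE)
  invisible(x)
}

#' Build the species-by-locus conflict matrix
#'
#' For each species and locus: with zero amplified samples the cell is
#' `NO_DATA`; with one, `SINGLE_SAMPLE`; with two or more, `CONFLICT` if
#' the amplified samples are not monophyletic in that locus' gene tree,
#' else `NO_CONFLICT`. Conflict is failure of monophyly only -- a species
#' whose samples form a clade placed differently than in the species
#' phylogeny is not in conflict.
#'
#' @param species_tree rooted species phylogeny ([ape::phylo]); each
#'   species' samples are checked for monophyly here and violations
#'   reported via warning (and recorded in
#'   `attr(result, "species_tree_violations")`).
#' @param gene_trees named list (locus -> rooted [ape::phylo]).
#' @param table a `sample_table` whose loci cover `names(gene_trees)`.
#' @return a `conflict_matrix` (character matrix species x locus).
#' @export
build_conflict_matrix <- function(species_tree, gene_trees, table) {
  loci <- names(gene_trees)
  if (is.null(loci) || any(loci == "")) abort("gene_trees must be named by locus")
  bad <- setdiff(loci, table_loci(table))
  if (length(bad)) abort("loci missing from metadata: ", paste(bad, collapse = ", "))
  species <- unique(table$species_id)

  violations <- character(0)
  if (!is.null(species_tree)) {
    for (sp in species) {
      ids <- intersect(table$sample_id[table$species_id == sp],
                       species_tree$tip.label)
      if (length(ids) >= 2 &&
          !monophyly_status(species_tree, ids)$is_monophyletic)
        violations <- c(violations, sp)
    }
    if (length(violations))
      warning("species not monophyletic in the species tree: ",
              paste(violations, collapse = ", "), call. = FALSE)
  }

  m <- matrix(NA_character_, length(species), length(loci),
              dimnames = list(species, loci))
  for (lc in loci) {
    gt <- gene_trees[[lc]]
    if (is.null(gt)) {
      ## locus without a tree (e.g. total amplification failure): cells can
      ## only be scored where no monophyly test is needed
      for (sp in species) {
        amp <- amplified_samples(table, lc, sp)
        m[sp, lc] <- if (length(amp) == 0) "NO_DATA"
        else if (length(amp) == 1) "SINGLE_SAMPLE"
        else abort("locus '", lc, "' has no gene tree but species '", sp,
                   "' has ", length(amp), " amplified samples")
      }
      next
    }
    failed <- table$sample_id[table[[lc]] == "FAILED"]
    inconsistent <- intersect(failed, gt$tip.label)
    if (length(inconsistent))
      abort("gene tree for '", lc, "' contains sample(s) marked FAILED: ",
            paste(inconsistent, collapse = ", "))
    for (sp in species) {
      amp <- amplified_samples(table, lc, sp)
      amp <- intersect(amp, gt$tip.label)
      m[sp, lc] <- if (length(amp) == 0) "NO_DATA"
      else if (length(amp) == 1) "SINGLE_SAMPLE"
      else if (monophyly_status(gt, amp)$is_monophyletic) "NO_CONFLICT"
      else "CONFLICT"
    }
  }
  out <- conflict_matrix(m)
  attr(out, "species_tree_violations") <- violations
  out
}

#' Per-locus conflict percentages
#'
#' For each locus, `100 * CONFLICT / (CONFLICT + NO_CONFLICT)`, rounded
#' half-up to one decimal. Species with a single amplified sample or no
#' data are excluded from the denominator; a locus with no evaluable
#' species gets `NA`.
#'
#' @param m a `conflict_matrix`.
#' @return named numeric vector (locus -> percent).
#' @export
conflict_percentages <- function(m) {
  stopifnot(inherits(m, "conflict_matrix"))
  vapply(colnames(m), function(lc) {
    nc <- sum(m[, lc] == "CONFLICT")
    nn <- sum(m[, lc] == "NO_CONFLICT")
    if (nc + nn == 0) return(NA_real_)
    round_half_up(100 * nc / (nc + nn), 1)
  }, numeric(1))
}

#' Flag putative hybrid individuals at one locus
#'
#' Two supported-discordance patterns are scored on a rooted gene tree:
#'
#' * `FOREIGN_NESTING`: sample `s` of species `X` sits inside a clade with
#'   support >= `support_min` whose other members all belong to other
#'   species, each of those host species being present with all of its
#'   amplified samples, while `X`'s remaining samples form a clade
#'   excluding `s`. This is the classic single-sample introgression
#'   signature (a sample grouping away from its conspecifics inside
#'   another species' clade).
#' * `SPECIES_MERGE`: the amplified samples of two species jointly form a
#'   clade with support >= `support_min` while neither species alone is
#'   supported as monophyletic -- the pattern left by two recently
#'   diverged species sharing (near-)identical sequences at a locus.
#'
#' @param species_tree rooted species phylogeny, used only to validate
#'   that each involved species is monophyletic there (may be `NULL`).
#' @param gene_tree rooted gene tree with supports in `node.label`.
#' @param table a `sample_table`.
#' @param locus locus name of `gene_tree` (a column of `table`).
#' @param support_min minimum bootstrap percent for a call (default 95).
#' @return data.frame of class `hybrid_calls` with columns `sample_id`,
#'   `species_id`, `locus`, `host_species` (comma-joined when several),
#'   `support`, `evidence`. Zero rows when nothing matches.
#' @export
flag_hybrids <- function(species_tree, gene_tree, table, locus,
                         support_min = 95) {
  tips <- gene_tree$tip.label
  sp_of <- stats::setNames(species_of(table, tips), tips)
  amp_by_sp <- split(tips, sp_of[tips])
  sets <- clade_tip_sets(gene_tree)
  sup <- node_support_values(gene_tree)
  supported <- which(!is.na(sup) & sup >= support_min)

  ## species monophyletic (topologically) in the gene tree
  mono <- vapply(amp_by_sp, function(ids)
    monophyly_status(gene_tree, ids)$is_monophyletic, logical(1))

  calls <- list()

  ## SPECIES_MERGE: supported clade = union of exactly two species' samples,
  ## with zero within-pair resolution (neither species forms even an
  ## unsupported clade of its own -- the identical-sequences pattern, as
  ## opposed to ordinary sister species with weakly supported clades)
  merged_species <- character(0)
  for (i in supported) {
    members <- sets[[i]]
    spp <- sort(unique(sp_of[members]))
    if (length(spp) != 2) next
    if (!setequal(members, unlist(amp_by_sp[spp], use.names = FALSE))) next
    if (mono[[spp[1]]] || mono[[spp[2]]]) next
    if (length(amp_by_sp[[spp[1]]]) < 2 || length(amp_by_sp[[spp[2]]]) < 2) next
    merged_species <- c(merged_species, spp)
    calls[[length(calls) + 1]] <- data.frame(
      sample_id = NA_character_,
      species_id = paste(spp, collapse = "+"),
      locus = locus, host_species = paste(spp, collapse = ","),
      support = sup[i], evidence = "SPECIES_MERGE",
      stringsAsFactors = FALSE)
  }

  ## FOREIGN_NESTING per sample
  for (s in tips) {
    X <- sp_of[[s]]
    own <- amp_by_sp[[X]]
    if (length(own) < 2) next
    if (X %in% merged_species) next
    rest <- setdiff(own, s)
    if (!monophyly_status(gene_tree, rest)$is_monophyletic) next
    ## minimal supported clade containing s with no conspecifics and
    ## complete host species
    cand <- supported[vapply(supported, function(i) s %in% sets[[i]], logical(1))]
    cand <- cand[order(lengths(sets[cand]))]
    for (i in cand) {
      members <- sets[[i]]
      others <- setdiff(members, s)
      if (!length(others)) next
      if (length(intersect(others, rest))) break  # conspecifics join first
      hosts <- sort(unique(sp_of[others]))
      complete <- all(vapply(hosts, function(h)
        all(amp_by_sp[[h]] %in% members), logical(1)))
      if (!complete) next
      calls[[length(calls) + 1]] <- data.frame(
        sample_id = s, species_id = X, locus = locus,
        host_species = paste(hosts, collapse = ","),
        support = sup[i], evidence = "FOREIGN_NESTING",
        stringsAsFactors = FALSE)
      break
    }
  }

  out <- if (length(calls)) do.call(rbind, calls)
  else data.frame(sample_id = character(0), species_id = character(0),
                  locus = character(0), host_species = character(0),
                  support = numeric(0), evidence = character(0),
                  stringsAsFactors = FALSE)
  out <- out[order(out$evidence, out$species_id, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hybrid_calls", "data.frame")
  out
}

#' Shared and conflicting supported bipartitions of two genealogies
#'
#' Both trees are restricted to their common leaf set; bipartitions with
#' support >= `threshold` are collected from each (full-tree supports,
#' splits restricted to the intersection, trivial splits dropped,
#' duplicates keep the maximum support). Two splits conflict when they
#' cannot coexist in one tree: all four side-intersections are non-empty.
#'
#' @param treeA,treeB [ape::phylo] trees with overlapping leaf sets
#'   (intersection >= 4) and supports in `node.label`.
#' @param threshold minimum support percent (default 70).
#' @return list with `shared` (list of splits present in both trees),
#'   `conflicting` (list of incompatible pairs, each a list `a`/`b`), and
#'   `splitsA`/`splitsB`. A split is a sorted character vector: the side
#'   not containing the alphabetically first common leaf.
#' @export
compare_genealogies <- function(treeA, treeB, threshold = 70) {
  common <- intersect(treeA$tip.label, treeB$tip.label)
  if (length(common) < 4) abort("leaf intersection < 4")
  sA <- restricted_splits(treeA, common, threshold)
  sB <- restricted_splits(treeB, common, threshold)
  keyA <- vapply(sA, paste, character(1), collapse = "|")
  keyB <- vapply(sB, paste, character(1), collapse = "|")
  shared <- sA[keyA %in% keyB]
  conflicting <- list()
  for (a in sA) {
    for (b in sB) {
      if (!splits_compatible(a, b, common))
        conflicting[[length(conflicting) + 1]] <- list(a = a, b = b)
    }
  }
  list(shared = shared, conflicting = conflicting,
       splitsA = sA, splitsB = sB)
}

## supported splits of `tree`, restricted to `common`, canonicalized
restricted_splits <- function(tree, common, threshold) {
  anchor <- sort(common)[1]
  out <- list()
  seen <- character(0)
  for (s in tree_splits(tree)) {
    if (is.na(s$support) || s$support < threshold) next
    side <- intersect(s$side, common)
    other <- setdiff(common, side)
    if (length(side) < 2 || length(other) < 2) next
    canon <- if (anchor %in% side) sort(other) else sort(side)
    key <- paste(canon, collapse = "|")
    if (!key %in% seen) {
      seen <- c(seen, key)
      out[[length(out) + 1]] <- canon
    }
  }
  out
}

## splits as canonical sides over the same leaf universe
splits_compatible <- function(a, b, universe) {
  a2 <- setdiff(universe, a)
  b2 <- setdiff(universe, b)
  !length(intersect(a, b)) || !length(intersect(a, b2)) ||
    !length(intersect(a2, b)) || !length(intersect(a2, b2))
}
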