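## simulate: multilocus synthetic data with planted hybridization events
## and a full truth ledger, so every pipeline stage is testable without
## external data.

#' Planted introgression events
#'
#' `tip_transfer` moves one sample into a donor species' subtree at one
#' locus (the single-sample hybrid pattern); `clade_merge` collapses two
#' species' samples into one zero-depth subtree at one locus (the
#' identical-sequences pattern left by two recently diverged species).
#'
#' @param sample_id sample to transfer.
#' @param locus locus name the event applies to.
#' @param donor_species species whose subtree receives the sample.
#' @return an event list for [sim_config()].
#' @export
tip_transfer <- function(sample_id, locus, donor_species) {
  list(type = "tip_transfer", sample_id = sample_id, locus = locus,
       donor_species = donor_species)
}

#' @rdname tip_transfer
#' @param species_a,species_b the two species merged at `locus`.
#' @export
clade_merge <- function(species_a, species_b, locus) {
  list(type = "clade_merge", species_a = species_a, species_b = species_b,
       locus = locus)
}

#' Simulation configuration
#'
#' Defaults emulate a multilocus survey of closely related fungal
#' species: interspecific divergence around 2% (root-to-tip height 0.02
#' substitutions/site), intraspecific variation two orders smaller
#' (`within_species_scale` 0.02 of the height), HKY85 substitution with a
#' transition/transversion rate ratio of 2, and per-locus amplification
#' dropout.
#'
#' @param n_species number of species (>= 2).
#' @param samples_per_species scalar or length-`n_species` integer vector.
#' @param loci named integer vector: locus name -> aligned length (sites).
#' @param species_tree_height expected root-to-tip depth,
#'   substitutions/site.
#' @param within_species_scale within-species subtree depth as a fraction
#'   of the height.
#' @param kappa transition/transversion rate ratio.
#' @param base_freqs equilibrium frequencies over A,C,G,T (sum to 1).
#' @param dropout_prob scalar or per-locus named vector of per-(sample,
#'   locus) amplification failure probabilities.
#' @param events list of [tip_transfer()] / [clade_merge()] events.
#' @param min_species_divergence optional floor on the closest species
#'   pair's divergence (see [sim_species_tree()]).
#' @param seed integer master seed; all randomness derives from it.
#' @return a validated `sim_config`.
#' @export
sim_config <- function(n_species, samples_per_species = 4,
                       loci = c(L1 = 800, L2 = 800, L3 = 800, L4 = 800),
                       species_tree_height = 0.02,
                       within_species_scale = 0.02,
                       kappa = 2.0,
                       base_freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       dropout_prob = 0,
                       events = list(),
                       min_species_divergence = NULL,
                       seed) {
  if (missing(seed)) abort("sim_config requires an explicit seed")
  if (n_species < 2) abort("n_species must be >= 2")
  if (length(samples_per_species) == 1)
    samples_per_species <- rep(samples_per_species, n_species)
  if (length(samples_per_species) != n_species)
    abort("samples_per_species must be scalar or length n_species")
  if (is.null(names(loci)) || any(names(loci) == ""))
    abort("loci must be a named vector of alignment lengths")
  if (abs(sum(base_freqs) - 1) > 1e-8) abort("base_freqs must sum to 1")
  if (any(base_freqs <= 0)) abort("base_freqs must be positive")
  if (length(dropout_prob) == 1)
    dropout_prob <- stats::setNames(rep(dropout_prob, length(loci)), names(loci))
  if (!all(names(loci) %in% names(dropout_prob)))
    abort("dropout_prob must cover every locus")
  if (any(dropout_prob < 0 | dropout_prob > 1))
    abort("dropout probabilities must lie in [0,1]")

  species <- sprintf("sp%02d", seq_len(n_species))
  samples <- unlist(lapply(seq_len(n_species), function(i)
    sprintf("%s_s%d", species[i], seq_len(samples_per_species[i]))))
  membership <- data.frame(
    sample_id = samples,
    species_id = rep(species, samples_per_species),
    stringsAsFactors = FALSE)

  for (ev in events) {
    if (!ev$locus %in% names(loci))
      abort("event references unknown locus: ", ev$locus)
    if (ev$type == "tip_transfer") {
      if (!ev$sample_id %in% samples)
        abort("event references unknown sample: ", ev$sample_id)
      if (!ev$donor_species %in% species)
        abort("event references unknown species: ", ev$donor_species)
      own <- membership$species_id[membership$sample_id == ev$sample_id]
      if (own == ev$donor_species)
        abort("tip_transfer donor equals the sample's own species")
    } else if (ev$type == "clade_merge") {
      if (!all(c(ev$species_a, ev$species_b) %in% species))
        abort("clade_merge references unknown species")
      if (ev$species_a == ev$species_b)
        abort("clade_merge needs two distinct species")
    } else abort("unknown event type: ", ev$type)
  }

  structure(list(n_species = n_species, species = species,
                 membership = membership, loci = loci,
                 species_tree_height = species_tree_height,
                 within_species_scale = within_species_scale,
                 kappa = kappa, base_freqs = base_freqs,
                 dropout_prob = dropout_prob, events = events,
                 min_species_divergence = min_species_divergence,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an ultrametric species tree
#'
#' Topology is Yule (pure-birth, via [ape::rphylo()]). Divergence times
#' are by default re-spaced to a basal-divergence-plus-radiation shape:
#' the root sits at `height` and the remaining divergences are evenly
#' spaced (order preserved) between
#' `radiation_fraction * height / (Nnode - 1)` and
#' `radiation_fraction * height`. Two properties follow: every species
#' pair is separated by a guaranteed minimum divergence (no pair is
#' statistically invisible at realistic locus lengths), and pooled
#' nucleotide diversity over a dense sample of the clade realizes close
#' to `height` itself (about 0.02 at the defaults), the magnitude typical
#' of a recently radiated species complex with one basal taxon.
#' `node_times = "yule"` keeps the raw birth-process times (rescaled to
#' `height`) instead, which can place sister species arbitrarily close.
#' Deterministic under `seed`.
#'
#' @param n_species number of tips (>= 2).
#' @param height root-to-tip depth in substitutions/site.
#' @param seed integer seed.
#' @param labels optional tip labels (default `sp01`, `sp02`, ...).
#' @param node_times `"even"` (default) or `"yule"`.
#' @param radiation_fraction depth of the shallow radiation relative to
#'   the root (default 0.6), used when `node_times = "even"`.
#' @param min_divergence optional floor on the divergence (twice the
#'   coalescence depth) of the closest species pair, substitutions/site;
#'   use it to guarantee that every species pair is resolvable at a given
#'   locus length.
#' @return rooted ultrametric [ape::phylo].
#' @export
sim_species_tree <- function(n_species, height, seed, labels = NULL,
                             node_times = c("even", "yule"),
                             radiation_fraction = 0.6,
                             min_divergence = NULL) {
  node_times <- match.arg(node_times)
  if (n_species < 2) abort("n_species must be >= 2")
  tree <- with_seed(seed, ape::rphylo(n_species, birth = 1, death = 0))
  depth_below <- max(ape::node.depth.edgelength(tree)) -
    ape::node.depth.edgelength(tree)  # node height above the tips
  ntip <- n_species
  if (node_times == "even") {
    node_h <- depth_below[(ntip + 1):(ntip + tree$Nnode)]
    rk <- rank(node_h, ties.method = "first")
    hi <- radiation_fraction * height
    lo <- if (tree$Nnode > 1) hi / (tree$Nnode - 1) else hi
    if (!is.null(min_divergence)) {
      if (min_divergence / 2 > hi)
        abort("min_divergence/2 exceeds the radiation depth (",
              "radiation_fraction * height = ", hi, ")")
      lo <- max(lo, min_divergence / 2)
    }
    new_h <- if (tree$Nnode == 1) height
    else lo + (hi - lo) * (rk - 1) / max(tree$Nnode - 2, 1)
    new_h[rk == tree$Nnode] <- height  # the root
    depth_below[(ntip + 1):(ntip + tree$Nnode)] <- new_h
    depth_below[seq_len(ntip)] <- 0
  } else {
    depth_below <- depth_below * height / max(depth_below)
  }
  tree$edge.length <- depth_below[tree$edge[, 1]] - depth_below[tree$edge[, 2]]
  tree$tip.label <- if (is.null(labels)) sprintf("sp%02d", seq_len(n_species))
  else labels
  tree
}

#' Simulate per-locus gene trees with planted events and dropout
#'
#' The baseline gene tree at each locus is the species tree with each
#' species tip replaced by a within-species coalescent subtree of depth
#' `height * within_species_scale`. A `tip_transfer` regrafts the named
#' sample inside the donor species' subtree at that locus only; a
#' `clade_merge` replaces the two species by a single zero-depth subtree
#' holding all their samples (so their sequences come out identical at
#' that locus). Dropout removes (sample, locus) leaves and is recorded;
#' samples named in events are never dropped at the event locus. Internal
#' branches of length zero are collapsed into polytomies, so "identical
#' sequences" regions carry no phantom resolution.
#'
#' Truth is derived from the realized gene trees themselves: the expected
#' conflict matrix marks each species CONFLICT wherever its retained
#' samples fail to be monophyletic in the true gene tree, and expected
#' hybrid calls are obtained by applying the topological nesting/merger
#' rules to the true trees (all true clades treated as fully supported).
#'
#' @param species_tree from [sim_species_tree()], tips = config species.
#' @param config a [sim_config()].
#' @return list with `gene_trees` (named list of rooted [ape::phylo]),
#'   `table` (a `sample_table` with dropout as FAILED) and `truth` (a
#'   `sim_truth`: events, dropout ledger, expected conflict matrix,
#'   expected hybrid calls, newick strings of all true trees).
#' @export
sim_gene_trees <- function(species_tree, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!setequal(species_tree$tip.label, config$species))
    abort("species_tree tips must match config species")
  memb <- config$membership
  d_w <- config$species_tree_height * config$within_species_scale
  loci <- names(config$loci)

  gene_trees <- list()
  dropout <- list()
  status <- matrix(1L, nrow(memb), length(loci),
                   dimnames = list(memb$sample_id, loci))

  with_seed(derive_seed(config$seed, 1L), {
    for (lc in loci) {
      ## per-locus membership groups (species -> samples at that position)
      groups <- split(memb$sample_id, memb$species_id)
      merged <- character(0)
      st <- species_tree
      protected <- character(0)
      for (ev in config$events) {
        if (ev$locus != lc) next
        if (ev$type == "tip_transfer") {
          own <- memb$species_id[memb$sample_id == ev$sample_id]
          groups[[own]] <- setdiff(groups[[own]], ev$sample_id)
          groups[[ev$donor_species]] <- c(groups[[ev$donor_species]],
                                          ev$sample_id)
          protected <- c(protected, ev$sample_id)
        } else {
          groups[[ev$species_a]] <- c(groups[[ev$species_a]],
                                      groups[[ev$species_b]])
          groups[[ev$species_b]] <- NULL
          merged <- c(merged, ev$species_a)
          st <- ape::drop.tip(st, ev$species_b)
        }
      }
      ## dropout draw (event samples protected at this locus)
      p <- config$dropout_prob[[lc]]
      if (p > 0) {
        drop <- memb$sample_id[stats::runif(nrow(memb)) < p]
        drop <- setdiff(drop, protected)
        if (length(intersect(drop, protected)))
          abort("event references a dropped sample at locus ", lc)
        status[drop, lc] <- 0L
        if (length(drop))
          dropout[[length(dropout) + 1]] <-
            data.frame(sample_id = drop, locus = lc, stringsAsFactors = FALSE)
        groups <- lapply(groups, setdiff, y = drop)
      }
      ## prune species left with no samples
      empty <- names(groups)[lengths(groups) == 0]
      for (sp in empty) {
        groups[[sp]] <- NULL
        if (sp %in% st$tip.label) st <- ape::drop.tip(st, sp)
      }
      if (is.null(st) || length(st$tip.label) < 2 ||
          sum(lengths(groups)) < 3) {
        ## locus effectively lost to dropout: no gene tree
        gene_trees[lc] <- list(NULL)
      } else {
        nwk <- render_gene_tree(st, groups, d_w, merged)
        gt <- ape::read.tree(text = nwk)
        gt <- ape::di2multi(gt, tol = 1e-12)
        gene_trees[[lc]] <- gt
      }
    }
  })

  tab <- data.frame(sample_id = memb$sample_id, species_id = memb$species_id,
                    voucher = paste0("SIM-", memb$sample_id),
                    stringsAsFactors = FALSE)
  for (lc in loci) tab[[lc]] <- status[, lc]
  tab <- sample_table(tab)

  dropout <- if (length(dropout)) do.call(rbind, dropout)
  else data.frame(sample_id = character(0), locus = character(0),
                  stringsAsFactors = FALSE)

  expected_matrix <- build_conflict_matrix(NULL, gene_trees, tab)
  expected_calls <- do.call(rbind, lapply(loci, function(lc) {
    gt <- gene_trees[[lc]]
    if (is.null(gt)) return(NULL)
    gt$node.label <- rep("100", gt$Nnode)
    flag_hybrids(NULL, gt, tab, lc, support_min = 95)
  }))

  truth <- structure(list(
    species_tree = ape::write.tree(species_tree),
    gene_trees = vapply(gene_trees, function(g)
      if (is.null(g)) NA_character_ else ape::write.tree(g), character(1)),
    events = config$events,
    dropout = dropout,
    expected_matrix = expected_matrix,
    expected_calls = expected_calls), class = "sim_truth")

  list(gene_trees = gene_trees, table = tab, truth = truth)
}

## render one locus' gene tree newick: species tree with tips replaced by
## within-species subtrees (depth d_w; 0 for merged groups)
render_gene_tree <- function(st, groups, d_w, merged) {
  ntip <- length(st$tip.label)
  root <- ntip + 1L
  children <- split(seq_len(nrow(st$edge)), st$edge[, 1])
  render <- function(node) {
    kids <- children[[as.character(node)]]
    parts <- vapply(kids, function(k) {
      child <- st$edge[k, 2]
      el <- st$edge.length[k]
      if (child <= ntip) render_tip(st$tip.label[child], el)
      else paste0(render(child), ":", format(el, digits = 12))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  render_tip <- function(sp, el) {
    g <- sort(groups[[sp]])
    if (length(g) == 1L) return(paste0(g, ":", format(el, digits = 12)))
    depth <- if (sp %in% merged) 0 else min(d_w, 0.9 * el)
    sub <- ape::rcoal(length(g), tip.label = sample(g))
    h <- max(ape::node.depth.edgelength(sub))
    sub$edge.length <- if (depth == 0) rep(0, length(sub$edge.length))
    else sub$edge.length * depth / h
    s <- ape::write.tree(sub)
    s <- sub(";$", "", s)
    paste0(s, ":", format(el - depth, digits = 12))
  }
  paste0(render(root), ";")
}

#' Simulate sequences along a tree under HKY85
#'
#' Root states are drawn from `base_freqs`; each branch applies the HKY85
#' transition-probability matrix `exp(Q t)` site by site, with `Q` scaled
#' to one expected substitution per site per unit branch length.
#' Deterministic under `seed`.
#'
#' @param tree rooted [ape::phylo] with non-negative branch lengths in
#'   substitutions/site.
#' @param length number of sites.
#' @param kappa transition/transversion rate ratio.
#' @param base_freqs equilibrium frequencies (A, C, G, T).
#' @param seed integer seed.
#' @param locus name for the resulting alignment.
#' @return a `locus_alignment` of the tip sequences.
#' @export
evolve_sequences <- function(tree, length, kappa = 2.0,
                             base_freqs = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                             seed, locus = "sim") {
  if (missing(seed)) abort("evolve_sequences requires an explicit seed")
  if (any(tree$edge.length < 0)) abort("negative branch length")
  if (abs(sum(base_freqs) - 1) > 1e-8) abort("base_freqs must sum to 1")
  eig <- hky_eigen(kappa, base_freqs)
  bases <- c("A", "C", "G", "T")
  ntip <- base::length(tree$tip.label)
  nnode <- tree$Nnode
  states <- vector("list", ntip + nnode)
  with_seed(seed, {
    root <- ntip + 1L
    states[[root]] <- sample.int(4L, length, replace = TRUE,
                                 prob = base_freqs)
    tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
    Pcache <- list()
    for (k in seq_len(nrow(tr$edge))) {
      par <- tr$edge[k, 1]; chi <- tr$edge[k, 2]
      t <- tr$edge.length[k]
      key <- format(t, digits = 15)
      P <- Pcache[[key]]
      if (is.null(P)) {
        P <- hky_pmatrix(eig, t)
        Pcache[[key]] <- P
      }
      parent_state <- states[[par]]
      child <- integer(length)
      for (s in 1:4) {
        idx <- which(parent_state == s)
        if (base::length(idx))
          child[idx] <- sample.int(4L, base::length(idx), replace = TRUE,
                                   prob = P[s, ])
      }
      states[[chi]] <- child
    }
  })
  seqs <- do.call(rbind, lapply(seq_len(ntip), function(i) bases[states[[i]]]))
  rownames(seqs) <- tree$tip.label
  locus_alignment(seqs, locus_name = locus)
}

## eigendecomposition of the normalized HKY85 rate matrix
hky_eigen <- function(kappa, base_freqs) {
  pi <- as.numeric(base_freqs)  # A C G T
  Q <- matrix(0, 4, 4)
  transition <- function(i, j) (i == 1 && j == 3) || (i == 3 && j == 1) ||
    (i == 2 && j == 4) || (i == 4 && j == 2)
  for (i in 1:4) for (j in 1:4) if (i != j)
    Q[i, j] <- if (transition(i, j)) kappa * pi[j] else pi[j]
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))  # expected rate; normalize to 1
  Q <- Q / mu
  ## symmetrize for a stable eigendecomposition (HKY is reversible)
  s <- sqrt(pi)
  B <- diag(s) %*% Q %*% diag(1 / s)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(values = e$values,
       right = diag(1 / s) %*% e$vectors,
       left = t(e$vectors) %*% diag(s))
}

hky_pmatrix <- function(eig, t) {
  P <- eig$right %*% diag(exp(eig$values * t)) %*% eig$left
  P[P < 0] <- 0
  P / rowSums(P)
}

#' A survey-scale simulation preset
#'
#' Twenty-two species with 1-9 samples each (83 samples), four unlinked
#' loci of 654, 827, 755 and 909 aligned sites, root-to-tip height 0.02
#' substitutions/site, and per-locus dropout of 14/83 and 15/83 on the
#' two least reliable loci -- the shape of a typical multilocus
#' concordance survey of closely related fungal species.
#'
#' @param seed integer master seed.
#' @param events planted events (default none).
#' @return a `sim_config`.
#' @export
sim_config_preset <- function(seed, events = list()) {
  sim_config(
    n_species = 22,
    samples_per_species = c(5, 2, 4, 5, 4, 2, 1, 9, 3, 4, 4, 2, 5, 6, 5,
                            5, 4, 6, 1, 2, 2, 2),
    loci = c("MAT1-1-1" = 654, "MAT1-2-1" = 827, "F1" = 755, "IGS" = 909),
    species_tree_height = 0.02,
    within_species_scale = 0.02,
    kappa = 2.0,
    dropout_prob = c("MAT1-1-1" = 0, "MAT1-2-1" = 0,
                     "F1" = 14 / 83, "IGS" = 15 / 83),
    events = events,
    seed = seed)
}

#' Simulate a full multilocus dataset in memory
#'
#' @param config a [sim_config()].
#' @return list with `alignments` (named list of `locus_alignment`),
#'   `table` (`sample_table`), `gene_trees` (true trees), `species_tree`
#'   and `truth` (`sim_truth`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sp_tree <- sim_species_tree(config$n_species, config$species_tree_height,
                              seed = derive_seed(config$seed, 0L),
                              labels = config$species,
                              min_divergence = config$min_species_divergence)
  gt <- sim_gene_trees(sp_tree, config)
  alignments <- list()
  loci <- names(config$loci)
  for (i in seq_along(loci)) {
    lc <- loci[i]
    if (is.null(gt$gene_trees[[lc]])) { alignments[lc] <- list(NULL); next }
    alignments[[lc]] <- evolve_sequences(
      gt$gene_trees[[lc]], config$loci[[lc]], kappa = config$kappa,
      base_freqs = config$base_freqs,
      seed = derive_seed(config$seed, 10L + i), locus = lc)
  }
  list(alignments = alignments, table = gt$table,
       gene_trees = gt$gene_trees, species_tree = sp_tree,
       truth = gt$truth)
}

#' Simulate a dataset and write it to disk
#'
#' Writes one FASTA per locus, the metadata TSV (dropout encoded as 0)
#' and a truth JSON (events, dropout ledger, expected conflict matrix,
#' expected hybrid calls, true trees as newick).
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return the [simulate_dataset()] list, invisibly, with `$paths` added.
#' @export
make_dataset <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) abort("cannot create output directory: ", outdir)
  ds <- simulate_dataset(config)
  paths <- list()
  for (lc in names(ds$alignments)) {
    if (is.null(ds$alignments[[lc]])) next
    f <- file.path(outdir, paste0(gsub("[^A-Za-z0-9._-]", "_", lc), ".fasta"))
    write_alignment(ds$alignments[[lc]], f)
    paths[[lc]] <- f
  }
  meta <- file.path(outdir, "samples.tsv")
  write_sample_table(ds$table, meta)
  paths$metadata <- meta
  truth_path <- file.path(outdir, "truth.json")
  truth <- ds$truth
  jsonlite::write_json(list(
    species_tree = truth$species_tree,
    gene_trees = as.list(truth$gene_trees),
    events = truth$events,
    dropout = truth$dropout,
    expected_matrix = list(
      species = rownames(truth$expected_matrix),
      loci = colnames(truth$expected_matrix),
      states = apply(truth$expected_matrix, 1, unname, simplify = FALSE)),
    expected_calls = truth$expected_calls
  ), truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$truth <- truth_path
  ds$paths <- paths
  invisible(ds)
}
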