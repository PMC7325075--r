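## cli_report: orchestration of the stages, table rendering, and the
## reproducibility log.

#' Pipeline configuration
#'
#' @param locus_paths named character vector: locus name -> FASTA path.
#' @param metadata_path path to the sample metadata TSV.
#' @param rooting named list: locus -> either `"midpoint"` or a character
#'   vector of outgroup sample ids (or species ids, resolved via the
#'   metadata). A `.species_tree` entry sets the species-tree rooting.
#'   Loci without an entry use `default_rooting`.
#' @param default_rooting fallback rooting mode (`"midpoint"` or outgroup
#'   sample/species ids).
#' @param species_tree_path optional newick file for an externally built
#'   species tree; when `NULL` the species tree is built from the
#'   concatenation of `species_tree_loci`.
#' @param species_tree_loci loci concatenated to build the species tree
#'   (default: all).
#' @param n_bootstrap bootstrap replicates per tree (default 1000).
#' @param support_display_threshold display threshold percent (default 70).
#' @param hybrid_support_min support threshold for hybrid calls (default 95).
#' @param alpha significance level for segregation tests (default 0.05).
#' @param isolate_path optional isolate TSV for the mating stage.
#' @param seed master seed; all stage seeds derive from it.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(locus_paths, metadata_path,
                            rooting = list(), default_rooting = "midpoint",
                            species_tree_path = NULL,
                            species_tree_loci = names(locus_paths),
                            n_bootstrap = 1000,
                            support_display_threshold = 70,
                            hybrid_support_min = 95,
                            alpha = 0.05,
                            isolate_path = NULL,
                            seed) {
  if (missing(seed)) abort("pipeline_config requires an explicit seed")
  if (is.null(names(locus_paths)) || any(names(locus_paths) == ""))
    abort("locus_paths must be named by locus")
  for (p in c(locus_paths, metadata_path, species_tree_path, isolate_path))
    if (!is.null(p) && !file.exists(p)) abort("file not found: ", p)
  for (th in c(support_display_threshold, hybrid_support_min))
    if (th < 0 || th > 100) abort("thresholds must lie in [0,100]")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0,1)")
  structure(list(locus_paths = locus_paths, metadata_path = metadata_path,
                 rooting = rooting, default_rooting = default_rooting,
                 species_tree_path = species_tree_path,
                 species_tree_loci = species_tree_loci,
                 n_bootstrap = as.integer(n_bootstrap),
                 support_display_threshold = support_display_threshold,
                 hybrid_support_min = hybrid_support_min,
                 alpha = alpha, isolate_path = isolate_path,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full concordance pipeline
#'
#' Stages: read inputs -> per-locus diversity summaries -> NJ + bootstrap
#' gene trees (rooted per config) -> species tree (imported or built from
#' concatenated loci) -> conflict matrix, conflict percentages and hybrid
#' calls -> mating-type segregation (if an isolate table is given).
#' All outputs are written under `outdir` (`divstats.tsv`,
#' `trees/<locus>.nwk`, `conflict_matrix.tsv`, `hybrids.tsv`,
#' `mating.tsv`, `report.json`, `run.log`) and returned in memory.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return list with `divstats`, `gene_trees`, `species_tree`,
#'   `conflict_matrix`, `conflict_percentages`, `hybrids`, `mating`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "trees"), showWarnings = FALSE)
  log_lines <- c(sprintf("gcpsr %s", as.character(utils::packageVersion("gcpsr"))),
                 sprintf("R %s", getRversion()),
                 sprintf("seed %d", config$seed),
                 sprintf("n_bootstrap %d", config$n_bootstrap),
                 sprintf("support_display_threshold %s",
                         config$support_display_threshold),
                 sprintf("hybrid_support_min %s", config$hybrid_support_min),
                 sprintf("alpha %s", config$alpha))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort("stage '", name, "' failed: ", conditionMessage(e)))
  }

  table <- stage("metadata", read_sample_table(config$metadata_path))
  alignments <- stage("alignments", {
    out <- lapply(names(config$locus_paths), function(lc)
      read_alignment(config$locus_paths[[lc]], lc))
    names(out) <- names(config$locus_paths)
    out
  })
  loci <- names(alignments)

  divstats <- stage("divstats",
    do.call(rbind, lapply(alignments, summarize_locus, table = table)))
  write_divstats(divstats, file.path(outdir, "divstats.tsv"))

  resolve_root <- function(spec_entry, tree) {
    if (identical(spec_entry, "midpoint"))
      return(root_tree(tree, "midpoint"))
    og <- spec_entry
    if (any(og %in% table$species_id))
      og <- table$sample_id[table$species_id %in% og]
    og <- intersect(og, tree$tip.label)
    if (!length(og)) abort("outgroup absent from tree")
    root_tree(tree, "outgroup", outgroup = og)
  }
  rooting_for <- function(lc) {
    if (!is.null(config$rooting[[lc]])) config$rooting[[lc]]
    else config$default_rooting
  }

  gene_trees <- stage("trees", {
    out <- list()
    for (i in seq_along(loci)) {
      lc <- loci[i]
      cfg <- bootstrap_config(config$n_bootstrap,
                              seed = derive_seed(config$seed, 100L + i),
                              support_display_threshold =
                                config$support_display_threshold)
      tr <- bootstrap_support(alignments[[lc]], cfg)
      tr <- resolve_root(rooting_for(lc), tr)
      write_newick(tr, file.path(outdir, "trees",
                                 paste0(gsub("[^A-Za-z0-9._-]", "_", lc),
                                        ".nwk")))
      out[[lc]] <- tr
    }
    out
  })

  species_tree <- stage("species_tree", {
    if (!is.null(config$species_tree_path)) {
      tr <- read_newick(config$species_tree_path)
    } else {
      cat_aln <- concatenate_alignments(alignments[config$species_tree_loci],
                                        table)
      cfg <- bootstrap_config(config$n_bootstrap,
                              seed = derive_seed(config$seed, 99L),
                              support_display_threshold =
                                config$support_display_threshold)
      tr <- bootstrap_support(cat_aln, cfg)
    }
    if (ape::is.rooted(tr) && !is.null(config$species_tree_path)) tr
    else resolve_root(if (!is.null(config$rooting[[".species_tree"]]))
      config$rooting[[".species_tree"]] else config$default_rooting, tr)
  })
  write_newick(species_tree, file.path(outdir, "trees", "species_tree.nwk"))

  concord <- stage("concord", {
    m <- build_conflict_matrix(species_tree, gene_trees, table)
    hy <- do.call(rbind, lapply(loci, function(lc)
      flag_hybrids(species_tree, gene_trees[[lc]], table, lc,
                   support_min = config$hybrid_support_min)))
    list(matrix = m, pct = conflict_percentages(m), hybrids = hy)
  })
  utils::write.table(render_conflict_table(concord$matrix),
                     file.path(outdir, "conflict_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(concord$hybrids),
                     file.path(outdir, "hybrids.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  mating <- NULL
  if (!is.null(config$isolate_path)) {
    mating <- stage("mating", {
      iso <- utils::read.delim(config$isolate_path, sep = "\t",
                               stringsAsFactors = FALSE)
      mating_summary(iso, alpha = config$alpha)
    })
    utils::write.table(mating, file.path(outdir, "mating.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- list(
    conflict_percentages = as.list(concord$pct),
    n_hybrid_calls = nrow(concord$hybrids),
    loci = loci,
    n_samples = nrow(table),
    n_species = length(unique(table$species_id)))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(outdir, "run.log"))

  list(divstats = divstats, gene_trees = gene_trees,
       species_tree = species_tree, conflict_matrix = concord$matrix,
       conflict_percentages = concord$pct, hybrids = concord$hybrids,
       mating = mating)
}

#' Concatenate locus alignments over their common samples
#'
#' Samples missing a locus (amplification failure) get N-padding for that
#' locus' columns, the standard supermatrix convention.
#'
#' @param alignments named list of `locus_alignment`s.
#' @param table a `sample_table` (defines the sample universe).
#' @return a `locus_alignment` named `"concat"`.
#' @export
concatenate_alignments <- function(alignments, table) {
  ids <- table$sample_id
  blocks <- lapply(alignments, function(a) {
    out <- matrix("N", length(ids), ncol(a),
                  dimnames = list(ids, NULL))
    present <- intersect(ids, rownames(a))
    out[present, ] <- unclass(a)[present, , drop = FALSE]
    out
  })
  keep <- rowSums(do.call(cbind, blocks) != "N") > 0
  locus_alignment(do.call(cbind, blocks)[keep, , drop = FALSE], "concat")
}

#' Render a conflict matrix as a publication-style table
#'
#' Rows = species with compact state codes (`C` conflict, `X` no
#' conflict, `O` single sample, `N` no data), plus a final
#' `"Total conflicts"` row holding the per-locus percentages formatted to
#' one decimal (`"NA"` for loci with no evaluable species).
#'
#' @param m a `conflict_matrix`.
#' @return data.frame with a `species` column and one column per locus.
#' @export
render_conflict_table <- function(m) {
  stopifnot(inherits(m, "conflict_matrix"))
  compact <- c(CONFLICT = "C", NO_CONFLICT = "X", SINGLE_SAMPLE = "O",
               NO_DATA = "N")
  body <- matrix(compact[m], nrow(m), ncol(m), dimnames = dimnames(m))
  pct <- conflict_percentages(m)
  totals <- ifelse(is.na(pct), "NA", paste0(formatC(pct, format = "f",
                                                    digits = 1), "%"))
  out <- data.frame(species = c(rownames(m), "Total conflicts"),
                    rbind(body, totals), check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a transcribed conflict-state table
#'
#' TSV with a `species` column and one column per locus holding compact
#' states `C`/`X`/`O`/`N` (any `"Total conflicts"` row is dropped);
#' convenient for re-deriving per-locus conflict percentages from a
#' published state matrix.
#'
#' @param path TSV path.
#' @return a `conflict_matrix`.
#' @export
read_conflict_states <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!"species" %in% names(df)) abort("state table needs a 'species' column")
  df <- df[df$species != "Total conflicts", , drop = FALSE]
  m <- as.matrix(df[, setdiff(names(df), "species"), drop = FALSE])
  rownames(m) <- df$species
  conflict_matrix(m)
}
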