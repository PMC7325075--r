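## divstats: per-locus / per-species alignment summary statistics --
## site classification and nucleotide diversity (pi).

#' Classify alignment columns
#'
#' Each column is classified using only unambiguous bases (gap and N
#' excluded):
#' * `CONSTANT`: at most one distinct state;
#' * `PARSIMONY_INFORMATIVE`: at least two states and every observed state
#'   occurs at least twice;
#' * `SINGLETON_VARIABLE`: variable, and every state beyond the most
#'   frequent one occurs exactly once (e.g. `A,A,A,T` or `A,A,T,C`);
#' * `OTHER_VARIABLE`: remaining variable patterns, i.e. columns mixing a
#'   second state seen at least twice with additional singleton states
#'   (e.g. `A,A,T,T,C`).
#'
#' The four categories partition the columns; the last three sum to the
#' variable-site count.
#'
#' @param aln a `locus_alignment` with at least two sequences.
#' @return a `site_classification`: list with `category` (character vector
#'   per column), `counts` (named table over the four categories),
#'   `n_sites` and `n_variable`.
#' @export
classify_sites <- function(aln) {
  if (nrow(aln) < 2L) abort("site classification needs >= 2 sequences")
  cats <- apply(unclass(aln), 2, classify_one_column)
  lev <- c("CONSTANT", "SINGLETON_VARIABLE", "PARSIMONY_INFORMATIVE",
           "OTHER_VARIABLE")
  counts <- table(factor(cats, levels = lev))
  structure(list(category = cats,
                 counts = counts,
                 n_sites = ncol(aln),
                 n_variable = sum(counts[lev[-1]])),
            class = "site_classification")
}

## one column -> category; gap/N dropped first
classify_one_column <- function(col) {
  col <- col[col %in% c("A", "C", "G", "T")]
  tab <- sort(table(col), decreasing = TRUE)
  if (length(tab) <= 1L) return("CONSTANT")
  if (min(tab) >= 2L) return("PARSIMONY_INFORMATIVE")
  if (tab[2L] == 1L) return("SINGLETON_VARIABLE")
  "OTHER_VARIABLE"
}

#' @export
print.site_classification <- function(x, ...) {
  cat("Site classification over", x$n_sites, "sites:\n")
  print(x$counts)
  invisible(x)
}

#' Nucleotide diversity (pi)
#'
#' Average over all unordered sequence pairs of the per-site difference
#' proportion, comparing only columns where both sequences carry an
#' unambiguous base (pairwise deletion of gaps and N). No multiple-hit
#' correction is applied.
#'
#' @param aln a `locus_alignment`.
#' @param sample_ids subset of row names to use (default: all).
#' @return list with `pi` (mean pairwise difference per compared site) and
#'   `n_pairs`. Errors if some pair shares no comparable column.
#' @examples
#' aln <- locus_alignment(c(a = "AAAAAAAAAA", b = "AAAAAAAAAT",
#'                          c = "AAAAAAAATT"), "demo")
#' nucleotide_diversity(aln)$pi  # (1+2+1)/3/10
#' @export
nucleotide_diversity <- function(aln, sample_ids = rownames(aln)) {
  missing_ids <- setdiff(sample_ids, rownames(aln))
  if (length(missing_ids))
    abort("sample id(s) not in alignment: ", paste(missing_ids, collapse = ", "))
  if (length(sample_ids) < 2L) abort("pi needs >= 2 sequences")
  mat <- unclass(aln)[sample_ids, , drop = FALSE]
  usable <- mat %in% c("A", "C", "G", "T")
  dim(usable) <- dim(mat)
  n <- nrow(mat)
  tot <- 0
  n_pairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- usable[i, ] & usable[j, ]
      n_comp <- sum(ok)
      if (n_comp == 0L)
        abort("no comparable sites between '", sample_ids[i], "' and '",
              sample_ids[j], "'")
      tot <- tot + sum(mat[i, ok] != mat[j, ok]) / n_comp
      n_pairs <- n_pairs + 1L
    }
  }
  list(pi = tot / n_pairs, n_pairs = n_pairs)
}

#' Per-locus and per-species diversity summary
#'
#' One row for all samples pooled plus one per species. pi is computed for
#' scopes with at least two amplified sequences present in the alignment;
#' species with fewer get `NA` (reported, not dropped). The percentage of
#' variable sites is displayed to two decimals (see Details).
#'
#' @details Percentages are displayed by rounding half-up to three
#' decimals then half-to-even to two, the successive display rounding used
#' by the survey tables this summary mirrors (120/654 -> 18.35,
#' 158/827 -> 19.10).
#'
#' @param aln a `locus_alignment`.
#' @param table a `sample_table` covering the alignment's samples.
#' @return data.frame of class `diversity_summary` with columns `locus`,
#'   `scope` (`ALL_SAMPLES` or a species_id), `n_seqs`, `n_sites`,
#'   `n_variable`, `pct_variable`, `n_PI`, `n_singleton`, `pi`.
#' @export
summarize_locus <- function(aln, table) {
  ids <- rownames(aln)
  missing_ids <- setdiff(ids, table$sample_id)
  if (length(missing_ids))
    abort("alignment sample(s) missing from metadata: ",
          paste(missing_ids, collapse = ", "))
  lname <- locus_name(aln)
  scopes <- c(list(ALL_SAMPLES = ids),
              split(ids, species_of(table, ids)))
  rows <- lapply(names(scopes), function(sc) {
    sub_ids <- scopes[[sc]]
    if (length(sub_ids) >= 2L) {
      cls <- classify_sites(locus_alignment(unclass(aln)[sub_ids, , drop = FALSE],
                                            lname))
      pi <- nucleotide_diversity(aln, sub_ids)$pi
      data.frame(locus = lname, scope = sc, n_seqs = length(sub_ids),
                 n_sites = cls$n_sites, n_variable = cls$n_variable,
                 pct_variable = round_pct2(100 * cls$n_variable / cls$n_sites),
                 n_PI = unname(cls$counts["PARSIMONY_INFORMATIVE"]),
                 n_singleton = unname(cls$counts["SINGLETON_VARIABLE"]),
                 pi = pi, stringsAsFactors = FALSE)
    } else {
      data.frame(locus = lname, scope = sc, n_seqs = length(sub_ids),
                 n_sites = ncol(aln), n_variable = NA_integer_,
                 pct_variable = NA_real_, n_PI = NA_integer_,
                 n_singleton = NA_integer_, pi = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diversity_summary", "data.frame")
  out
}

#' Write diversity summaries as TSV
#' @param summaries a `diversity_summary` (or rbind of several).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_divstats <- function(summaries, path) {
  utils::write.table(as.data.frame(summaries), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
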