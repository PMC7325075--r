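## seqio: readers/writers for the formats the pipeline touches and the
## sample metadata everything downstream keys on.

#' Construct a locus alignment
#'
#' A locus alignment is a character matrix over the alphabet
#' `{A,C,G,T,N,-}` with one row per sample (rownames are sample ids, which
#' must be unique) and one column per aligned site. Characters outside the
#' alphabet are mapped to `N` with a warning; lowercase input is stored
#' uppercase.
#'
#' @param seqs named character vector of aligned sequences (one string per
#'   sample), or a character matrix with rownames.
#' @param locus_name identifier for the locus.
#' @return an object of class `locus_alignment`.
#' @examples
#' aln <- locus_alignment(c(s1 = "ACGT", s2 = "ACGA"), "demo")
#' n_sites(aln)
#' @export
locus_alignment <- function(seqs, locus_name = "locus") {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
      abort("all sequences must be named by sample id")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      abort("unaligned input: sequences have differing lengths (",
            paste(unique(lens), collapse = ", "), ")")
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(mat) <- names(seqs)
  }
  if (is.null(rownames(mat))) abort("alignment rows must be named by sample id")
  if (anyDuplicated(rownames(mat)))
    abort("duplicate sample ids in alignment: ",
          paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  if (ncol(mat) < 1L) abort("alignment must have at least one site")
  mat[] <- toupper(mat)
  bad <- !(mat %in% DNA_ALPHABET)
  if (any(bad)) {
    warning(sum(bad), " character(s) outside {A,C,G,T,N,-} mapped to N in locus '",
            locus_name, "'", call. = FALSE)
    mat[bad] <- "N"
  }
  structure(mat, class = c("locus_alignment", class(mat)),
            locus_name = locus_name)
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("Locus alignment '", attr(x, "locus_name"), "': ",
      nrow(x), " sequences x ", ncol(x), " sites\n", sep = "")
  invisible(x)
}

#' Number of aligned sites
#' @param aln a `locus_alignment`.
#' @return integer number of columns.
#' @export
n_sites <- function(aln) ncol(aln)

#' Locus name of an alignment
#' @param aln a `locus_alignment`.
#' @return character scalar.
#' @export
locus_name <- function(aln) attr(aln, "locus_name")

#' Read an aligned FASTA file as a locus alignment
#'
#' Wraps [ape::read.FASTA()] and validates the result: records must be
#' non-empty, of equal length, with unique ids. Characters outside
#' `{A,C,G,T,N,-}` (including IUPAC ambiguity codes other than N) are
#' mapped to `N` with a warning.
#'
#' @param path path to a FASTA file.
#' @param locus_name identifier for the locus (default: file name sans
#'   extension).
#' @return a `locus_alignment`.
#' @export
read_alignment <- function(path, locus_name = NULL) {
  if (!file.exists(path)) abort("FASTA file not found: ", path)
  if (is.null(locus_name))
    locus_name <- sub("\\.[^.]*$", "", basename(path))
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) abort("no FASTA records in ", path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L)
    abort("unaligned input in ", path, ": record lengths ",
          paste(unique(lens), collapse = ", "))
  chr <- toupper(do.call(rbind, as.character(dna)))
  rownames(chr) <- names(dna)
  locus_alignment(chr, locus_name = locus_name)
}

#' Write a locus alignment to FASTA
#'
#' @param aln a `locus_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  dna <- ape::as.DNAbin(unclass(aln))
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Read the sample metadata table
#'
#' The table is TSV with header columns `sample_id`, `species_id`,
#' `voucher`, then one column per locus holding 1 (amplified) or 0 (the
#' locus failed to amplify for that sample, the "x" cells of a
#' presence/absence survey table). Failed cells are kept as `FAILED`
#' rather than dropping the row, so per-species single-sample/no-data
#' bookkeeping stays computable. Accession-style voucher strings are free
#' text and are not assumed unique.
#'
#' @param path path to the TSV file.
#' @return a `sample_table`: a data.frame with columns `sample_id`,
#'   `species_id`, `voucher` and one factor-free character column per
#'   locus with values `"AMPLIFIED"`/`"FAILED"`.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) abort("metadata file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  sample_table(df)
}

#' Construct/validate a sample table
#'
#' @param df data.frame with columns `sample_id`, `species_id`, `voucher`
#'   and one column per locus containing 1/0 or `"AMPLIFIED"`/`"FAILED"`.
#' @return validated `sample_table`.
#' @export
sample_table <- function(df) {
  need <- c("sample_id", "species_id", "voucher")
  if (!all(need %in% names(df)))
    abort("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    abort("duplicate sample_id in metadata: ",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (any(is.na(df$species_id) | df$species_id == ""))
    abort("every sample must have a species_id")
  loci <- setdiff(names(df), need)
  for (lc in loci) {
    v <- df[[lc]]
    if (is.numeric(v)) {
      if (!all(v %in% c(0, 1))) abort("locus column '", lc, "' must be 0/1")
      df[[lc]] <- ifelse(v == 1, "AMPLIFIED", "FAILED")
    } else if (!all(v %in% c("AMPLIFIED", "FAILED"))) {
      abort("locus column '", lc, "' must be 0/1 or AMPLIFIED/FAILED")
    }
  }
  df$sample_id <- as.character(df$sample_id)
  df$species_id <- as.character(df$species_id)
  structure(df, class = c("sample_table", "data.frame"), loci = loci)
}

#' Loci covered by a sample table
#' @param table a `sample_table`.
#' @return character vector of locus names.
#' @export
table_loci <- function(table) attr(table, "loci")

#' Sample ids amplified for a locus
#' @param table a `sample_table`.
#' @param locus locus name (must be a column of the table).
#' @param species optional species_id to restrict to.
#' @return character vector of sample ids.
#' @export
amplified_samples <- function(table, locus, species = NULL) {
  if (!locus %in% table_loci(table))
    abort("locus '", locus, "' not in metadata (has: ",
          paste(table_loci(table), collapse = ", "), ")")
  keep <- table[[locus]] == "AMPLIFIED"
  if (!is.null(species)) keep <- keep & table$species_id %in% species
  table$sample_id[keep]
}

#' Species of given samples
#' @param table a `sample_table`.
#' @param sample_ids character vector of sample ids.
#' @return character vector of species_ids, same order.
#' @export
species_of <- function(table, sample_ids) {
  idx <- match(sample_ids, table$sample_id)
  if (anyNA(idx))
    abort("sample id(s) not in metadata: ",
          paste(sample_ids[is.na(idx)], collapse = ", "))
  table$species_id[idx]
}

#' Write a sample table as TSV
#' @param table a `sample_table`.
#' @param path output path.
#' @param binary write locus status as 1/0 instead of AMPLIFIED/FAILED.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(table, path, binary = TRUE) {
  df <- as.data.frame(table)
  if (binary)
    for (lc in table_loci(table)) df[[lc]] <- as.integer(df[[lc]] == "AMPLIFIED")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a newick tree with bootstrap supports as internal-node labels
#'
#' Internal node labels are by default interpreted as bootstrap support
#' percentages (the usual RAxML-style output) and validated to lie in
#' [0, 100]; `labels = "clade"` turns validation off and keeps labels as
#' arbitrary clade names.
#'
#' @param path path to a newick file.
#' @param labels `"support"` (default) or `"clade"`.
#' @return an [ape::phylo] tree. Leaf labels are sample ids; supports, if
#'   present, live in `tree$node.label`.
#' @export
read_newick <- function(path, labels = c("support", "clade")) {
  labels <- match.arg(labels)
  if (!file.exists(path)) abort("newick file not found: ", path)
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) abort("newick parse error in ", path,
                                             ": ", conditionMessage(e)))
  if (is.null(tree)) abort("newick parse error in ", path)
  if (anyDuplicated(tree$tip.label))
    abort("duplicate leaf labels in ", path)
  if (labels == "support" && !is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    present <- !is.na(sup)
    if (any(present & (sup < 0 | sup > 100)))
      abort("support value outside [0,100] in ", path)
  }
  tree
}

#' Write a tree to newick
#' @param tree an [ape::phylo].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
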