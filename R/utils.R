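## Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Round half away from zero
#'
#' Decimal rounding where ties go up (for non-negative input), as used for
#' the 1-decimal conflict percentages (81.25 -> 81.3). Base `round()` uses
#' round-half-to-even and would give 81.2.
#'
#' @param x numeric vector, assumed non-negative.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5 + 1e-9) / m
}

#' Two-decimal display rounding for percentages
#'
#' Percentages of variable sites are displayed to two decimals by first
#' rounding half-up to three decimals and then applying round-half-to-even
#' at the second decimal. This successive (display) rounding matches the
#' convention of the summary tables the package is designed to reproduce:
#' 100*120/654 = 18.3486 -> 18.35 and 100*158/827 = 19.1052 -> 19.10
#' (exact tie 19.105 resolved to the even digit).
#'
#' @param x numeric vector of percentages, non-negative.
#' @return numeric vector rounded for display at 2 decimals.
#' @keywords internal
round_pct2 <- function(x) {
  ## integer arithmetic at the 3rd decimal to avoid binary-float surprises
  m3 <- floor(x * 1000 + 0.5 + 1e-9)  # half-up to 3 decimals, as integer
  base <- m3 %/% 10
  d <- m3 %% 10
  up <- (d > 5) | (d == 5 & base %% 2 == 1)
  (base + as.numeric(up)) / 100
}

## stop() with call.=FALSE everywhere for clean user-facing messages
abort <- function(...) stop(..., call. = FALSE)

## derive a reproducible sub-seed (kept below 2^31) from a master seed
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2011L + as.integer(offset) %% 2011L
}

## evaluate expr with a temporary RNG state seeded by `seed`, restoring
## the caller-visible RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## numeric support values from an ape phylo's node.label ("" -> NA)
node_support_values <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(lab))
}

## list of tip-label sets, one per internal node of a (rooted) phylo,
## indexed by internal node number - Ntip. Own postorder accumulation;
## independent of ape::prop.part.
clade_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; chi <- tr$edge[k, 2]
    sets[[par]] <- c(sets[[par]], sets[[chi]])
  }
  lapply(sets[(ntip + 1):(ntip + nnode)], sort)
}
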