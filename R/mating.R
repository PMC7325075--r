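## mating: idiomorph calling from amplicon lengths, exact 1:1 segregation
## testing of single-ascospore isolates, and reproductive-mode
## classification.

#' Call a mating-type idiomorph from amplicon lengths
#'
#' The two idiomorphs amplify at characteristic lengths: MAT1-1-1 at
#' 708 bp and MAT1-2-1 between 869 and 880 bp, so gel-based length reading
#' suffices for typing. A length within `708 +/- tol` is MAT1-1 evidence;
#' within `[869 - tol, 880 + tol]`, MAT1-2 evidence. The default
#' tolerance (15 bp) keeps the two windows disjoint; a tolerance that
#' would let them overlap is rejected, as is a length matching both.
#'
#' @param amplicons numeric vector of amplicon lengths (bp), or a
#'   data.frame with a `length_bp` column.
#' @param tol half-width of the length windows (bp).
#' @return an `idiomorph_call`: list with `call` in
#'   `{MAT1_1_ONLY, MAT1_2_ONLY, BOTH, NONE}` and `evidence` (the lengths
#'   assigned to each window).
#' @examples
#' call_idiomorph(708)$call        # MAT1_1_ONLY
#' call_idiomorph(c(708, 875))$call  # BOTH
#' @export
call_idiomorph <- function(amplicons, tol = 15) {
  if (is.data.frame(amplicons)) amplicons <- amplicons$length_bp
  lens <- as.numeric(amplicons)
  if (any(lens <= 0) || anyNA(lens)) abort("amplicon lengths must be positive")
  w11 <- c(708 - tol, 708 + tol)
  w12 <- c(869 - tol, 880 + tol)
  if (w11[2] >= w12[1])
    abort("tolerance ", tol, " bp makes the idiomorph length windows overlap")
  in11 <- lens >= w11[1] & lens <= w11[2]
  in12 <- lens >= w12[1] & lens <= w12[2]
  if (any(in11 & in12))
    abort("amplicon length matching both idiomorph windows: ",
          paste(lens[in11 & in12], collapse = ", "))
  call <- if (any(in11) && any(in12)) "BOTH"
  else if (any(in11)) "MAT1_1_ONLY"
  else if (any(in12)) "MAT1_2_ONLY"
  else "NONE"
  structure(list(call = call,
                 evidence = list(mat11 = lens[in11], mat12 = lens[in12])),
            class = "idiomorph_call")
}

#' Exact two-sided binomial test of 1:1 segregation
#'
#' P-value of the observed mating-type split against Binomial(n, 1/2),
#' two-sided by tail distance: `P(|X - n/2| >= |n11 - n/2|)`, summed
#' directly over the binomial mass. For the symmetric null this agrees
#' with the usual minimum-likelihood two-sided rule.
#'
#' @param n11,n12 non-negative counts of the two mating types
#'   (`n11 + n12 >= 1`).
#' @return p-value in [0, 1].
#' @examples
#' segregation_test(10, 10)  # 1
#' segregation_test(12, 8)   # 0.5034
#' @export
segregation_test <- function(n11, n12) {
  if (n11 < 0 || n12 < 0) abort("counts must be non-negative")
  n <- n11 + n12
  if (n < 1) abort("need at least one spore")
  d <- abs(n11 - n / 2)
  k <- 0:n
  sum(stats::dbinom(k[abs(k - n / 2) >= d - 1e-9], n, 0.5))
}

#' Classify the reproductive mode of a species
#'
#' Rules, applied in order:
#' * any single-spore isolate carrying both idiomorphs =>
#'   `PUTATIVE_SECONDARY_HOMOTHALLIC` (a spore packaging both mating
#'   types);
#' * spores all single-typed, both types present, and the exact 1:1
#'   segregation test not rejected at `alpha` => `HETEROTHALLIC`;
#' * no spores, but parent tissue shows both idiomorphs =>
#'   `PRESUMED_HETEROTHALLIC` (the call available when no ascospores can
#'   be obtained);
#' * otherwise `INDETERMINATE`, with the reason recorded.
#'
#' @param strain_calls list of `idiomorph_call`s from parent tissue (may
#'   be empty).
#' @param spore_calls list of `idiomorph_call`s from single-ascospore
#'   isolates (may be empty).
#' @param alpha significance level for the segregation test (default
#'   0.05).
#' @param species_id optional identifier carried into the result.
#' @return a `segregation_result`: list with `species_id`, `n_mat11`,
#'   `n_mat12`, `p_value`, `mode_call`, `reason`.
#' @export
classify_reproductive_mode <- function(strain_calls, spore_calls,
                                       alpha = 0.05, species_id = NA_character_) {
  as_calls <- function(x) {
    if (inherits(x, "idiomorph_call")) list(x) else x
  }
  strain_calls <- as_calls(strain_calls)
  spore_calls <- as_calls(spore_calls)
  if (!length(strain_calls) && !length(spore_calls))
    abort("need at least one strain or spore idiomorph call")
  spore_types <- vapply(spore_calls, function(x) x$call, character(1))
  n11 <- sum(spore_types == "MAT1_1_ONLY")
  n12 <- sum(spore_types == "MAT1_2_ONLY")
  p <- if (n11 + n12 >= 1) segregation_test(n11, n12) else NA_real_
  parent_both <- any(vapply(strain_calls, function(x) x$call == "BOTH",
                            logical(1)))

  if (any(spore_types == "BOTH")) {
    mode <- "PUTATIVE_SECONDARY_HOMOTHALLIC"
    reason <- "spore(s) carrying both idiomorphs"
  } else if (n11 >= 1 && n12 >= 1 && !is.na(p) && p >= alpha) {
    mode <- "HETEROTHALLIC"
    reason <- sprintf("single-typed spores, 1:1 not rejected (p = %.3f)", p)
  } else if (!length(spore_calls) && parent_both) {
    mode <- "PRESUMED_HETEROTHALLIC"
    reason <- "no spores; parent tissue carries both idiomorphs"
  } else if (n11 + n12 >= 1 && (n11 == 0 || n12 == 0)) {
    mode <- "INDETERMINATE"
    reason <- "only one mating type among spores"
  } else if (!is.na(p) && p < alpha) {
    mode <- "INDETERMINATE"
    reason <- sprintf("segregation deviates from 1:1 (p = %.4g)", p)
  } else {
    mode <- "INDETERMINATE"
    reason <- "insufficient evidence"
  }
  structure(list(species_id = species_id, n_mat11 = n11, n_mat12 = n12,
                 p_value = p, mode_call = mode, reason = reason),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("%s: %d MAT1-1 : %d MAT1-2, p = %s -> %s (%s)\n",
              ifelse(is.na(x$species_id), "species", x$species_id),
              x$n_mat11, x$n_mat12,
              ifelse(is.na(x$p_value), "NA", format(x$p_value, digits = 4)),
              x$mode_call, x$reason))
  invisible(x)
}

#' Mating analysis over an isolate table
#'
#' Convenience wrapper running [classify_reproductive_mode()] per species
#' over a table of isolates.
#'
#' @param isolates data.frame with columns `isolate_id`, `species_id`,
#'   `is_spore` (logical/0-1) and either `mat11_detected`/`mat12_detected`
#'   (logical/0-1) or a `length_bp` column of amplicon lengths separated
#'   by `;`.
#' @param alpha significance level.
#' @return data.frame, one row per species: `species_id`, `n_mat11`,
#'   `n_mat12`, `p_value`, `mode_call`, `reason`.
#' @export
mating_summary <- function(isolates, alpha = 0.05) {
  need <- c("isolate_id", "species_id", "is_spore")
  if (!all(need %in% names(isolates)))
    abort("isolate table must have columns: ", paste(need, collapse = ", "))
  to_call <- function(row) {
    if ("length_bp" %in% names(isolates)) {
      lens <- as.numeric(strsplit(as.character(row[["length_bp"]]), ";")[[1]])
      call_idiomorph(lens)
    } else {
      m11 <- as.logical(as.integer(row[["mat11_detected"]]))
      m12 <- as.logical(as.integer(row[["mat12_detected"]]))
      call <- if (m11 && m12) "BOTH" else if (m11) "MAT1_1_ONLY"
      else if (m12) "MAT1_2_ONLY" else "NONE"
      structure(list(call = call, evidence = list()), class = "idiomorph_call")
    }
  }
  out <- lapply(split(isolates, isolates$species_id), function(df) {
    calls <- lapply(seq_len(nrow(df)), function(i) to_call(df[i, ]))
    is_spore <- as.logical(as.integer(df$is_spore))
    res <- classify_reproductive_mode(calls[!is_spore], calls[is_spore],
                                      alpha = alpha,
                                      species_id = df$species_id[1])
    data.frame(species_id = res$species_id, n_mat11 = res$n_mat11,
               n_mat12 = res$n_mat12, p_value = res$p_value,
               mode_call = res$mode_call, reason = res$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
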