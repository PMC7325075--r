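make_table <- function(species_map, loci, failed = NULL) {
  df <- data.frame(sample_id = names(species_map),
                   species_id = unname(species_map),
                   voucher = "-", stringsAsFactors = FALSE)
  for (lc in loci) df[[lc]] <- 1
  if (!is.null(failed))
    for (k in seq_len(nrow(failed)))
      df[df$sample_id == failed$sample_id[k], failed$locus[k]] <- 0
  sample_table(df)
}

test_that("monophyly status matches hand cases and clade enumeration", {
  tr <- ape::read.tree(text = "((a1,a2)95,(b1,b2)88)100;")
  st <- monophyly_status(tr, c("a1", "a2"))
  expect_true(st$is_monophyletic)
  expect_equal(st$support, 95)
  tr2 <- ape::read.tree(text = "((a1,b1),(a2,b2));")
  expect_false(monophyly_status(tr2, c("a1", "a2"))$is_monophyletic)
  expect_true(monophyly_status(tr2, "a1")$is_monophyletic)
  expect_true(is.na(monophyly_status(tr2, "a1")$support))
  expect_error(monophyly_status(tr2, c("a1", "zz")), "not in tree")

  set.seed(501)
  for (rep in 1:8) {
    n <- sample(5:12, 1)
    tree <- random_supported_tree(n)
    for (k in 1:6) {
      ss <- sample(tree$tip.label, sample(2:(n - 1), 1))
      got <- monophyly_status(tree, ss)$is_monophyletic
      expect_equal(got, oracle_monophyletic(tree, ss))
      expect_equal(got, ape::is.monophyletic(tree, ss))
    }
  }
})

test_that("conflict matrix states follow amplification counts and monophyly", {
  sp_tree <- ape::read.tree(text = "(((a1,a2),(b1,b2)),(c1,c2));")
  concordant <- sp_tree
  discordant <- ape::read.tree(text = "(((a1,b1),(a2,b2)),(c1,c2));")
  tab <- make_table(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B",
                      c1 = "C", c2 = "C"), c("L1", "L2"))
  m <- build_conflict_matrix(sp_tree,
                             list(L1 = concordant, L2 = concordant), tab)
  expect_true(all(m == "NO_CONFLICT"))
  expect_equal(unname(conflict_percentages(m)), c(0, 0))

  m2 <- build_conflict_matrix(sp_tree,
                              list(L1 = discordant, L2 = concordant), tab)
  expect_equal(unname(m2[, "L1"]), c("CONFLICT", "CONFLICT", "NO_CONFLICT"))

  ## single-sample and no-data bookkeeping
  tab3 <- make_table(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B",
                       c1 = "C", c2 = "C"), c("L1", "L2"),
                     failed = data.frame(sample_id = c("c2", "b1", "b2"),
                                         locus = c("L1", "L2", "L2")))
  g1 <- ape::drop.tip(concordant, "c2")
  g2 <- ape::drop.tip(concordant, c("b1", "b2"))
  m3 <- build_conflict_matrix(sp_tree, list(L1 = g1, L2 = g2), tab3)
  expect_equal(unname(m3["C", "L1"]), "SINGLE_SAMPLE")
  expect_equal(unname(m3["B", "L2"]), "NO_DATA")

  ## a FAILED sample appearing in the gene tree is a metadata inconsistency
  expect_error(build_conflict_matrix(sp_tree,
                                     list(L1 = concordant, L2 = concordant),
                                     tab3),
               "FAILED")
})

test_that("conflict percentages use the stated denominator and rounding", {
  states <- matrix("NO_CONFLICT", 20, 1,
                   dimnames = list(sprintf("s%02d", 1:20), "L"))
  states[1:6, 1] <- "CONFLICT"
  expect_equal(unname(conflict_percentages(conflict_matrix(states))), 30.0)
  st2 <- matrix(c(rep("CONFLICT", 13), rep("NO_CONFLICT", 3),
                  rep("SINGLE_SAMPLE", 4), rep("NO_DATA", 2)), 22, 1,
                dimnames = list(sprintf("s%02d", 1:22), "L"))
  expect_equal(unname(conflict_percentages(conflict_matrix(st2))), 81.3)
  st3 <- matrix(rep(c("SINGLE_SAMPLE", "NO_DATA"), 3), 6, 1,
                dimnames = list(sprintf("s%d", 1:6), "L"))
  expect_true(is.na(conflict_percentages(conflict_matrix(st3))))
})

test_that("foreign nesting is flagged for the nested sample only", {
  gt <- ape::read.tree(text =
    "(((x1,x2)99,((y1,y2,x3)97,o1)80)95,(o2,o3)90)100;")
  tab <- make_table(c(x1 = "X", x2 = "X", x3 = "X", y1 = "Y", y2 = "Y",
                      o1 = "O1", o2 = "O2", o3 = "O2"), "L1")
  calls <- flag_hybrids(NULL, gt, tab, "L1", support_min = 95)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$sample_id, "x3")
  expect_equal(calls$species_id, "X")
  expect_equal(calls$host_species, "Y")
  expect_equal(calls$support, 97)
  expect_equal(calls$evidence, "FOREIGN_NESTING")

  ## fully concordant tree: nothing to flag
  conc <- ape::read.tree(text = "(((x1,x2,x3)99,(y1,y2)98)95,(o2,o3)90)100;")
  tab2 <- make_table(c(x1 = "X", x2 = "X", x3 = "X", y1 = "Y", y2 = "Y",
                       o2 = "O2", o3 = "O2"), "L1")
  expect_equal(nrow(flag_hybrids(NULL, conc, tab2, "L1")), 0)

  ## below the support threshold: no call
  weak <- ape::read.tree(text =
    "(((x1,x2)99,((y1,y2,x3)80,o1)80)95,(o2,o3)90)100;")
  expect_equal(nrow(flag_hybrids(NULL, weak, tab, "L1", support_min = 95)), 0)
})

test_that("an unresolved two-species clade is a species merger", {
  gt <- ape::read.tree(text = "((x1,x2,y1,y2)100,((z1,z2)97,(w1,w2)96)90)0;")
  tab <- make_table(c(x1 = "X", x2 = "X", y1 = "Y", y2 = "Y",
                      z1 = "Z", z2 = "Z", w1 = "W", w2 = "W"), "L1")
  calls <- flag_hybrids(NULL, gt, tab, "L1", support_min = 95)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$evidence, "SPECIES_MERGE")
  expect_equal(calls$species_id, "X+Y")
  expect_equal(calls$support, 100)
  ## ordinary resolved sister species must not be merged
  sis <- ape::read.tree(text = "(((x1,x2)60,(y1,y2)55)100,((z1,z2)97,(w1,w2)96)90)0;")
  expect_equal(nrow(flag_hybrids(NULL, sis, tab, "L1", support_min = 95)), 0)
})

test_that("genealogy comparison finds shared and incompatible splits", {
  t1 <- ape::read.tree(text = "((a,b)90,(c,d)90,e);")
  t2 <- ape::read.tree(text = "((a,c)90,(b,d)90,e);")
  same <- compare_genealogies(t1, t1)
  expect_equal(length(same$conflicting), 0)
  expect_gte(length(same$shared), 1)
  cross <- compare_genealogies(t1, t2)
  expect_gte(length(cross$conflicting), 1)
  expect_equal(length(cross$shared), 0)
  expect_error(compare_genealogies(
    ape::read.tree(text = "((a,b)90,c);"),
    ape::read.tree(text = "((a,b)90,c);")), "intersection")
})

test_that("split incompatibility matches the four-intersection rule", {
  set.seed(502)
  for (rep in 1:10) {
    n <- sample(6:9, 1)
    t1 <- random_supported_tree(n)
    t2 <- random_supported_tree(n)
    t2$tip.label <- t1$tip.label[match(t2$tip.label, sort(t2$tip.label))]
    common <- sort(intersect(t1$tip.label, t2$tip.label))
    res <- compare_genealogies(t1, t2, threshold = 0)
    for (a in res$splitsA) {
      for (b in res$splitsB) {
        in_conflict <- any(vapply(res$conflicting, function(p)
          identical(p$a, a) && identical(p$b, b), logical(1)))
        expect_equal(!in_conflict,
                     oracle_splits_compatible(a, b, common))
      }
    }
  }
})
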