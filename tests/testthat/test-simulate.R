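test_that("species trees are ultrametric, exact-height and deterministic", {
  two <- sim_species_tree(2, 0.02, seed = 1)
  d <- ape::node.depth.edgelength(two)
  expect_equal(unname(d[1:2]), c(0.02, 0.02))

  tr <- sim_species_tree(10, 0.03, seed = 5)
  depths <- ape::node.depth.edgelength(tr)
  expect_equal(unname(depths[1:10]), rep(0.03, 10), tolerance = 1e-12)
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(sim_species_tree(10, 0.03, seed = 5)))
  expect_false(identical(ape::write.tree(tr),
                         ape::write.tree(sim_species_tree(10, 0.03, seed = 6))))
  expect_error(sim_species_tree(1, 0.02, seed = 1), ">= 2")

  ## a divergence floor is honored
  fl <- sim_species_tree(8, 0.05, seed = 9, min_divergence = 0.05)
  co <- ape::cophenetic.phylo(fl)
  expect_gte(min(co[upper.tri(co)]), 0.05 - 1e-12)
})

test_that("three-taxon Yule topologies are uniform (labeled histories)", {
  ## closed form: each of the three rooted labeled topologies on {a,b,c}
  ## has probability 1/3 under the Yule process
  outs <- vapply(1:300, function(s) {
    tr <- sim_species_tree(3, 0.02, seed = 10000 + s)
    ## identify the cherry
    pp <- ape::prop.part(tr)
    lab <- attr(pp, "labels")
    cherry <- vapply(pp, length, integer(1)) == 2
    paste(sort(lab[pp[cherry][[1]]]), collapse = "")
  }, character(1))
  tab <- table(factor(outs, levels = c("sp01sp02", "sp01sp03", "sp02sp03")))
  p <- stats::chisq.test(tab, p = rep(1 / 3, 3))$p.value
  expect_gt(p, 0.001)
})

test_that("event-free gene trees keep every species monophyletic", {
  cfg <- sim_config(n_species = 6, samples_per_species = 3,
                    loci = c(L1 = 300, L2 = 300), seed = 11)
  sp <- sim_species_tree(6, cfg$species_tree_height,
                         seed = 1, labels = cfg$species)
  gt <- sim_gene_trees(sp, cfg)
  for (lc in names(gt$gene_trees)) {
    for (spp in cfg$species) {
      ids <- gt$table$sample_id[gt$table$species_id == spp]
      expect_true(monophyly_status(gt$gene_trees[[lc]], ids)$is_monophyletic)
    }
  }
  expect_true(all(gt$truth$expected_matrix == "NO_CONFLICT"))
  expect_equal(nrow(gt$truth$expected_calls), 0)
})

test_that("planted events reshape exactly the targeted locus", {
  cfg <- sim_config(n_species = 6, samples_per_species = 3,
                    loci = c(L1 = 300, L2 = 300),
                    events = list(tip_transfer("sp02_s1", "L1", "sp05")),
                    seed = 12)
  sp <- sim_species_tree(6, cfg$species_tree_height, seed = 2,
                         labels = cfg$species)
  gt <- sim_gene_trees(sp, cfg)
  m <- gt$truth$expected_matrix
  expect_equal(unname(m["sp02", "L1"]), "CONFLICT")
  expect_true(all(m[, "L2"] == "NO_CONFLICT"))
  ## the transferred sample nests with the donor at L1 only
  calls <- gt$truth$expected_calls
  tt <- calls[calls$evidence == "FOREIGN_NESTING", ]
  expect_equal(tt$sample_id, "sp02_s1")
  expect_equal(tt$locus, "L1")
  expect_match(tt$host_species, "sp05")

  ## merged species lose their identity at the merged locus
  cfg2 <- sim_config(n_species = 6, samples_per_species = 3,
                     loci = c(L1 = 300, L2 = 300),
                     events = list(clade_merge("sp03", "sp04", "L2")),
                     seed = 13)
  gt2 <- sim_gene_trees(sim_species_tree(6, cfg2$species_tree_height, seed = 3,
                                         labels = cfg2$species), cfg2)
  calls2 <- gt2$truth$expected_calls
  expect_true("SPECIES_MERGE" %in% calls2$evidence)
  expect_equal(calls2$locus[calls2$evidence == "SPECIES_MERGE"], "L2")
  ## and their sequences at that locus are identical by construction
  a2 <- evolve_sequences(gt2$gene_trees[["L2"]], 300, seed = 99, locus = "L2")
  ids <- gt2$table$sample_id[gt2$table$species_id %in% c("sp03", "sp04")]
  expect_equal(nucleotide_diversity(a2, ids)$pi, 0)
})

test_that("total dropout empties a locus into NO_DATA", {
  cfg <- sim_config(n_species = 4, samples_per_species = 3,
                    loci = c(L1 = 200, L2 = 200),
                    dropout_prob = c(L1 = 0, L2 = 1), seed = 14)
  ds <- suppressWarnings(simulate_dataset(cfg))
  expect_null(ds$gene_trees$L2)
  expect_true(all(ds$truth$expected_matrix[, "L2"] == "NO_DATA"))
  expect_true(all(ds$table$L2 == "FAILED"))
  expect_equal(sort(unique(ds$truth$dropout$locus)), "L2")
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(1, seed = 1), ">= 2")
  expect_error(sim_config(4, base_freqs = c(A = 0.5, C = 0.5, G = 0.2,
                                            T = -0.2), seed = 1), "sum|positive")
  expect_error(sim_config(4, events = list(tip_transfer("zz", "L1", "sp02")),
                          seed = 1), "unknown sample")
  expect_error(sim_config(4, events = list(tip_transfer("sp01_s1", "L9",
                                                        "sp02")),
                          seed = 1), "unknown locus")
  expect_error(sim_config(4, events = list(clade_merge("sp01", "sp01", "L1")),
                          seed = 1), "distinct")
  expect_error(sim_config(4, dropout_prob = 1.2, seed = 1), "\\[0,1\\]")
})

test_that("HKY simulation matches its analytic expectations", {
  ## zero-length star: all sequences equal the root draw
  star <- ape::read.tree(text = "(a:0,b:0,c:0);")
  a0 <- evolve_sequences(star, 50, seed = 21)
  expect_equal(unclass(a0)["a", ], unclass(a0)["b", ], ignore_attr = TRUE)
  expect_equal(unclass(a0)["a", ], unclass(a0)["c", ], ignore_attr = TRUE)

  ## two taxa, total path 0.1: observed mismatch near the closed-form
  ## expectation computed through an independent matrix exponential
  kappa <- 2; bf <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  L <- 100000
  two <- ape::read.tree(text = "(a:0.05,b:0.05);")
  aln <- evolve_sequences(two, L, kappa = kappa, base_freqs = bf, seed = 22)
  obs <- p_distance(aln, "raw")["a", "b"]
  Q <- matrix(0.25, 4, 4)
  Q[1, 3] <- Q[3, 1] <- Q[2, 4] <- Q[4, 2] <- 0.25 * kappa
  diag(Q) <- 0; diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(0.25 * diag(Q)))
  P <- as.matrix(Matrix::expm(Q * 0.1))
  expected <- 1 - sum(0.25 * diag(P))
  se <- sqrt(expected * (1 - expected) / L)
  expect_lt(abs(obs - expected), 3 * se)

  ## root composition follows base_freqs
  bf2 <- c(A = 0.4, C = 0.3, G = 0.2, T = 0.1)
  a2 <- evolve_sequences(star, 20000, base_freqs = bf2, seed = 23)
  comp <- table(factor(unclass(a2)["a", ], levels = c("A", "C", "G", "T")))
  for (b in 1:4) {
    se_b <- sqrt(bf2[b] * (1 - bf2[b]) / 20000)
    expect_lt(abs(comp[b] / 20000 - bf2[b]), 3 * se_b)
  }

  neg <- ape::read.tree(text = "(a:-0.1,b:0.1);")
  expect_error(evolve_sequences(neg, 10, seed = 1), "negative")
  ## determinism
  expect_identical(unclass(evolve_sequences(two, 30, seed = 5)),
                   unclass(evolve_sequences(two, 30, seed = 5)))
})

test_that("datasets are written completely and reproducibly", {
  cfg <- sim_config(n_species = 5, samples_per_species = 2,
                    loci = c(locA = 120, locB = 150),
                    dropout_prob = c(locA = 0, locB = 0.2), seed = 31)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  ds <- make_dataset(cfg, d1)
  make_dataset(cfg, d2)
  for (f in c("locA.fasta", "locB.fasta", "samples.tsv", "truth.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  back <- read_alignment(file.path(d1, "locA.fasta"), "locA")
  expect_equal(n_sites(back), 120)
  expect_equal(unclass(back), unclass(ds$alignments$locA))
  tab <- read_sample_table(file.path(d1, "samples.tsv"))
  expect_equal(nrow(tab), 10)
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_true(all(c("species_tree", "gene_trees", "dropout",
                    "expected_matrix") %in% names(truth)))
})

test_that("the survey preset realizes its stated diversity magnitudes", {
  ## pooled (interspecific) pi near 0.02 and small within-species pi,
  ## checked on one locus across seeded replicate runs
  set.seed(701)
  n_runs <- 12
  ok_inter <- logical(n_runs); ok_intra <- logical(n_runs)
  for (s in seq_len(n_runs)) {
    cfg <- sim_config_preset(seed = 5000 + s)
    sp <- sim_species_tree(cfg$n_species, cfg$species_tree_height,
                           seed = 5100 + s, labels = cfg$species)
    gt <- sim_gene_trees(sp, cfg)
    a <- evolve_sequences(gt$gene_trees[["MAT1-1-1"]], 654,
                          seed = 5200 + s, locus = "MAT1-1-1")
    ok_inter[s] <- {
      pi <- nucleotide_diversity(a)$pi
      pi >= 0.010 && pi <= 0.035
    }
    intra <- c()
    for (spp in unique(gt$table$species_id)) {
      ids <- intersect(rownames(a),
                       gt$table$sample_id[gt$table$species_id == spp])
      if (length(ids) >= 2) intra <- c(intra, nucleotide_diversity(a, ids)$pi)
    }
    ok_intra[s] <- max(intra) <= 0.012
  }
  expect_gte(mean(ok_inter), 0.95)
  expect_gte(mean(ok_intra), 0.95)
})

test_that("the preset writes the configured loci and dropout shape", {
  cfg <- sim_config_preset(seed = 77)
  expect_equal(cfg$loci,
               c("MAT1-1-1" = 654, "MAT1-2-1" = 827, F1 = 755, IGS = 909))
  expect_equal(sum(lengths(split(cfg$membership$sample_id,
                                 cfg$membership$species_id))), 83)
  expect_equal(range(table(cfg$membership$species_id)), c(1, 9))
})
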