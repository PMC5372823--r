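test_that("zero contamination gives contaminated bins equal to true bins", {
  sim <- simulate_community(sim_spec(n_genomes = 3, scaffolds_per_genome = 10,
                                     contamination_rate = 0,
                                     with_sequences = FALSE, seed = 3))
  expect_equal(lapply(sim$contaminated_bins, `[[`, "members"),
               lapply(sim$true_bins, `[[`, "members"))
})

test_that("identical seeds give byte-identical community files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec <- sim_spec(n_genomes = 3, scaffolds_per_genome = 8, seed = 42)
  s1 <- simulate_community(spec)
  s2 <- simulate_community(spec)
  f1 <- write_community(s1, d1, hits = simulate_hits(s1$truth, s1$taxonomy,
                                                     seed = 42))
  f2 <- write_community(s2, d2, hits = simulate_hits(s2$truth, s2$taxonomy,
                                                     seed = 42))
  for (k in names(f1))
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]),
                     info = paste("file:", k))
  # and a different seed changes the coverage
  s3 <- simulate_community(sim_spec(n_genomes = 3, scaffolds_per_genome = 8,
                                    seed = 43))
  expect_false(identical(unclass(s1$coverage), unclass(s3$coverage)))
})

test_that("truth table covers every emitted scaffold exactly once", {
  sim <- simulate_community(sim_spec(with_sequences = FALSE, seed = 9))
  expect_setequal(sim$truth$scaffold_id, sim$scaffolds$info$id)
  expect_false(anyDuplicated(sim$truth$scaffold_id) > 0)
  # every contaminated-bin member is in the truth table with that bin
  for (b in sim$contaminated_bins) {
    rows <- sim$truth[match(b$members, sim$truth$scaffold_id), ]
    expect_true(all(rows$bin == b$bin_id))
  }
})

test_that("realized mean depth tracks the drawn genome abundance", {
  sim <- simulate_community(sim_spec(scaffolds_per_genome = 100,
                                     contamination_rate = 0,
                                     with_sequences = FALSE, seed = 21))
  for (g in rownames(sim$abundance)) {
    ids <- sim$truth$scaffold_id[sim$truth$genome == g]
    for (ds in colnames(sim$abundance)) {
      d <- unclass(sim$coverage)[ids, ds]
      # lognormal noise: E[depth] = abund * exp(sd^2/2); compare on log scale
      expected <- log(sim$abundance[g, ds])
      se <- sd(log(d)) / sqrt(length(d))
      expect_lt(abs(mean(log(d)) - expected), 3 * se + 0.05)
    }
  }
})

test_that("planted contaminants typically carry a strong differential signal", {
  # the bulk of planted contaminants separate clearly in z-difference;
  # individual ones can land closer when the bin's spread is inflated
  sim <- simulate_community(sim_spec(seed = 5, with_sequences = FALSE))
  dz <- numeric(0)
  for (b in sim$contaminated_bins) {
    za <- binpolish:::zscores(binpolish:::cov_depth(sim$coverage,
                                                    b$members, "A"))
    zb <- binpolish:::zscores(binpolish:::cov_depth(sim$coverage,
                                                    b$members, "B"))
    cont <- sim$truth$scaffold_id[sim$truth$bin == b$bin_id &
                                    sim$truth$contaminant]
    dz <- c(dz, abs(za - zb)[cont])
  }
  expect_gte(median(dz), 3)
})

test_that("contaminants at |dz| >= 3 are recovered with high recall/precision", {
  # recovery property conditioned on a clear planted signal, pooled over
  # 20 seeded communities
  tp <- 0L; fn <- 0L; fp <- 0L
  for (seed in 1:20) {
    sim <- simulate_community(sim_spec(seed = seed, with_sequences = FALSE))
    for (b in sim$contaminated_bins) {
      za <- binpolish:::zscores(binpolish:::cov_depth(sim$coverage,
                                                      b$members, "A"))
      zb <- binpolish:::zscores(binpolish:::cov_depth(sim$coverage,
                                                      b$members, "B"))
      cont <- sim$truth$scaffold_id[sim$truth$bin == b$bin_id &
                                      sim$truth$contaminant]
      strong <- cont[abs(za - zb)[cont] >= 3]
      res <- zscore_purify(b, sim$coverage, "A", "B")
      tp <- tp + sum(strong %in% res$removed)
      fn <- fn + sum(!(strong %in% res$removed))
      fp <- fp + sum(!(res$removed %in% cont))
    }
  }
  expect_gte(tp / (tp + fn), 0.9)   # recall
  expect_gte(tp / (tp + fp), 0.9)   # precision
})

test_that("simulated sequences respect per-genome GC and strain pairing", {
  sim <- simulate_community(sim_spec(n_genomes = 3, scaffolds_per_genome = 6,
                                     contamination_rate = 0,
                                     strain_pair = TRUE, seed = 13))
  gc <- gc_content(sim$scaffolds$seq)
  names(gc) <- names(sim$scaffolds$seq)
  by_gen <- split(gc[sim$truth$scaffold_id], sim$truth$genome)
  # within-genome GC spread is tight around the genome draw
  for (v in by_gen) expect_lt(max(v) - min(v), 0.1)
  # strain pair: genome 2 sequences near-identical to genome 1
  s1 <- as.character(sim$scaffolds$seq[["g1_s001"]])
  s2 <- as.character(sim$scaffolds$seq[["g2_s001"]])
  same <- mean(strsplit(s1, "")[[1]] == strsplit(s2, "")[[1]])
  expect_gte(same, 0.95)
})

test_that("simulated hits drive the expected LCA outcomes", {
  sim <- simulate_community(sim_spec(seed = 31, with_sequences = FALSE,
                                     scaffolds_per_genome = 20))
  # noise 0: every scaffold's LCA is inside its true phylum
  hits <- simulate_hits(sim$truth, sim$taxonomy, cross_phylum_noise = 0,
                        weak_evalue_frac = 0, seed = 31)
  idx <- sample(nrow(sim$truth), 30)
  for (i in idx) {
    a <- assign_scaffold_lca(hits, sim$truth$scaffold_id[i], sim$taxonomy,
                             target_phylum = sim$truth$phylum[i])
    expect_false(a$conflict)
    ph <- binpolish:::tax_ancestor_at_rank(sim$taxonomy, a$lca_node)
    expect_equal(unname(ph), sim$truth$phylum[i])
  }
  # e-values all above the cutoff: everything unassigned
  weak <- simulate_hits(sim$truth, sim$taxonomy, weak_evalue_frac = 1,
                        seed = 31)
  a <- assign_scaffold_lca(weak, sim$truth$scaffold_id[1], sim$taxonomy)
  expect_equal(a$lca_node, "unassigned")
})

test_that("conflict flags match truth under 10% cross-phylum noise", {
  sim <- simulate_community(sim_spec(seed = 55, with_sequences = FALSE))
  hits <- simulate_hits(sim$truth, sim$taxonomy, cross_phylum_noise = 0.1,
                        seed = 55)
  agree <- 0L; total <- 0L
  for (b in sim$contaminated_bins) {
    asg <- assign_bin_lca(b, hits, sim$taxonomy)
    rows <- sim$truth[match(b$members, sim$truth$scaffold_id), ]
    expected <- rows$phylum != b$target_taxon
    agree <- agree + sum(asg$conflict == expected)
    total <- total + nrow(asg)
  }
  expect_gte(agree / total, 0.95)
})

test_that("infeasible specs are rejected", {
  expect_error(sim_spec(n_genomes = 1, contamination_rate = 0.1),
               "two genomes")
  expect_error(sim_spec(contamination_rate = 1.5))
})
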