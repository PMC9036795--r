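test_that("genome-pair generation is reproducible and self-consistent", {
  a <- gen_genome_pair(seed = 4, n_chromosomes = 2, chrom_length = 20000,
                       snp_rate = 0.05, n_inversions = 1,
                       n_translocations = 1, n_contigs = 4)
  b <- gen_genome_pair(seed = 4, n_chromosomes = 2, chrom_length = 20000,
                       snp_rate = 0.05, n_inversions = 1,
                       n_translocations = 1, n_contigs = 4)
  expect_identical(a$ref, b$ref)
  expect_identical(a$query, b$query)
  expect_identical(a$matches, b$matches)
  expect_identical(a$truth, b$truth)
  # match identities equal the realised mutation fraction per contig
  truth <- a$truth[match(a$matches$query_id, a$truth$contig), ]
  len <- a$matches$target_end - a$matches$target_start
  expect_equal(a$matches$identity_fraction, 1 - truth$snps / len)
})

test_that("programmed identity shows up in the weighted-identity statistic", {
  gen <- gen_genome_pair(seed = 1, n_chromosomes = 4, chrom_length = 250000,
                         snp_rate = 0.10, n_inversions = 1,
                         n_translocations = 1, n_contigs = 8)
  wid <- weighted_identity(filter_matches(gen$matches))
  overall <- sum(wid$pct_id * wid$total_match_len) / sum(wid$total_match_len)
  expect_equal(overall, 90, tolerance = 0.5 / 90) # binomial spread at 1 Mbp
})

test_that("rearrangement-free generation maps contigs forward onto origin", {
  gen <- gen_genome_pair(seed = 10, n_chromosomes = 2, chrom_length = 20000,
                         snp_rate = 0.02, n_inversions = 0,
                         n_translocations = 0, n_contigs = 4)
  asg <- assign_contigs(gen$matches)
  expect_true(all(asg$orientation == "forward"))
  expect_equal(asg$chromosome,
               gen$truth$chromosome[match(asg$contig, gen$truth$contig)])
  one_inv <- gen_genome_pair(seed = 11, n_chromosomes = 2,
                             chrom_length = 20000, snp_rate = 0.02,
                             n_inversions = 1, n_translocations = 0,
                             n_contigs = 4)
  asg2 <- assign_contigs(one_inv$matches)
  expect_equal(sum(asg2$orientation == "reverse"), 1L)
})

test_that("generated FASTA files feed the sketch pipeline", {
  dir <- tempfile()
  gen <- gen_genome_pair(seed = 2, n_chromosomes = 2, chrom_length = 15000,
                         snp_rate = 0.01, n_inversions = 0,
                         n_translocations = 0, n_contigs = 2, dir = dir)
  expect_true(all(file.exists(gen$files)))
  D <- mash_distance_matrix(gen$files, k = 17, s = 300)
  expect_lt(D["ref", "query"], 0.02)
})

test_that("tree distance generation yields additive matrices at zero noise", {
  gen <- gen_tree_distances(seed = 7, n_taxa = 4, noise_sd = 0)
  D <- gen$D
  labs <- rownames(D)
  # four-point condition: the two largest of the three pair sums are equal
  sums <- c(D[labs[1], labs[2]] + D[labs[3], labs[4]],
            D[labs[1], labs[3]] + D[labs[2], labs[4]],
            D[labs[1], labs[4]] + D[labs[2], labs[3]])
  sums <- sort(sums, decreasing = TRUE)
  expect_equal(sums[1], sums[2], tolerance = 1e-10)
  res <- build_tree(D, n_jumbles = 2)
  expect_true(same_topology(res$tree, gen$tree))
})

test_that("the 11-taxon preset carries the expected clade structure", {
  gen <- gen_tree_distances(seed = 1, preset = "komagataella")
  expect_equal(nrow(gen$D), 11)
  expect_true(all(c("phaffii_a", "kurtzmanii", "pastoris_c", "ulmi",
                    "outgroup") %in% rownames(gen$D)))
  rooted <- ape::root(gen$tree, outgroup = "outgroup", resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, c("phaffii_a", "phaffii_b",
                                             "kurtzmanii")))
  expect_true(ape::is.monophyletic(rooted, c("pastoris_a", "pastoris_b",
                                             "pastoris_c", "ulmi")))
  expect_true(ape::is.monophyletic(rooted, c("mondaviorum", "populi",
                                             "pseudopastoris")))
})

test_that("labeling datasets regenerate identically per seed", {
  a <- gen_mfa_dataset(seed = 9, noise_sd = 0.01)
  b <- gen_mfa_dataset(seed = 9, noise_sd = 0.01)
  for (i in seq_along(a$measurements)) {
    expect_identical(a$measurements[[i]]$raw, b$measurements[[i]]$raw)
  }
  expect_identical(a$truth$flux, b$truth$flux)
})

test_that("oxPPP-zero datasets leave 6-phosphogluconate below the pentoses", {
  gen <- gen_mfa_dataset(seed = 5, scenario = flux_scenario("oxppp_zero"),
                         noise_sd = 0)
  cids <- gen$truth$cids
  for (m in c("X5P", "Ru5P", "R5P")) {
    expect_lt(cids$PG6[2], cids[[m]][2])
  }
})

test_that("50:50 QC samples correct to the Pascal row", {
  frag <- fragment_spec("qc3", "C12H30NO3Si2", 3)
  qc <- gen_qc_sample(frag, seed = 1, noise_sd = 0)
  cc <- correct_cid(qc$raw, frag)
  expect_equal(cc$ra, c(12.5, 37.5, 37.5, 12.5), tolerance = 1e-6)
  rep <- qc_pascal(cc, 3)
  expect_true(rep$pass)
})
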