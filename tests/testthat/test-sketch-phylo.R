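test_that("sketching is deterministic and canonical", {
  s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
             collapse = "")
  a <- sketch(s, k = 21, s = 200, hash_seed = 7)
  b <- sketch(s, k = 21, s = 200, hash_seed = 7)
  expect_identical(a$hashes, b$hashes)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""))
  expect_identical(sketch(rc, k = 21, s = 200, hash_seed = 7)$hashes,
                   a$hashes)
  # lowercase input hashes identically
  expect_identical(sketch(tolower(s), k = 21, s = 200, hash_seed = 7)$hashes,
                   a$hashes)
  expect_error(sketch("ACGT", k = 21), "shorter than k")
})

test_that("mash distance follows the sketch-Jaccard formula", {
  mk <- function(h) structure(list(hashes = h, k = 21L, s = 10L,
                                   hash_seed = 1, genome_id = "g"),
                              class = "kmer_sketch")
  a <- mk((1:10) / 100)
  expect_equal(mash_distance(a, a), 0)
  # merged bottom-10 of union holds hashes 1..10; 5 shared => j = 0.5
  b <- mk(c(1:5, 11:15) / 100)
  expect_equal(mash_distance(a, b), -log(2 * 0.5 / 1.5) / 21,
               tolerance = 1e-12)
  disjoint <- mk((21:30) / 100)
  expect_equal(mash_distance(a, disjoint), 1)
  bad_k <- mk((1:10) / 100); bad_k$k <- 15L
  expect_error(mash_distance(a, bad_k), "different k")
})

test_that("mash distance is a premetric on random sketches", {
  set.seed(11)
  sketches <- lapply(1:4, function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
    sketch(s, k = 15, s = 100, hash_seed = 3, genome_id = paste0("g", i))
  })
  for (i in 1:4) {
    expect_equal(mash_distance(sketches[[i]], sketches[[i]]), 0)
    for (j in 1:4) {
      dij <- mash_distance(sketches[[i]], sketches[[j]])
      expect_gte(dij, 0)
      expect_equal(dij, mash_distance(sketches[[j]], sketches[[i]]))
    }
  }
  D <- mash_distance_matrix(sketches)
  expect_true(isSymmetric(D))
  expect_equal(diag(D), setNames(rep(0, 4), paste0("g", 1:4)))
})

test_that("sketch distances shrink with sequence similarity", {
  gen <- gen_genome_pair(seed = 21, n_chromosomes = 1, chrom_length = 20000,
                         snp_rate = 0.02, n_inversions = 0,
                         n_translocations = 0, n_contigs = 1)
  ref <- sketch(gen$ref, k = 17, s = 500, genome_id = "ref")
  qry <- sketch(gen$query, k = 17, s = 500, genome_id = "qry")
  set.seed(1)
  other <- sketch(paste(sample(c("A", "C", "G", "T"), 20000, TRUE),
                        collapse = ""), k = 17, s = 500, genome_id = "rnd")
  d_close <- mash_distance(ref, qry)
  d_far <- mash_distance(ref, other)
  expect_lt(d_close, 0.05)
  expect_gt(d_far, 0.2)
})

test_that("FM branch fitting reproduces additive distances exactly", {
  set.seed(5)
  tr <- ape::rtree(4, rooted = FALSE, br = function(n) runif(n, 0.1, 1))
  D <- ape::cophenetic.phylo(tr)
  fit <- evaluate_tree(tr, D)
  expect_lt(fit$criterion, 1e-12)
  refit_D <- ape::cophenetic.phylo(fit$tree)[rownames(D), colnames(D)]
  expect_equal(refit_D, D, tolerance = 1e-6)
  # wrong topology scores strictly worse
  wrong <- read_newick(text = sprintf("((%s,%s),%s,%s);", tr$tip.label[1],
                                      tr$tip.label[2], tr$tip.label[3],
                                      tr$tip.label[4]))
  alt <- read_newick(text = sprintf("((%s,%s),%s,%s);", tr$tip.label[1],
                                    tr$tip.label[3], tr$tip.label[2],
                                    tr$tip.label[4]))
  crits <- c(evaluate_tree(wrong, D)$criterion,
             evaluate_tree(alt, D)$criterion)
  expect_gt(max(crits), 1e-6) # at least one of the alternatives is wrong
})

test_that("three-taxon star has the closed-form branch lengths", {
  D <- matrix(c(0, 3, 5, 3, 0, 4, 5, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  fit <- evaluate_tree(read_newick(text = "(a:1,b:1,c:1);"), D)
  expect_lt(fit$criterion, 1e-12)
  lens <- setNames(fit$tree$edge.length,
                   fit$tree$tip.label[fit$tree$edge[, 2]])
  expect_equal(lens[["a"]], (3 + 5 - 4) / 2)
  expect_equal(lens[["b"]], (3 + 4 - 5) / 2)
  expect_equal(lens[["c"]], (5 + 4 - 3) / 2)
})

test_that("build_tree recovers generating topologies from additive matrices", {
  for (seed in c(3, 14)) {
    gen <- gen_tree_distances(seed, n_taxa = 6, noise_sd = 0)
    res <- build_tree(gen$D, n_jumbles = 2, jumble_seed = 23893)
    expect_lt(res$criterion, 1e-12)
    expect_true(same_topology(res$tree, gen$tree))
  }
})

test_that("build_tree is deterministic for a fixed jumble seed", {
  gen <- gen_tree_distances(8, n_taxa = 6, noise_sd = 0.02)
  r1 <- build_tree(gen$D, n_jumbles = 3, jumble_seed = 23893)
  r2 <- build_tree(gen$D, n_jumbles = 3, jumble_seed = 23893)
  expect_equal(r1$criterion, r2$criterion)
  expect_identical(write_newick(r1$tree), write_newick(r2$tree))
})

test_that("fitted criterion is invariant to leaf-order permutation of D", {
  gen <- gen_tree_distances(4, n_taxa = 5, noise_sd = 0.05)
  fit1 <- evaluate_tree(gen$tree, gen$D)
  perm <- sample(rownames(gen$D))
  fit2 <- evaluate_tree(gen$tree, gen$D[perm, perm])
  expect_equal(fit1$criterion, fit2$criterion, tolerance = 1e-9)
})

test_that("zero off-diagonal distances are handled with a warning", {
  gen <- gen_tree_distances(6, n_taxa = 4, noise_sd = 0)
  D <- gen$D
  D[1, 2] <- D[2, 1] <- 0
  expect_warning(fit <- evaluate_tree(gen$tree, D), "epsilon")
  expect_true(is.finite(fit$criterion))
})
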