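mt <- function(...) match_table(...)

test_that("filter_matches applies both predicates and is idempotent", {
  tab <- mt(c("c1", "c2", "c3"), c(0, 0, 0), c(500, 1200, 15000),
            c("chr1", "chr1", "chr1"), c(0, 0, 0), c(500, 1200, 15000),
            c("+", "+", "+"), c(0.9, 0.9, 0.9), c(60L, 0L, 60L))
  kept <- filter_matches(tab, min_len = 1000, min_mapq = 1)
  expect_equal(kept$query_id, "c3")
  expect_equal(filter_matches(tab, 0, 0), tab, ignore_attr = TRUE)
  # display filter keeps only the 15 kb match
  disp <- filter_matches(tab, min_len = 10000, min_mapq = 0)
  expect_equal(nrow(disp), 1)
  # idempotence
  again <- filter_matches(kept, min_len = 1000, min_mapq = 1)
  expect_equal(again, kept, ignore_attr = TRUE)
})

test_that("weighted identity matches hand-computed values", {
  one <- mt("c", 0, 1000, "chr1", 0, 1000, "+", 0.90, 60L)
  expect_equal(weighted_identity(one)$pct_id, 90)
  two <- mt(c("c", "c"), c(0, 0), c(1000, 3000), c("chr1", "chr1"),
            c(0, 1000), c(1000, 4000), c("+", "+"), c(0.80, 1.00),
            c(60L, 60L))
  expect_equal(weighted_identity(two)$pct_id, 95)
  three <- mt(rep("c", 3), c(0, 0, 0), c(500, 1500, 2000), rep("chr1", 3),
              c(0, 500, 2000), c(500, 2000, 4000), rep("+", 3),
              c(0.90, 0.95, 0.99), rep(60L, 3))
  expect_equal(weighted_identity(three)$pct_id, 96.375)
})

test_that("weighted identity equals a per-base oracle on tiled matches", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    lens <- sample(500:5000, n)
    ids <- runif(n, 0.7, 1)
    starts <- cumsum(c(0, lens[-n]))
    tab <- mt(paste0("c", seq_len(n)), rep(0, n), lens, rep("chr1", n),
              starts, starts + lens, rep("+", n), ids, rep(60L, n))
    # per-base oracle: assign each base its match identity, average
    per_base <- rep(ids, times = lens)
    expect_equal(weighted_identity(tab)$pct_id, 100 * mean(per_base),
                 tolerance = 1e-9)
  }
})

test_that("coverage merges overlaps and is invariant under match splitting", {
  tab <- mt(c("a", "b"), c(0, 0), c(4000, 2000), c("chr1", "chr1"),
            c(0, 3000), c(4000, 5000), c("+", "+"), c(1, 1), c(60L, 60L))
  cov <- coverage_fraction(tab, c(chr1 = 10000))
  expect_equal(cov$pct_cov, 50)
  whole <- mt("a", 0, 10000, "chr1", 0, 10000, "+", 1, 60L)
  expect_equal(coverage_fraction(whole, c(chr1 = 10000))$pct_cov, 100)
  expect_equal(coverage_fraction(mt(), c(chr1 = 10000))$pct_cov, 0)
  # splitting any match into adjacent pieces leaves coverage unchanged
  split <- mt(c("a", "a", "b"), c(0, 0, 0), c(2500, 1500, 2000),
              rep("chr1", 3), c(0, 2500, 3000), c(2500, 4000, 5000),
              rep("+", 3), rep(1, 3), rep(60L, 3))
  expect_equal(coverage_fraction(split, c(chr1 = 10000))$pct_cov, 50)
  beyond <- mt("a", 0, 900, "chr1", 0, 900, "+", 1, 60L)
  expect_error(coverage_fraction(beyond, c(chr1 = 500)), "beyond")
})

test_that("contig assignment picks majority chromosome and orientation", {
  tab <- mt(rep("ctgX", 3), c(0, 0, 0), c(8000, 2000, 3000),
            c("chr2", "chr1", "chr2"), c(0, 0, 10000),
            c(8000, 2000, 13000), c("-", "+", "+"),
            rep(0.95, 3), rep(60L, 3))
  asg <- assign_contigs(tab)
  expect_equal(asg$chromosome, "chr2")
  expect_equal(asg$orientation, "reverse") # 8000 reverse vs 3000 forward
  expect_equal(asg$support_fraction, 11000 / 13000)
  expect_false(asg$ambiguous)
  single <- assign_contigs(mt("c1", 0, 5000, "chr3", 0, 5000, "+", 1, 60L))
  expect_equal(single$chromosome, "chr3")
  expect_equal(single$orientation, "forward")
  expect_equal(single$support_fraction, 1)
})

test_that("contig assignment recovers generator truth on rearranged genomes", {
  for (seed in c(2, 9, 17)) {
    gen <- gen_genome_pair(seed = seed, n_chromosomes = 3,
                           chrom_length = 30000, snp_rate = 0.05,
                           n_inversions = 2, n_translocations = 1,
                           n_contigs = 7)
    asg <- assign_contigs(filter_matches(gen$matches))
    truth <- gen$truth[match(asg$contig, gen$truth$contig), ]
    expect_equal(asg$chromosome, truth$chromosome)
    expect_equal(asg$orientation, truth$orientation)
  }
})

test_that("assembly metrics follow the N50 definition", {
  m <- assembly_metrics(c(5, 4, 3, 2, 1))
  expect_equal(m$n50, 4)
  expect_equal(m$n50_number, 2L)
  expect_equal(m$longest, 5)
  expect_equal(m$sum_top4, 14)
  one <- assembly_metrics(100)
  expect_equal(one$n50, 100)
  expect_equal(one$n50_number, 1L)
  expect_error(assembly_metrics(numeric()), "no contig")
  # invariants on random inputs
  set.seed(7)
  for (i in 1:10) {
    lens <- sample(1:10000, sample(2:30, 1))
    m <- assembly_metrics(lens)
    expect_lte(m$n50, m$longest)
    expect_lte(m$longest, m$total_size)
    expect_lte(m$sum_top4, m$total_size)
    expect_gte(m$n50_number, 1L)
  }
})

test_that("link table applies the display filter and drops matchless contigs", {
  tab <- mt(c("big", "small"), c(0, 0), c(20000, 3000), c("chr1", "chr1"),
            c(0, 30000), c(20000, 33000), c("+", "+"), c(0.99, 0.99),
            c(60L, 60L))
  links <- link_table(tab, display_min_len = 10000)
  expect_equal(links$query_id, "big")
})
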