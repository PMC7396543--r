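test_that("E-value filtering and self-hit removal behave as specified", {
  ga <- toy_genes("A", 3)
  h <- data.frame(query_id = c("A.1.g01", "A.1.g02", "A.1.g01"),
                  subject_id = c("B.1.g01", "B.1.g02", "A.1.g01"),
                  percent_identity = 80, evalue = c(1e-10, 1e-3, 1e-20),
                  bitscore = 100, stringsAsFactors = FALSE)
  expect_identical(nrow(filter_hits(h, 1e-5)), 2L)
  expect_identical(nrow(filter_hits(h[0, ], 1e-5)), 0L)
  expect_identical(nrow(filter_hits(h, 1e-5, self = TRUE)), 1L)
})

test_that("a diagonal run with one noise hit yields exactly one block", {
  # brute-force enumeration of this instance: the only chain of length >= 5
  # is x1..x5 <-> y1..y5; the x7<->y2 hit cannot extend it
  ga <- toy_genes("A", 8); gb <- toy_genes("B", 8)
  h <- toy_hits(ga, gb, c(1:5, 7), c(1:5, 2))
  bl <- find_colinear_blocks(ga, gb, h, min_block_genes = 5, max_gap = 2)
  expect_identical(nrow(bl$blocks), 1L)
  expect_identical(bl$blocks$n_pairs, 5L)
  expect_identical(bl$blocks$orientation, "parallel")
  expect_identical(bl$pairs$gene_a, ga$gene_id[1:5])
  expect_identical(bl$pairs$gene_b, gb$gene_id[1:5])
  expect_equal(oracle_best_chain_len(c(1:5, 7), c(1:5, 2), 3), 5)
})

test_that("chains below the minimum block size are discarded", {
  ga <- toy_genes("A", 8); gb <- toy_genes("B", 8)
  h <- toy_hits(ga, gb, 1:4, 1:4)
  bl <- find_colinear_blocks(ga, gb, h, min_block_genes = 5, max_gap = 2)
  expect_identical(nrow(bl$blocks), 0L)
})

test_that("reversed gene order gives one antiparallel block", {
  ga <- toy_genes("A", 8); gb <- toy_genes("B", 8)
  h <- toy_hits(ga, gb, 1:5, 8:4)
  bl <- find_colinear_blocks(ga, gb, h, min_block_genes = 5, max_gap = 2)
  expect_identical(nrow(bl$blocks), 1L)
  expect_identical(bl$blocks$orientation, "antiparallel")
  expect_identical(bl$blocks$n_pairs, 5L)
  expect_equal(oracle_longest_chain(1:5, 8:4, 3, anti = TRUE), 5)
})

test_that("swapping the two genomes transposes blocks with identical sizes", {
  set.seed(31)
  for (rep in 1:10) {
    na <- sample(6:12, 1); nb <- sample(6:12, 1)
    ga <- toy_genes("A", na); gb <- toy_genes("B", nb)
    nh <- sample(5:12, 1)
    pr <- cbind(sample(na, nh, TRUE), sample(nb, nh, TRUE))
    pr <- pr[!duplicated(pr), , drop = FALSE]
    h <- toy_hits(ga, gb, pr[, 1], pr[, 2])
    hswap <- data.frame(query_id = h$subject_id, subject_id = h$query_id,
                        percent_identity = 80, evalue = 1e-20,
                        bitscore = 100, stringsAsFactors = FALSE)
    b1 <- find_colinear_blocks(ga, gb, h, min_block_genes = 3, max_gap = 3,
                               tandem_window = 0)
    b2 <- find_colinear_blocks(gb, ga, hswap, min_block_genes = 3,
                               max_gap = 3, tandem_window = 0)
    expect_identical(sort(b1$blocks$n_pairs), sort(b2$blocks$n_pairs))
  }
})

test_that("longest chains are monotone in max_gap and block counts in min size", {
  set.seed(32)
  for (rep in 1:10) {
    ga <- toy_genes("A", 12); gb <- toy_genes("B", 12)
    pr <- cbind(sample(12, 10, TRUE), sample(12, 10, TRUE))
    pr <- pr[!duplicated(pr), , drop = FALSE]
    h <- toy_hits(ga, gb, pr[, 1], pr[, 2])
    longest <- function(gap) {
      b <- find_colinear_blocks(ga, gb, h, min_block_genes = 1,
                                max_gap = gap, tandem_window = 0)
      if (nrow(b$blocks)) max(b$blocks$n_pairs) else 0L
    }
    expect_true(longest(1) <= longest(3))
    expect_true(longest(3) <= longest(11))
    nblocks <- function(mn) {
      nrow(find_colinear_blocks(ga, gb, h, min_block_genes = mn,
                                max_gap = 3, tandem_window = 0)$blocks)
    }
    expect_true(nblocks(2) >= nblocks(4))
  }
})

test_that("each hit pair is reported in at most one block", {
  ga <- toy_genes("A", 12); gb <- toy_genes("B", 12)
  h <- toy_hits(ga, gb, c(1:6, 1:6), c(1:6, 7:12))
  bl <- find_colinear_blocks(ga, gb, h, min_block_genes = 3, max_gap = 2,
                             tandem_window = 0)
  keys <- paste(bl$pairs$gene_a, bl$pairs$gene_b)
  expect_false(anyDuplicated(keys) > 0)
})

test_that("self-comparison of a subgenome without ancient duplication yields no blocks", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 40,
                    codons_per_gene = 30, seed = 17)
  ds <- simulate_dataset(cfg)
  ah <- ds$genes[ds$genes$genome == "Ah", ]
  h <- ds$hits[ds$hits$query_id %in% ah$gene_id &
                 ds$hits$subject_id %in% ah$gene_id, ]
  bl <- find_colinear_blocks(ah, ah, filter_hits(h, 1e-5, self = TRUE),
                             self = TRUE)
  expect_identical(nrow(bl$blocks), 0L)
})

test_that("a long block on an otherwise empty chromosome pair is significant", {
  ga <- toy_genes("A", 20); gb <- toy_genes("B", 20)
  h <- toy_hits(ga, gb, 1:10, 1:10)
  bl <- find_colinear_blocks(ga, gb, h, min_block_genes = 5, max_gap = 2)
  p <- block_pvalue(bl, bl$blocks$block_id[1], n_permutations = 1000,
                    seed = 5)
  expect_lte(p, 0.05)
  # determinism under a fixed seed
  p2 <- block_pvalue(bl, bl$blocks$block_id[1], n_permutations = 1000,
                     seed = 5)
  expect_identical(p, p2)
})

test_that("a single-hit chain can never beat the permutation null", {
  ga <- toy_genes("A", 5); gb <- toy_genes("B", 5)
  h <- toy_hits(ga, gb, 3, 3)
  bl <- find_colinear_blocks(ga, gb, h, min_block_genes = 1, max_gap = 2)
  expect_identical(bl$blocks$n_pairs, 1L)
  p <- suppressWarnings(
    block_pvalue(bl, bl$blocks$block_id[1], n_permutations = 50, seed = 2))
  expect_identical(p, 1.0)
  expect_warning(score_blocks(bl, n_permutations = 50, seed = 2),
                 "fewer than 100")
})
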