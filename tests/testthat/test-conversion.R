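roles <- c("out_x", "hex_x", "out_y", "hex_y")

test_that("QC rejects gap-heavy and low-identity alignments", {
  params <- pipeline_params(bootstrap_replicates = 10)
  gappy <- quartet_alignment(setNames(c(
    paste(rep("A", 100), collapse = ""),
    paste(c(rep("-", 55), rep("A", 45)), collapse = ""),
    paste(rep("A", 100), collapse = ""),
    paste(rep("A", 100), collapse = "")), roles))
  expect_identical(qc_filter(gappy, params)$reason, "gap_fraction")

  lowid <- quartet_alignment(setNames(c(
    paste(rep("A", 100), collapse = ""),
    paste(c(rep("A", 39), rep("W", 61)), collapse = ""),
    paste(rep("A", 100), collapse = ""),
    paste(rep("A", 100), collapse = "")), roles))
  expect_identical(qc_filter(lowid, params)$reason, "low_identity")

  ok <- quartet_alignment(setNames(c(
    paste(rep("A", 100), collapse = ""),
    paste(c(rep("A", 60), rep("W", 40)), collapse = ""),
    paste(rep("A", 100), collapse = ""),
    paste(rep("A", 100), collapse = "")), roles))
  expect_true(qc_filter(ok, params)$pass)
})

test_that("distance matrix implements p-distance and Poisson correction", {
  aln <- quartet_alignment(setNames(c("AAAA", "AATT", "AAAA", "AAAA"), roles))
  d <- distance_matrix(aln, "pdist")
  expect_equal(unname(d["out_x", "hex_x"]), 0.5)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  dp <- distance_matrix(aln, "poisson")
  expect_equal(unname(dp["out_x", "hex_x"]), -log(0.5), tolerance = 1e-12)
  # saturation capping
  sat <- quartet_alignment(setNames(c("AAAA", "WWWW", "AAAA", "AAAA"), roles))
  w <- capture_warnings(dsat <- distance_matrix(sat, "poisson"))
  expect_true(any(grepl("capped", w)))
  expect_true(all(is.finite(dsat)))
})

test_that("NJ split follows the four-point condition with deterministic ties", {
  d <- matrix(10, 4, 4, dimnames = list(roles, roles))
  diag(d) <- 0
  d["out_x", "hex_x"] <- d["hex_x", "out_x"] <- 2
  d["out_y", "hex_y"] <- d["hex_y", "out_y"] <- 2
  nj <- nj_topology(d)
  expect_false(nj$tied)
  expect_identical(nj$pair1, sort(c("out_x", "hex_x")))
  expect_identical(nj$split, 1L)

  tie <- matrix(1, 4, 4, dimnames = list(roles, roles))
  diag(tie) <- 0
  njt <- nj_topology(tie)
  expect_true(njt$tied)
  expect_identical(njt$split, 2L)  # split holding the lexicographically
                                   # smallest role pair {hex_x, hex_y}
})

test_that("NJ recovers the generating split of additive matrices and matches ape", {
  skip_if_not_installed("ape")
  set.seed(41)
  for (i in 1:50) {
    split <- sample(3, 1)
    d <- oracle_additive_matrix(split, runif(4, 0.05, 1), runif(1, 0.05, 0.5))
    nj <- nj_topology(d)
    expect_false(nj$tied)
    expect_identical(nj$split, split)
    expect_identical(ape_nj_split(d), split)
  }
  # random (non-additive) matrices: agreement with ape's NJ
  for (i in 1:100) {
    d <- matrix(0, 4, 4, dimnames = list(roles, roles))
    d[upper.tri(d)] <- runif(6, 0.05, 1)
    d <- d + t(d)
    nj <- nj_topology(d)
    if (!nj$tied) expect_identical(ape_nj_split(d), nj$split)
  }
})

test_that("donor assignment follows the cross-distance rule", {
  d <- matrix(0.3, 4, 4, dimnames = list(roles, roles))
  diag(d) <- 0
  d["hex_y", "out_x"] <- d["out_x", "hex_y"] <- 0.05
  d["hex_x", "out_y"] <- d["out_y", "hex_x"] <- 0.30
  expect_identical(assign_donor(d)$donor, "hex_x")
  d2 <- d
  d2["hex_y", "out_x"] <- d2["out_x", "hex_y"] <- 0.30
  d2["hex_x", "out_y"] <- d2["out_y", "hex_x"] <- 0.05
  expect_identical(assign_donor(d2)$donor, "hex_y")
  d3 <- d
  d3["hex_x", "out_y"] <- d3["out_y", "hex_x"] <- 0.05
  expect_true(is.na(assign_donor(d3)$donor))
})

test_that("bootstrap support is high for a clean homeolog pair and reproducible", {
  set.seed(43)
  qs <- toy_quartet_seqs(n_codons = 150, converted = TRUE, post = 0)
  aln <- align_quartet(qs$protein)
  params <- pipeline_params(bootstrap_replicates = 200)
  s1 <- bootstrap_support(aln, params, target = "homeolog", seed = 7)
  s2 <- bootstrap_support(aln, params, target = "homeolog", seed = 7)
  expect_identical(s1, s2)
  expect_gt(s1, 0.9)
  # all-identical alignment: every replicate ties, nothing is supported
  ident <- quartet_alignment(setNames(rep("MKVLWAALLV", 4), roles))
  expect_identical(bootstrap_support(ident, params, "expected", seed = 1), 0)
})

test_that("classification separates expected, converted and filtered quartets", {
  params <- pipeline_params(bootstrap_replicates = 100, seed = 5)
  set.seed(47)
  qs_exp <- toy_quartet_seqs(n_codons = 200, converted = FALSE)
  call_exp <- classify_call(align_quartet(qs_exp$protein, qs_exp$cds), params,
                            "q1", "test")
  expect_identical(call_exp$status, "expected")
  expect_true(is.na(call_exp$donor_role))

  qs_conv <- toy_quartet_seqs(n_codons = 200, converted = TRUE,
                              donor = "hex_y")
  call_conv <- classify_call(align_quartet(qs_conv$protein, qs_conv$cds),
                             params, "q2", "test")
  expect_identical(call_conv$status, "converted")
  expect_identical(call_conv$donor_role, "hex_y")
  expect_identical(call_conv$acceptor_role, "hex_x")
  expect_gt(call_conv$support, 0.70)
  # converted homeolog pair is closer than either is to the opposite outgroup
  expect_lt(call_conv$ks_hex, min(call_conv$ks_hx_oy, call_conv$ks_hy_ox))

  # one sequence mostly unrelated -> filtered, no topology fields
  bad <- qs_exp$protein
  bad["hex_x"] <- paste(rep("W", nchar(bad["hex_x"])), collapse = "")
  call_bad <- classify_call(align_quartet(bad), params, "q3", "test")
  expect_identical(call_bad$status, "filtered")
  expect_identical(call_bad$filter_reason, "low_identity")
  expect_true(is.na(call_bad$topology))
  expect_true(is.na(call_bad$support))
})

test_that("raising the support threshold never increases converted calls", {
  set.seed(53)
  qs <- replicate(12, toy_quartet_seqs(n_codons = 80,
                                       converted = runif(1) < 0.5),
                  simplify = FALSE)
  count_converted <- function(min_support) {
    params <- pipeline_params(bootstrap_replicates = 100,
                              min_support = min_support, seed = 5)
    sum(vapply(seq_along(qs), function(i) {
      set.seed(1000 + i)  # same resampling at every threshold
      classify_call(align_quartet(qs[[i]]$protein), params)$status ==
        "converted"
    }, logical(1)))
  }
  n50 <- count_converted(0.50)
  n70 <- count_converted(0.70)
  n90 <- count_converted(0.90)
  expect_true(n50 >= n70 && n70 >= n90)
})
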