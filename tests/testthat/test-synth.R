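test_that("config validation enforces the evolutionary scenario", {
  expect_error(sim_config(shallow_divergence = 0.5, deep_divergence = 0.3),
               "shallow")
  expect_error(sim_config(conversion_rate = 1.2), "conversion_rate")
  expect_error(sim_config(codons_per_gene = 10), "codons_per_gene")
})

test_that("zero branch length leaves the sequence untouched and fixed seeds reproduce", {
  cds <- paste(rep("ATGGCT", 50), collapse = "")
  set.seed(7)
  expect_identical(mutate_sequence(cds, 0), cds)
  set.seed(1); a <- mutate_sequence(cds, 0.05)
  set.seed(1); b <- mutate_sequence(cds, 0.05)
  expect_identical(a, b)
  expect_error(mutate_sequence("ATGG", 0.1), "multiple of 3")
})

test_that("changed-site fraction matches the Poisson/uniform-base expectation", {
  # expectation of the process, confirmed by a 1000-replicate Monte-Carlo
  # oracle: (3/4)(1 - exp(-4b/3)) = 0.3649 at b = 0.5 (MC mean 0.3647)
  cds <- paste(rep("ATGGCT", 50), collapse = "")
  set.seed(3)
  mut <- mutate_sequence(cds, 0.5)
  obs <- mean(strsplit(cds, "")[[1]] != strsplit(mut, "")[[1]])
  expected <- 0.3649372
  tol <- 3 * sqrt(expected * (1 - expected) / nchar(cds))
  expect_lt(abs(obs - expected), tol)
})

test_that("mutation never introduces stop codons", {
  set.seed(11)
  for (i in 1:20) {
    m <- mutate_sequence(random_sense_cds(60), 0.8)
    codons <- substring(m, seq(1, nchar(m), 3), seq(3, nchar(m), 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("full-gene conversion copies the donor over the acceptor", {
  expect_identical(impose_conversion("ATGAAA", "ATGCCC"), "ATGAAA")
  expect_identical(impose_conversion("ATGAAA", "ATGAAA"), "ATGAAA")
  conv <- impose_conversion("ATGAAATTT", "ATGCCCGGG")
  expect_equal(pairwise_identity(conv, "ATGAAATTT"), 1.0)
  expect_error(impose_conversion("ATG", "ATGAAA"), "length")
})

test_that("gene counts are conserved without loss and ranks are consecutive", {
  cfg <- sim_config(n_chromosomes = 2, genes_per_chromosome = 100,
                    codons_per_gene = 30, gene_loss_rate = 0, seed = 4)
  ds <- simulate_dataset(cfg)
  counts <- table(ds$genes$genome)
  expect_true(all(counts == 200))
  for (g in unique(ds$genes$genome)) {
    for (ch in unique(ds$genes$chromosome)) {
      r <- sort(ds$genes$rank[ds$genes$genome == g & ds$genes$chromosome == ch])
      expect_identical(r, seq_along(r))
    }
  }
  # orthologous genes share rank when nothing is lost
  ah <- ds$genes[ds$genes$genome == "Ah", ]
  dd <- ds$genes[ds$genes$genome == "Dd", ]
  expect_identical(ah$rank[order(ah$locus)], dd$rank[order(dd$locus)])
  # each gene id appears once per table and once per FASTA
  expect_false(anyDuplicated(ds$genes$gene_id) > 0)
  expect_identical(sort(names(ds$cds)), sort(ds$genes$gene_id))
  expect_identical(sort(names(ds$protein)), sort(ds$genes$gene_id))
})

test_that("conversion truth counts follow the configured rate and bias", {
  cfg0 <- sim_config(n_chromosomes = 2, genes_per_chromosome = 50,
                     codons_per_gene = 30, conversion_rate = 0, seed = 9)
  expect_identical(sum(simulate_dataset(cfg0)$truth$converted), 0L)

  cfg <- sim_config(n_chromosomes = 5, genes_per_chromosome = 200,
                    codons_per_gene = 30, conversion_rate = 0.1,
                    donor_bias = 0.62, gene_loss_rate = 0, seed = 11)
  tr <- simulate_dataset(cfg)$truth
  n <- nrow(tr)
  expect_identical(n, 1000L)
  k <- sum(tr$converted)
  expect_lt(abs(k - 0.1 * n), 3 * sqrt(n * 0.1 * 0.9))
  y <- sum(tr$donor_role == "hex_y", na.rm = TRUE)
  expect_lt(abs(y - 0.62 * k), 3 * sqrt(k * 0.62 * 0.38))
  expect_true(all(is.na(tr$donor_role[!tr$converted])))
  expect_true(all(!is.na(tr$donor_role[tr$converted])))
})

test_that("truth records only reference genes present in the dataset", {
  cfg <- sim_config(n_chromosomes = 2, genes_per_chromosome = 50,
                    codons_per_gene = 30, gene_loss_rate = 0.1, seed = 21)
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$truth$anchor_id %in% ds$genes$gene_id))
  expect_true(all(ds$hits$query_id %in% ds$genes$gene_id))
  expect_true(all(ds$hits$subject_id %in% ds$genes$gene_id))
})

test_that("identical config and seed produce byte-identical output files", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 30,
                    codons_per_gene = 30, seed = 13)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("written dataset round-trips through the readers", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 30,
                    codons_per_gene = 30, seed = 14)
  ds <- simulate_dataset(cfg)
  d <- file.path(tempdir(), "ds_rt")
  write_dataset(ds, d)
  g <- read_gene_table(file.path(d, "genes_Dd.tsv"))
  expect_identical(g$gene_id, ds$genes$gene_id[ds$genes$genome == "Dd"])
  h <- read_hits(file.path(d, "hits.tsv"))
  expect_equal(nrow(h), nrow(ds$hits))
  fa <- read_fasta(file.path(d, "cds_Ah.fa"))
  ids <- ds$genes$gene_id[ds$genes$genome == "Ah"]
  expect_identical(unname(fa[ids]), unname(ds$cds[ids]))
  unlink(d, recursive = TRUE)
})
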