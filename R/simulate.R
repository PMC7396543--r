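# Synthetic allopolyploid dataset generator.
#
# The simulator emulates the genome panel used for quartet-based conversion
# calling in hexaploid wheat: a reference diploid (Dd), a second diploid
# outgroup (Ad), one tetraploid subgenome (Bt) and the three hexaploid
# subgenomes (Ah, Bh, Dh).  Every locus descends from one ancestral CDS,
# lineages A/B/D diverge deeply, each outgroup/hexaploid copy pair diverges
# shallowly, and a configurable fraction of loci carries one full-gene
# conversion between the Ah and Dh homeologs with a configurable donor bias.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, .STOP_CODONS)
}

#' Simulation configuration for the synthetic allopolyploid dataset
#'
#' Defaults encode the study conditions used throughout the package's
#' validation: 500 loci of 400 codons (the typical plant CDS length of
#' ~1.2 kb), deep divergence between the parental
#' lineages (expected 0.3 substitutions/site) against shallow
#' outgroup-vs-subgenome divergence (0.02), a 10\% whole-gene conversion
#' rate between the Ah and Dh homeologs with a 62\% bias toward the Dh copy
#' as donor, very little post-conversion divergence (0.005), and sparse
#' gene loss.
#'
#' @param n_chromosomes number of chromosomes per (sub)genome.
#' @param genes_per_chromosome loci per chromosome.
#' @param codons_per_gene codons per CDS (>= 30 so the 40\% identity / 50\%
#'   gap alignment filters are meaningful).
#' @param deep_divergence expected substitutions/site separating any two of
#'   the parental lineages (A, B, D).
#' @param shallow_divergence expected substitutions/site separating each
#'   diploid/tetraploid outgroup copy from its hexaploid subgenome copy;
#'   must be much smaller than `deep_divergence`.
#' @param conversion_rate probability that a locus carries one full-gene
#'   conversion between the two hexaploid homeologs of the canonical
#'   quartet (Ah--Dh).
#' @param donor_bias probability that the Dh (Y-role) copy is the donor,
#'   given a conversion.
#' @param post_conversion_divergence expected substitutions/site accrued by
#'   both homeolog copies after the conversion event.
#' @param gene_loss_rate per-gene probability of deletion in any one genome.
#' @param seed integer seed driving all simulation randomness.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 5L,
                       genes_per_chromosome = 100L,
                       codons_per_gene = 400L,
                       deep_divergence = 0.3,
                       shallow_divergence = 0.02,
                       conversion_rate = 0.10,
                       donor_bias = 0.62,
                       post_conversion_divergence = 0.005,
                       gene_loss_rate = 0.02,
                       seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              codons_per_gene = as.integer(codons_per_gene),
              deep_divergence = deep_divergence,
              shallow_divergence = shallow_divergence,
              conversion_rate = conversion_rate,
              donor_bias = donor_bias,
              post_conversion_divergence = post_conversion_divergence,
              gene_loss_rate = gene_loss_rate,
              seed = as.integer(seed))
  if (cfg$n_chromosomes < 1L || cfg$genes_per_chromosome < 1L)
    .stopf("config error: need at least one chromosome and one gene")
  if (cfg$codons_per_gene < 30L)
    .stopf("config error: codons_per_gene must be >= 30")
  if (!(cfg$shallow_divergence < cfg$deep_divergence))
    .stopf("config error: shallow_divergence must be < deep_divergence")
  for (f in c("conversion_rate", "donor_bias", "gene_loss_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      .stopf("config error: %s must be in [0, 1]", f)
  }
  if (cfg$deep_divergence < 0 || cfg$shallow_divergence < 0 ||
      cfg$post_conversion_divergence < 0)
    .stopf("config error: divergences must be non-negative")
  structure(cfg, class = "sim_config")
}

#' Evolve a codon sequence by a Poisson substitution process
#'
#' Draws a Poisson(branch_length x sites) number of substitution events;
#' each event picks a uniform site and a uniform alternative base
#' (a Jukes--Cantor-like process).  Events that would create a stop codon
#' are rejected and redrawn, keeping the protein translation valid, so the
#' expected number of applied substitutions per site equals `branch_length`.
#' Uses the current R random number generator state.
#'
#' @param cds codon sequence (single string, length divisible by 3).
#' @param branch_length expected substitutions per site (>= 0).
#' @return mutated codon sequence of the same length.
#' @export
mutate_sequence <- function(cds, branch_length) {
  n <- nchar(cds)
  if (n %% 3L != 0L) .stopf("format error: CDS length %d not a multiple of 3", n)
  if (branch_length < 0) .stopf("branch_length must be >= 0")
  if (branch_length == 0) return(cds)
  x <- strsplit(cds, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  n_events <- rpois(1L, branch_length * n)
  applied <- 0L
  guard <- 0L
  while (applied < n_events) {
    guard <- guard + 1L
    if (guard > 1000L * n_events + 1000L)
      .stopf("mutation rejection loop failed to terminate")
    pos <- sample.int(n, 1L)
    cur <- x[pos]
    alt <- sample(bases[bases != cur], 1L)
    c0 <- pos - (pos - 1L) %% 3L
    codon <- x[c0:(c0 + 2L)]
    codon[(pos - 1L) %% 3L + 1L] <- alt
    if (paste(codon, collapse = "") %in% .STOP_CODONS) next
    x[pos] <- alt
    applied <- applied + 1L
  }
  paste(x, collapse = "")
}

#' Impose a full-gene conversion
#'
#' Whole-gene conversion model: the acceptor sequence is overwritten by the
#' donor sequence.  Post-conversion divergence is applied separately by the
#' caller to both copies.
#'
#' @param donor_cds donor codon sequence.
#' @param acceptor_cds acceptor codon sequence (same length).
#' @return the converted acceptor sequence (a copy of the donor).
#' @export
impose_conversion <- function(donor_cds, acceptor_cds) {
  if (nchar(donor_cds) != nchar(acceptor_cds))
    .stopf("model error: donor and acceptor lengths differ (%d vs %d)",
           nchar(donor_cds), nchar(acceptor_cds))
  donor_cds
}

# fraction of identical positions between two equal-length strings
.string_identity <- function(a, b) {
  mean(strsplit(a, "", fixed = TRUE)[[1]] == strsplit(b, "", fixed = TRUE)[[1]])
}

#' Simulate a synthetic multi-(sub)genome dataset with known conversion truth
#'
#' Builds one ancestral gene per locus, evolves it along the fixed species
#' topology (lineages A, B, D separated by `deep_divergence`; within each
#' lineage the outgroup and hexaploid copies separated by
#' `shallow_divergence`), imposes whole-gene conversion on a
#' `conversion_rate` fraction of Ah--Dh homeolog pairs with donor chosen by
#' `donor_bias`, applies sparse gene loss, and emits gene-position tables,
#' CDS/protein sequences, homology hits derived from known common ancestry,
#' and a per-locus truth table.
#'
#' @param config a [sim_config()] object.
#' @return object of class `synthetic_dataset`: a list with elements
#'   `genes` (data.frame: gene_id, genome, chromosome, start, end, strand,
#'   rank, locus), `cds` and `protein` (named character vectors),
#'   `hits` (data.frame: query_id, subject_id, percent_identity, evalue,
#'   bitscore), `truth` (data.frame: anchor_id, locus, converted,
#'   donor_role, acceptor_role, donor_genome), `genomes` (data.frame:
#'   genome, role, lineage) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genomes <- data.frame(
    genome  = c("Ad", "Dd", "Bt", "Ah", "Bh", "Dh"),
    role    = c("diploid_outgroup", "reference", "tetraploid_subgenome",
                "hexaploid", "hexaploid", "hexaploid"),
    lineage = c("A", "D", "B", "A", "B", "D"),
    stringsAsFactors = FALSE)
  gl <- genomes$genome
  nchr <- config$n_chromosomes
  gpc <- config$genes_per_chromosome
  n_loci <- nchr * gpc
  sense <- .sense_codons()

  seqs <- lapply(setNames(gl, gl), function(g) character(n_loci))
  truth_conv <- logical(n_loci)
  truth_donor <- character(n_loci)   # "Ah"/"Dh"/NA

  half_deep <- config$deep_divergence / 2
  half_shallow <- config$shallow_divergence / 2

  for (locus in seq_len(n_loci)) {
    anc <- paste(sample(sense, config$codons_per_gene, replace = TRUE),
                 collapse = "")
    lin <- list(A = mutate_sequence(anc, half_deep),
                B = mutate_sequence(anc, half_deep),
                D = mutate_sequence(anc, half_deep))
    s <- vapply(gl, function(g) {
      mutate_sequence(lin[[genomes$lineage[genomes$genome == g]]], half_shallow)
    }, character(1))
    conv <- runif(1L) < config$conversion_rate
    donor_g <- NA_character_
    if (conv) {
      donor_g <- if (runif(1L) < config$donor_bias) "Dh" else "Ah"
      acceptor_g <- if (donor_g == "Dh") "Ah" else "Dh"
      s[acceptor_g] <- impose_conversion(s[donor_g], s[acceptor_g])
      s["Ah"] <- mutate_sequence(s["Ah"], config$post_conversion_divergence)
      s["Dh"] <- mutate_sequence(s["Dh"], config$post_conversion_divergence)
    }
    for (g in gl) seqs[[g]][locus] <- s[[g]]
    truth_conv[locus] <- conv
    truth_donor[locus] <- donor_g
  }

  # gene loss, drawn per genome x locus
  lost <- matrix(runif(length(gl) * n_loci) < config$gene_loss_rate,
                 nrow = length(gl), dimnames = list(gl, NULL))

  chrom_of <- rep(seq_len(nchr), each = gpc)
  idx_in_chrom <- rep(seq_len(gpc), times = nchr)
  gene_len <- 3L * config$codons_per_gene

  gene_id <- function(g, locus) {
    sprintf("%s%dg%03d", g, chrom_of[locus], idx_in_chrom[locus])
  }

  gene_tabs <- lapply(setNames(gl, gl), function(g) {
    keep <- which(!lost[g, ])
    if (!length(keep)) return(NULL)
    chrom <- chrom_of[keep]
    rank <- unlist(lapply(split(seq_along(keep), chrom), seq_along),
                   use.names = FALSE)
    data.frame(gene_id = gene_id(g, keep),
               genome = g,
               chromosome = as.character(chrom),
               start = (idx_in_chrom[keep] - 1L) * (gene_len + 1000L) + 1L,
               end = (idx_in_chrom[keep] - 1L) * (gene_len + 1000L) + gene_len,
               strand = "+",
               rank = rank,
               locus = keep,
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, gene_tabs)
  rownames(genes) <- NULL

  all_ids <- genes$gene_id
  cds <- setNames(unlist(lapply(gl, function(g) {
    keep <- which(!lost[g, ])
    seqs[[g]][keep]
  }), use.names = FALSE), all_ids)
  protein <- setNames(
    as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                       no.init.codon = TRUE)),
    all_ids)

  # homology hits: every inter-genome pair descending from the same locus,
  # both directions, identity computed from the protein sequences
  hit_rows <- vector("list", n_loci)
  for (locus in seq_len(n_loci)) {
    present <- gl[!lost[, locus]]
    if (length(present) < 2L) next
    pp <- combn(present, 2)
    q <- character(0); s <- character(0); pid <- numeric(0)
    for (k in seq_len(ncol(pp))) {
      g1 <- pp[1, k]; g2 <- pp[2, k]
      id1 <- gene_id(g1, locus); id2 <- gene_id(g2, locus)
      ident <- .string_identity(protein[[id1]], protein[[id2]])
      q <- c(q, id1, id2); s <- c(s, id2, id1)
      pid <- c(pid, ident, ident)
    }
    hit_rows[[locus]] <- data.frame(
      query_id = q, subject_id = s,
      percent_identity = round(100 * pid, 2),
      evalue = signif(10^(-pmax(20, 150 * pid)), 3),
      bitscore = round(2 * pid * config$codons_per_gene, 1),
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, hit_rows)
  rownames(hits) <- NULL

  # truth: one record per locus whose Dd anchor survives
  anchor_ok <- !lost["Dd", ]
  truth <- data.frame(
    anchor_id = gene_id("Dd", which(anchor_ok)),
    locus = which(anchor_ok),
    converted = truth_conv[anchor_ok],
    donor_role = ifelse(truth_conv[anchor_ok],
                        ifelse(truth_donor[anchor_ok] == "Dh",
                               "hex_y", "hex_x"), NA_character_),
    acceptor_role = ifelse(truth_conv[anchor_ok],
                           ifelse(truth_donor[anchor_ok] == "Dh",
                                  "hex_x", "hex_y"), NA_character_),
    donor_genome = truth_donor[anchor_ok],
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL

  structure(list(genes = genes, cds = cds, protein = protein, hits = hits,
                 truth = truth, genomes = genomes, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d genomes, %d genes, %d homology hits\n",
              nrow(x$genomes), nrow(x$genes), nrow(x$hits)))
  cat(sprintf("  truth: %d loci, %d converted\n",
              nrow(x$truth), sum(x$truth$converted)))
  invisible(x)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits one gene-position TSV, one CDS FASTA and one protein FASTA per
#' genome, plus the homology-hit and truth TSVs.
#'
#' @param ds a [simulate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in ds$genomes$genome) {
    gt <- ds$genes[ds$genes$genome == g,
                   c("gene_id", "genome", "chromosome", "start", "end",
                     "strand", "rank")]
    .write_tsv(gt, file.path(dir, sprintf("genes_%s.tsv", g)))
    ids <- ds$genes$gene_id[ds$genes$genome == g]
    .write_fasta(ds$cds[ids], file.path(dir, sprintf("cds_%s.fa", g)), "dna")
    .write_fasta(ds$protein[ids], file.path(dir, sprintf("pep_%s.fa", g)), "aa")
  }
  .write_tsv(ds$hits, file.path(dir, "hits.tsv"))
  .write_tsv(ds$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a gene-position table
#'
#' @param path TSV with columns gene_id, genome, chromosome, start, end,
#'   strand, rank.
#' @return data.frame.
#' @export
read_gene_table <- function(path) {
  df <- .read_tsv(path)
  need <- c("gene_id", "genome", "chromosome", "start", "end", "strand", "rank")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("gene table %s lacks columns: %s", path,
                           paste(miss, collapse = ", "))
  df$chromosome <- as.character(df$chromosome)
  df
}

#' Read a tabular homology-hit file
#'
#' @param path TSV with columns query_id, subject_id, percent_identity,
#'   evalue, bitscore.
#' @return data.frame.
#' @export
read_hits <- function(path) {
  df <- .read_tsv(path)
  need <- c("query_id", "subject_id", "percent_identity", "evalue", "bitscore")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("hit table %s lacks columns: %s", path,
                           paste(miss, collapse = ", "))
  df
}
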