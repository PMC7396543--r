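# Colinear (synteny) block detection between two gene orders.
#
# Hits are chained by dynamic programming over chromosome ranks: pair
# (i, j) may extend pair (i', j') iff both rank differences are in
# (0, max_gap + 1], i.e. at most max_gap intervening non-colinear genes;
# for antiparallel blocks the second-chromosome ranks must decrease.
# Significance is a within-chromosome rank-permutation test with add-one
# smoothing (same null as a random gene order).

#' Filter homology hits by E-value
#'
#' @param hits data.frame with columns query_id, subject_id,
#'   percent_identity, evalue, bitscore.
#' @param evalue_cutoff retain hits with evalue <= cutoff (default the
#'   conventional 1e-5 protein-homology cutoff).
#' @param self in self-comparison mode also drop self-hits
#'   (query_id == subject_id).
#' @return filtered data.frame.
#' @export
filter_hits <- function(hits, evalue_cutoff = 1e-5, self = FALSE) {
  if (evalue_cutoff <= 0) .stopf("evalue_cutoff must be > 0")
  keep <- hits$evalue <= evalue_cutoff
  if (self) keep <- keep & hits$query_id != hits$subject_id
  hits[keep, , drop = FALSE]
}

# collapse tandem fan-outs: within (anchor gene, other chromosome), subject
# genes whose ranks form runs with gaps <= window keep only the best bitscore
.collapse_tandem <- function(ph, side = c("b", "a"), window = 1L) {
  side <- match.arg(side)
  anchor <- if (side == "b") ph$gene_a else ph$gene_b
  chr <- if (side == "b") ph$chrom_b else ph$chrom_a
  rnk <- if (side == "b") ph$rank_b else ph$rank_a
  keep <- rep(TRUE, nrow(ph))
  grp <- paste(anchor, chr, sep = "\r")
  for (g in unique(grp[duplicated(grp)])) {
    ix <- which(grp == g)
    o <- ix[order(rnk[ix])]
    run <- cumsum(c(1L, diff(rnk[o]) > window))
    for (r in unique(run)) {
      members <- o[run == r]
      if (length(members) > 1L) {
        best <- members[order(-ph$bitscore[members], rnk[members])][1L]
        keep[setdiff(members, best)] <- FALSE
      }
    }
  }
  ph[keep, , drop = FALSE]
}

# longest-chain DP over pairs sorted by (ra, rb asc / desc).
# Returns integer chain of row indices (into ra/rb) of one best chain.
.chain_dp <- function(ra, rb, G, anti = FALSE) {
  n <- length(ra)
  if (!n) return(integer(0))
  o <- order(ra, if (anti) -rb else rb)
  sra <- ra[o]; srb <- rb[o]
  len <- integer(n); prev <- integer(n)
  for (j in seq_len(n)) {
    if (j > 1L) {
      i <- seq_len(j - 1L)
      da <- sra[j] - sra[i]
      db <- if (anti) srb[i] - srb[j] else srb[j] - srb[i]
      ok <- i[da > 0L & da <= G & db > 0L & db <= G]
    } else ok <- integer(0)
    if (length(ok)) {
      best <- ok[which.max(len[ok])]
      len[j] <- len[best] + 1L
      prev[j] <- best
    } else {
      len[j] <- 1L
      prev[j] <- 0L
    }
  }
  end <- which.max(len)  # earliest endpoint in sort order wins ties
  chain <- integer(len[end])
  k <- len[end]; cur <- end
  while (cur > 0L) { chain[k] <- cur; k <- k - 1L; cur <- prev[cur] }
  o[chain]
}

# best chain length over both orientations (used by the permutation null)
.best_chain_len <- function(ra, rb, G) {
  max(length(.chain_dp(ra, rb, G, FALSE)),
      length(.chain_dp(ra, rb, G, TRUE)))
}

#' Find colinear blocks between two gene orders
#'
#' Chains filtered homology hits into maximal colinear blocks per
#' chromosome pair and orientation by dynamic programming, then greedily
#' reports non-overlapping blocks by descending chain length (each hit pair
#' enters at most one block).  Chain score is pair count, matching the
#' gene-count block definition; blocks shorter than `min_block_genes` are
#' discarded.
#'
#' @param genes_a,genes_b gene tables (see [read_gene_table()] for columns);
#'   `genes_a` is the first/reference side.
#' @param hits filtered homology hits; hits whose ids are absent from the
#'   gene tables are dropped (or rejected when `strict`).
#' @param min_block_genes minimum colinear genes per block (default 5).
#' @param max_gap maximum intervening non-colinear genes between
#'   consecutive block members (default 50).
#' @param self self-comparison mode: self-hits and mirrored duplicate pairs
#'   are removed before chaining.
#' @param tandem_window tandem-array collapse: among hits from one gene to
#'   a run of near-adjacent genes (rank gaps <= window) on one chromosome,
#'   only the best-scoring hit enters the DP.
#' @param strict error (instead of dropping) when a hit references an
#'   unknown gene id.
#' @return object of class `colinear_blocks`: list with `blocks`
#'   (block_id, genome_a, genome_b, chrom_a, chrom_b, orientation, n_pairs,
#'   p_value) and `pairs` (block_id, gene_a, gene_b, rank_a, rank_b).
#'   `p_value` is NA until [score_blocks()] is run.
#' @export
find_colinear_blocks <- function(genes_a, genes_b, hits,
                                 min_block_genes = 5L, max_gap = 50L,
                                 self = FALSE, tandem_window = 1L,
                                 strict = FALSE) {
  G <- as.integer(max_gap) + 1L
  ia <- match(hits$query_id, genes_a$gene_id)
  ib <- match(hits$subject_id, genes_b$gene_id)
  known <- !is.na(ia) & !is.na(ib)
  if (strict && !all(known))
    .stopf("input error: %d hits reference unknown gene ids", sum(!known))
  ph <- data.frame(gene_a = hits$query_id[known],
                   gene_b = hits$subject_id[known],
                   chrom_a = genes_a$chromosome[ia[known]],
                   chrom_b = genes_b$chromosome[ib[known]],
                   rank_a = genes_a$rank[ia[known]],
                   rank_b = genes_b$rank[ib[known]],
                   bitscore = hits$bitscore[known],
                   stringsAsFactors = FALSE)
  if (self) {
    ph <- ph[ph$gene_a != ph$gene_b, , drop = FALSE]
    # keep one of each mirrored pair, oriented by (chrom, rank)
    fwd <- (ph$chrom_a < ph$chrom_b) |
      (ph$chrom_a == ph$chrom_b & ph$rank_a < ph$rank_b)
    key <- ifelse(fwd, paste(ph$gene_a, ph$gene_b), paste(ph$gene_b, ph$gene_a))
    ph <- ph[fwd & !duplicated(key[fwd]), , drop = FALSE]
  }
  ph <- ph[!duplicated(paste(ph$gene_a, ph$gene_b)), , drop = FALSE]
  if (nrow(ph)) {
    ph <- .collapse_tandem(ph, "b", tandem_window)
    ph <- .collapse_tandem(ph, "a", tandem_window)
  }

  blocks <- list(); pair_rows <- list(); dp_input <- list()
  if (nrow(ph)) {
    ph <- ph[order(ph$chrom_a, ph$chrom_b, ph$rank_a, ph$rank_b), ]
    cp_key <- paste(ph$chrom_a, ph$chrom_b, sep = "\r")
    for (cp in unique(cp_key)) {
      sub <- ph[cp_key == cp, , drop = FALSE]
      dp_input[[cp]] <- list(
        chrom_a = sub$chrom_a[1L], chrom_b = sub$chrom_b[1L],
        rank_a = sub$rank_a, rank_b = sub$rank_b,
        n_b = sum(genes_b$chromosome == sub$chrom_b[1L]))
      avail <- rep(TRUE, nrow(sub))
      repeat {
        idx <- which(avail)
        if (length(idx) < min_block_genes) break
        best_chain <- integer(0); best_anti <- FALSE
        for (anti in c(FALSE, TRUE)) {
          ch <- .chain_dp(sub$rank_a[idx], sub$rank_b[idx], G, anti)
          if (length(ch) > length(best_chain)) {
            best_chain <- idx[ch]; best_anti <- anti
          }
        }
        if (length(best_chain) < min_block_genes) break
        blocks[[length(blocks) + 1L]] <- data.frame(
          genome_a = genes_a$genome[1L], genome_b = genes_b$genome[1L],
          chrom_a = sub$chrom_a[1L], chrom_b = sub$chrom_b[1L],
          orientation = if (best_anti) "antiparallel" else "parallel",
          n_pairs = length(best_chain),
          first_rank = sub$rank_a[best_chain[1L]],
          stringsAsFactors = FALSE)
        pair_rows[[length(pair_rows) + 1L]] <-
          sub[best_chain, c("gene_a", "gene_b", "rank_a", "rank_b")]
        avail[best_chain] <- FALSE
      }
    }
  }

  if (!length(blocks)) {
    bl <- data.frame(block_id = character(0), genome_a = character(0),
                     genome_b = character(0), chrom_a = character(0),
                     chrom_b = character(0), orientation = character(0),
                     n_pairs = integer(0), p_value = numeric(0),
                     stringsAsFactors = FALSE)
    pr <- data.frame(block_id = character(0), gene_a = character(0),
                     gene_b = character(0), rank_a = integer(0),
                     rank_b = integer(0), stringsAsFactors = FALSE)
    out <- list(blocks = bl, pairs = pr)
  } else {
    bl <- do.call(rbind, blocks)
    ord <- order(bl$chrom_a, bl$chrom_b, -bl$n_pairs, bl$first_rank)
    bl <- bl[ord, , drop = FALSE]
    bl$block_id <- sprintf("%s_%s_B%04d", bl$genome_a, bl$genome_b,
                           seq_len(nrow(bl)))
    pr <- do.call(rbind, lapply(seq_along(ord), function(i) {
      cbind(block_id = bl$block_id[i], pair_rows[[ord[i]]],
            stringsAsFactors = FALSE)
    }))
    bl$p_value <- NA_real_
    bl$first_rank <- NULL
    bl <- bl[, c("block_id", "genome_a", "genome_b", "chrom_a", "chrom_b",
                 "orientation", "n_pairs", "p_value")]
    rownames(bl) <- NULL; rownames(pr) <- NULL
    out <- list(blocks = bl, pairs = pr)
  }
  attr(out, "dp_input") <- dp_input
  attr(out, "max_gap") <- as.integer(max_gap)
  class(out) <- "colinear_blocks"
  out
}

#' @export
print.colinear_blocks <- function(x, ...) {
  cat(sprintf("colinear_blocks: %d blocks, %d gene pairs\n",
              nrow(x$blocks), nrow(x$pairs)))
  invisible(x)
}

#' Permutation significance of colinear blocks
#'
#' For each block, permutes the rank assignment of the second genome's
#' genes within the block's chromosome, recomputes the best chain length on
#' that chromosome pair (either orientation), and reports the add-one
#' smoothed tail probability
#' `p = (1 + #\{permutation best >= n_pairs\}) / (1 + n_permutations)`.
#'
#' @param bl a [find_colinear_blocks()] result.
#' @param n_permutations permutation replicates (default 200; a
#'   warning is signalled below 100).
#' @param seed integer seed for reproducible permutations (NULL uses the
#'   current RNG state).
#' @return `bl` with the `p_value` column filled.
#' @export
score_blocks <- function(bl, n_permutations = 200L, seed = NULL) {
  stopifnot(inherits(bl, "colinear_blocks"))
  if (n_permutations < 100L)
    warning("fewer than 100 permutations: p-values are coarse")
  if (!is.null(seed)) set.seed(seed)
  if (!nrow(bl$blocks)) return(bl)
  dp <- attr(bl, "dp_input")
  G <- attr(bl, "max_gap") + 1L
  cp_key <- paste(bl$blocks$chrom_a, bl$blocks$chrom_b, sep = "\r")
  for (cp in unique(cp_key)) {
    inp <- dp[[cp]]
    n_b <- max(inp$n_b, max(inp$rank_b))
    best <- integer(n_permutations)
    for (r in seq_len(n_permutations)) {
      perm <- sample.int(n_b)
      best[r] <- .best_chain_len(inp$rank_a, perm[inp$rank_b], G)
    }
    for (i in which(cp_key == cp)) {
      np <- bl$blocks$n_pairs[i]
      bl$blocks$p_value[i] <- (1 + sum(best >= np)) / (1 + n_permutations)
    }
  }
  bl
}

#' Permutation p-value of a single colinear block
#'
#' Convenience wrapper around [score_blocks()] for one block.
#'
#' @param bl a [find_colinear_blocks()] result.
#' @param block_id block to score.
#' @inheritParams score_blocks
#' @return the permutation p-value in (0, 1].
#' @export
block_pvalue <- function(bl, block_id, n_permutations = 200L, seed = NULL) {
  scored <- score_blocks(bl, n_permutations, seed)
  ix <- match(block_id, scored$blocks$block_id)
  if (is.na(ix)) .stopf("unknown block_id: %s", block_id)
  scored$blocks$p_value[ix]
}

#' Read colinear blocks from TSV files
#'
#' Rebuilds a `colinear_blocks` object from the two TSVs written by
#' [write_blocks()].  The permutation inputs are not reconstructed, so
#' [score_blocks()] cannot be re-run on the result; the stored p-values
#' are preserved.
#'
#' @param blocks_path,pairs_path the block-level and gene-pair TSVs.
#' @return a `colinear_blocks` object.
#' @export
read_blocks <- function(blocks_path, pairs_path) {
  out <- list(blocks = .read_tsv(blocks_path), pairs = .read_tsv(pairs_path))
  out$blocks$chrom_a <- as.character(out$blocks$chrom_a)
  out$blocks$chrom_b <- as.character(out$blocks$chrom_b)
  class(out) <- "colinear_blocks"
  out
}

#' Write colinear blocks to TSV files
#'
#' @param bl a [find_colinear_blocks()] result.
#' @param blocks_path,pairs_path output TSVs (block level and gene-pair
#'   level).
#' @return invisibly, the block data.frame.
#' @export
write_blocks <- function(bl, blocks_path, pairs_path) {
  .write_tsv(bl$blocks, blocks_path)
  .write_tsv(bl$pairs, pairs_path)
  invisible(bl$blocks)
}
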