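# End-to-end pipeline: simulate (or load) -> colinearity -> alignment table
# -> quartets -> conversion calls -> summary, plus truth-table scoring.

#' Default quartet comparisons for the simulated genome panel
#'
#' The three between-subgenome comparisons of the hexaploid: A vs D with
#' the diploid outgroups, A vs B and B vs D with the tetraploid B as the
#' missing diploid's stand-in outgroup.
#'
#' @return named list of [comparison_spec()] objects.
#' @export
default_comparisons <- function() {
  list(
    AdAhDdDh = comparison_spec("AdAhDdDh", out_x = "Ad", hex_x = "Ah",
                               out_y = "Dd", hex_y = "Dh"),
    AdAhBtBh = comparison_spec("AdAhBtBh", out_x = "Ad", hex_x = "Ah",
                               out_y = "Bt", hex_y = "Bh"),
    BtBhDdDh = comparison_spec("BtBhDdDh", out_x = "Bt", hex_x = "Bh",
                               out_y = "Dd", hex_y = "Dh"))
}

#' Run the conversion-detection pipeline on a dataset
#'
#' Filters hits, detects and scores colinear blocks of every genome against
#' the reference, builds the alignment table, extracts quartets for the
#' requested comparisons and calls conversion.
#'
#' @param ds a [simulate_dataset()] result (or an equivalent list with
#'   `genes`, `cds`, `protein`, `hits`, `genomes` elements).
#' @param params [pipeline_params()].
#' @param comparisons list of [comparison_spec()] (default
#'   [default_comparisons()] restricted to available genomes).
#' @param evalue_cutoff homology E-value cutoff (default 1e-5).
#' @param min_block_genes,max_gap colinearity chaining parameters
#'   (defaults 5 and 50).
#' @param alpha keep blocks with permutation p <= alpha (default 0.05).
#' @param n_permutations permutation replicates per block (default 200).
#' @return list: dataset, blocks (per genome), table, quartets, calls,
#'   summary.
#' @export
analyze_dataset <- function(ds, params = pipeline_params(),
                            comparisons = NULL,
                            evalue_cutoff = 1e-5, min_block_genes = 5L,
                            max_gap = 50L, alpha = 0.05,
                            n_permutations = 200L) {
  ref_genome <- ds$genomes$genome[ds$genomes$role == "reference"][1L]
  others <- setdiff(ds$genomes$genome, ref_genome)
  hits <- filter_hits(ds$hits, evalue_cutoff)
  ref_genes <- ds$genes[ds$genes$genome == ref_genome, ]
  blocks <- list()
  for (g in others) {
    gg <- ds$genes[ds$genes$genome == g, ]
    h <- hits[hits$query_id %in% ref_genes$gene_id &
                hits$subject_id %in% gg$gene_id, ]
    bl <- find_colinear_blocks(ref_genes, gg, h,
                               min_block_genes = min_block_genes,
                               max_gap = max_gap)
    bl <- score_blocks(bl, n_permutations = n_permutations,
                       seed = params$seed)
    sig <- bl$blocks$block_id[bl$blocks$p_value <= alpha]
    bl$pairs <- bl$pairs[bl$pairs$block_id %in% sig, , drop = FALSE]
    bl$blocks <- bl$blocks[bl$blocks$block_id %in% sig, , drop = FALSE]
    blocks[[g]] <- bl
  }
  tab <- build_alignment_table(ref_genes, blocks)
  if (is.null(comparisons)) {
    comparisons <- Filter(function(cs) {
      all(c(cs$out_x, cs$hex_x, cs$out_y, cs$hex_y) %in% names(tab))
    }, default_comparisons())
  }
  quartets <- do.call(rbind, lapply(comparisons, extract_quartets, tab = tab))
  rownames(quartets) <- NULL
  calls <- call_conversions(quartets, ds$cds, ds$protein, params)
  list(dataset = ds, blocks = blocks, table = tab, quartets = quartets,
       calls = calls, summary = summarize_by_comparison(calls))
}

#' Simulate a dataset and run the full pipeline
#'
#' @param config a [sim_config()].
#' @param params [pipeline_params()].
#' @param ... further arguments to [analyze_dataset()].
#' @return the [analyze_dataset()] result, with the truth scoring of the
#'   canonical Ad/Ah/Dd/Dh comparison attached as `truth_scores`.
#' @export
run_pipeline <- function(config = sim_config(), params = pipeline_params(),
                         ...) {
  ds <- simulate_dataset(config)
  res <- analyze_dataset(ds, params, ...)
  if ("AdAhDdDh" %in% res$calls$comparison)
    res$truth_scores <- score_against_truth(res$calls, res$quartets, ds$truth)
  res
}

#' Score conversion calls against the simulator truth table
#'
#' Joins the canonical Ad/Ah/Dd/Dh quartets to the truth table via the
#' reference (Dd) anchor gene and reports recovery metrics.
#'
#' @param calls data.frame from [call_conversions()].
#' @param quartets data.frame from [extract_quartets()].
#' @param truth the `truth` element of a [simulate_dataset()] result.
#' @param comparison comparison label to score (default `"AdAhDdDh"`).
#' @return list: n_scored, n_true_converted, sensitivity, false_call_rate,
#'   donor_accuracy, donor_split_y (fraction of called conversions with the
#'   Y-role donor), n_called_converted.
#' @export
score_against_truth <- function(calls, quartets, truth,
                                comparison = "AdAhDdDh") {
  q <- quartets[quartets$comparison == comparison, ]
  cc <- calls[match(q$quartet_id, calls$quartet_id), ]
  tr <- truth[match(q$gene_out_y, truth$anchor_id), ]
  ok <- !is.na(tr$anchor_id)
  cc <- cc[ok, ]; tr <- tr[ok, ]
  called <- cc$status == "converted"
  pos <- tr$converted
  tp <- called & pos
  donor_match <- cc$donor_role[tp] == tr$donor_role[tp]
  list(n_scored = nrow(cc),
       n_true_converted = sum(pos),
       n_called_converted = sum(called),
       sensitivity = if (sum(pos)) sum(tp) / sum(pos) else NA_real_,
       false_call_rate = if (sum(!pos)) sum(called & !pos) / sum(!pos)
                         else NA_real_,
       donor_accuracy = if (sum(tp)) mean(donor_match) else NA_real_,
       donor_split_y = if (sum(called)) mean(cc$donor_role[called] == "hex_y")
                       else NA_real_)
}

#' Write pipeline outputs as TSV files
#'
#' Emits the block, pair, alignment-table, quartet, call and summary TSVs
#' with stable formatting, so identical runs are byte-identical.
#'
#' @param res a [run_pipeline()] / [analyze_dataset()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(res$blocks)) {
    write_blocks(res$blocks[[g]],
                 file.path(dir, sprintf("blocks_%s.tsv", g)),
                 file.path(dir, sprintf("block_pairs_%s.tsv", g)))
  }
  .write_tsv(as.data.frame(res$table), file.path(dir, "alignment_table.tsv"))
  .write_tsv(res$quartets, file.path(dir, "quartets.tsv"))
  .write_tsv(res$calls, file.path(dir, "calls.tsv"))
  .write_tsv(res$summary, file.path(dir, "summary.tsv"))
  invisible(dir)
}
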