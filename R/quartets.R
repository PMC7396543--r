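# Reference-anchored alignment table and homologous gene quartets.

#' Build a reference-anchored multi-genome alignment table
#'
#' One row per reference gene in (chromosome, rank) order; one column per
#' aligned genome.  A cell is filled when the reference gene participates
#' in a significant colinear block pair with that genome, and is NA (gap)
#' otherwise.  When a reference gene is covered by several blocks of the
#' same genome, the pair from the block with the smaller p-value wins
#' (then larger n_pairs, then lexicographic block_id); the same priority
#' resolves a subject gene claimed by two rows, so every gene id appears in
#' at most one cell.
#'
#' @param reference_genes gene table of the reference genome.
#' @param blocks_list named list (genome label -> [find_colinear_blocks()]
#'   result pairing the reference with that genome, typically filtered to
#'   significant blocks).
#' @return data.frame of class `alignment_table`: columns ref_id,
#'   ref_chrom, ref_rank, a column named after the reference genome
#'   (identical to ref_id) and one column per aligned genome.
#' @export
build_alignment_table <- function(reference_genes, blocks_list) {
  ref <- reference_genes[order(reference_genes$chromosome,
                               reference_genes$rank), ]
  ref_genome <- ref$genome[1L]
  tab <- data.frame(ref_id = ref$gene_id,
                    ref_chrom = ref$chromosome,
                    ref_rank = ref$rank,
                    stringsAsFactors = FALSE)
  tab[[ref_genome]] <- ref$gene_id
  for (g in names(blocks_list)) {
    bl <- blocks_list[[g]]
    col <- rep(NA_character_, nrow(tab))
    if (nrow(bl$pairs)) {
      pr <- bl$pairs
      # orient so gene_a is the reference side
      if (!any(pr$gene_a %in% tab$ref_id) && any(pr$gene_b %in% tab$ref_id)) {
        pr <- data.frame(block_id = pr$block_id, gene_a = pr$gene_b,
                         gene_b = pr$gene_a, rank_a = pr$rank_b,
                         rank_b = pr$rank_a, stringsAsFactors = FALSE)
      }
      meta <- bl$blocks[match(pr$block_id, bl$blocks$block_id), ]
      o <- order(meta$p_value, -meta$n_pairs, meta$block_id,
                 pr$rank_a, pr$rank_b)
      pr <- pr[o, ]
      used_subject <- character(0)
      for (k in seq_len(nrow(pr))) {
        row <- match(pr$gene_a[k], tab$ref_id)
        if (is.na(row)) next
        if (!is.na(col[row])) next
        if (pr$gene_b[k] %in% used_subject) next
        col[row] <- pr$gene_b[k]
        used_subject <- c(used_subject, pr$gene_b[k])
      }
    }
    tab[[g]] <- col
  }
  dup <- unlist(tab[, -(1:3)], use.names = FALSE)
  dup <- dup[!is.na(dup)]
  if (anyDuplicated(dup))
    .stopf("consistency error: gene id claimed by two cells: %s",
           dup[duplicated(dup)][1L])
  class(tab) <- c("alignment_table", "data.frame")
  tab
}

#' A quartet comparison specification
#'
#' Maps the four quartet roles to genome columns of the alignment table:
#' two polyploid homeologs (`hex_x`, `hex_y`) and each one's
#' diploid/tetraploid outgroup ortholog (`out_x`, `out_y`).
#'
#' @param label comparison label carried into calls and summaries.
#' @param out_x,hex_x,out_y,hex_y genome column names.
#' @return named list of class `comparison_spec`.
#' @export
comparison_spec <- function(label, out_x, hex_x, out_y, hex_y) {
  structure(list(label = label, out_x = out_x, hex_x = hex_x,
                 out_y = out_y, hex_y = hex_y),
            class = "comparison_spec")
}

#' Extract homologous gene quartets from an alignment table
#'
#' Emits one quartet per table row where all four role cells are filled;
#' rows with any gap (gene loss) are skipped and never called.
#'
#' @param tab an [build_alignment_table()] result.
#' @param comparison a [comparison_spec()].
#' @return data.frame: quartet_id, comparison, gene_out_x, gene_hex_x,
#'   gene_out_y, gene_hex_y, ref_id (sorted by reference rank).
#' @export
extract_quartets <- function(tab, comparison) {
  stopifnot(inherits(comparison, "comparison_spec"))
  roles <- c("out_x", "hex_x", "out_y", "hex_y")
  cols <- vapply(roles, function(r) comparison[[r]], character(1))
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    .stopf("config error: unknown role column(s): %s",
           paste(miss, collapse = ", "))
  cells <- as.data.frame(tab)[, cols, drop = FALSE]
  ok <- rowSums(is.na(cells)) == 0L
  q <- data.frame(quartet_id = sprintf("%s_Q%05d", comparison$label,
                                       seq_len(sum(ok))),
                  comparison = comparison$label,
                  gene_out_x = cells[ok, 1L],
                  gene_hex_x = cells[ok, 2L],
                  gene_out_y = cells[ok, 3L],
                  gene_hex_y = cells[ok, 4L],
                  ref_id = tab$ref_id[ok],
                  stringsAsFactors = FALSE)
  rownames(q) <- NULL
  q
}

#' Extract within-subgenome paralog quartets (ancient WGD duplicates)
#'
#' For each colinear paralog pair detected by self-comparison of one
#' subgenome (descendants of the grass-common whole-genome duplication),
#' looks up each locus's outgroup ortholog in the alignment table and emits
#' a quartet only when both orthologs exist.
#'
#' @param self_blocks a [find_colinear_blocks()] result computed in
#'   self-comparison mode on the subgenome.
#' @param tab an [build_alignment_table()] result.
#' @param subgenome alignment-table column of the subgenome.
#' @param outgroup alignment-table column of the matching
#'   diploid/tetraploid outgroup.
#' @param label comparison label (default `<outgroup><subgenome>_cWGD`).
#' @return data.frame in the [extract_quartets()] layout, with the two
#'   paralogous loci as hex_x / hex_y and their outgroup orthologs as
#'   out_x / out_y.
#' @export
extract_paralog_quartets <- function(self_blocks, tab, subgenome, outgroup,
                                     label = NULL) {
  if (is.null(label)) label <- paste0(outgroup, subgenome, "_cWGD")
  if (!all(c(subgenome, outgroup) %in% names(tab)))
    .stopf("config error: unknown role column(s)")
  sub_col <- tab[[subgenome]]
  out_col <- tab[[outgroup]]
  ortho_of <- function(g) {
    row <- match(g, sub_col)
    if (is.na(row)) NA_character_ else out_col[row]
  }
  pr <- self_blocks$pairs
  rows <- list()
  for (k in seq_len(nrow(pr))) {
    g1 <- pr$gene_a[k]; g2 <- pr$gene_b[k]
    o1 <- ortho_of(g1); o2 <- ortho_of(g2)
    if (is.na(o1) || is.na(o2)) next
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = label, gene_out_x = o1, gene_hex_x = g1,
      gene_out_y = o2, gene_hex_y = g2,
      ref_id = NA_character_, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(quartet_id = character(0), comparison = character(0),
                      gene_out_x = character(0), gene_hex_x = character(0),
                      gene_out_y = character(0), gene_hex_y = character(0),
                      ref_id = character(0), stringsAsFactors = FALSE))
  q <- do.call(rbind, rows)
  q <- cbind(quartet_id = sprintf("%s_Q%05d", label, seq_len(nrow(q))), q,
             stringsAsFactors = FALSE)
  rownames(q) <- NULL
  q
}
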