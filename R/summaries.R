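# Summary tables: conversion counts/percents, donor splits, ortho-group
# support, and GO enrichment of converted genes against the colinear
# background.

#' Percentage string from a count ratio
#'
#' `100 * num / den`, rounded half-away-from-zero to two decimals and
#' rendered with two decimal places, the convention of the conversion
#' summary tables.
#'
#' @param num,den numerator and denominator counts.
#' @return list(raw = numeric, string = character).
#' @export
percent_2dp <- function(num, den) {
  if (den == 0) return(list(raw = NA_real_, string = ""))
  raw <- 100 * num / den
  list(raw = raw, string = sprintf("%.2f", round_half_up(raw, 2)))
}

#' Donor-split percentages
#'
#' Splits conversion donor counts of the two roles into a pair of
#' percentages of their total, rounded half-away-from-zero to two
#' decimals.
#'
#' @param c1,c2 donor counts (role X, role Y), not both zero.
#' @return numeric vector of two percentages; c(NA, NA) when both counts
#'   are zero (rendered empty downstream).
#' @export
donor_split_percent <- function(c1, c2) {
  tot <- c1 + c2
  if (tot == 0) return(c(NA_real_, NA_real_))
  round_half_up(c(100 * c1 / tot, 100 * c2 / tot), 2)
}

#' Summarize conversion calls per comparison
#'
#' `n_quartets` counts the quartets entering calling (non-filtered);
#' `n_converted` the converted calls; percentages and donor splits follow
#' the two-decimal half-up convention.
#'
#' @param calls data.frame from [call_conversions()].
#' @return data.frame: comparison, n_quartets, n_converted,
#'   percent_converted (2-decimal string), percent_converted_raw,
#'   donor_x, donor_y, donor_percent_x, donor_percent_y.
#' @export
summarize_by_comparison <- function(calls) {
  out <- lapply(split(calls, calls$comparison), function(cc) {
    nq <- sum(cc$status != "filtered")
    nc <- sum(cc$status == "converted")
    pc <- percent_2dp(nc, nq)
    dx <- sum(cc$donor_role == "hex_x", na.rm = TRUE)
    dy <- sum(cc$donor_role == "hex_y", na.rm = TRUE)
    dp <- donor_split_percent(dx, dy)
    data.frame(comparison = cc$comparison[1L],
               n_quartets = nq, n_converted = nc,
               percent_converted = pc$string,
               percent_converted_raw = pc$raw,
               donor_x = dx, donor_y = dy,
               donor_percent_x = dp[1L], donor_percent_y = dp[2L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Ortho-group support of colinear gene pairs
#'
#' A pair is supported when both genes map to the same cluster id
#' (OrthoMCL-style ortho-group membership); genes missing from the cluster
#' table count as unsupported.
#'
#' @param pairs data.frame with columns gene_a, gene_b (e.g. the `pairs`
#'   element of [find_colinear_blocks()]).
#' @param clusters data.frame with columns gene_id, cluster_id.
#' @return list(n_pairs, n_supported, percent) with percent rounded
#'   half-up to two decimals.
#' @export
orthogroup_support_percent <- function(pairs, clusters) {
  ca <- clusters$cluster_id[match(pairs$gene_a, clusters$gene_id)]
  cb <- clusters$cluster_id[match(pairs$gene_b, clusters$gene_id)]
  supported <- !is.na(ca) & !is.na(cb) & ca == cb
  n <- nrow(pairs)
  list(n_pairs = n, n_supported = sum(supported),
       percent = if (n > 0) round_half_up(100 * sum(supported) / n, 2) else NA_real_)
}

#' Two-sided Fisher exact (hypergeometric) p-value of a 2x2 table
#'
#' The two-sided convention sums all tables with the fixed margins whose
#' hypergeometric probability does not exceed the observed table's; for a
#' fixed-margin 2x2 table this is the hypergeometric test.
#'
#' @param a,b,c,d cell counts (row 1 = a, b; row 2 = c, d).
#' @return p-value in (0, 1].
#' @export
fisher_2x2_p <- function(a, b, c, d) {
  fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
}

#' GO enrichment of converted genes against a background set
#'
#' Per category, a 2x2 table (converted vs not, within the background,
#' crossed with in-category vs not) is scored with the two-sided Fisher
#' exact (hypergeometric) test; raw p-values are the headline output (a
#' Benjamini-Hochberg column `p_bh` is added as a labelled extension).
#' Categories with no background gene are skipped.
#'
#' @param converted character vector of converted gene ids (must be a
#'   subset of `background`).
#' @param background character vector of background gene ids (e.g. all
#'   colinear genes).
#' @param annotation data.frame with columns gene_id, go_id and optionally
#'   category (top-level GO category label).
#' @return data.frame sorted by p: go_id, category, n_converted_in,
#'   n_converted, n_background_in, n_background, direction, p_value, p_bh.
#' @export
go_enrichment <- function(converted, background, annotation) {
  converted <- unique(converted)
  background <- unique(background)
  if (!all(converted %in% background))
    .stopf("input error: converted genes absent from background")
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  if (!nrow(ann))
    return(data.frame(go_id = character(0), category = character(0),
                      n_converted_in = integer(0), n_converted = integer(0),
                      n_background_in = integer(0), n_background = integer(0),
                      direction = character(0), p_value = numeric(0),
                      p_bh = numeric(0), stringsAsFactors = FALSE))
  has_cat <- "category" %in% names(ann)
  n_conv <- length(converted)
  n_bg <- length(background)
  rows <- lapply(split(ann, ann$go_id), function(a) {
    genes_in <- unique(a$gene_id)
    a_in <- sum(converted %in% genes_in)
    bg_in <- length(genes_in)
    p <- fisher_2x2_p(a_in, n_conv - a_in,
                      bg_in - a_in, (n_bg - n_conv) - (bg_in - a_in))
    prop_conv <- a_in / n_conv
    prop_rest <- (bg_in - a_in) / (n_bg - n_conv)
    data.frame(go_id = a$go_id[1L],
               category = if (has_cat) a$category[1L] else NA_character_,
               n_converted_in = a_in, n_converted = n_conv,
               n_background_in = bg_in, n_background = n_bg,
               direction = if (prop_conv >= prop_rest) "enriched" else "depleted",
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$go_id), ]
  rownames(out) <- NULL
  out
}
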