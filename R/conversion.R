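# Per-quartet conversion calling: QC, distances, NJ topology, bootstrap
# support, topology classification and donor assignment.
#
# The expected quartet topology pairs each polyploid copy with its own
# outgroup ortholog; the aberrant topology pairs the two homeologs, the
# signature of conversion.  An aberrant split is accepted as conversion
# only when its bootstrap support exceeds min_support, and the donor is the
# copy whose outgroup the acceptor has moved toward.

#' Conversion-calling parameters
#'
#' @param max_gap_fraction discard an alignment when any sequence has more
#'   than this fraction of gap sites (default 0.5).
#' @param min_identity discard an alignment when the minimum over the six
#'   pairwise amino-acid identities falls below this (default 0.40).
#' @param bootstrap_replicates column-resampling replicates (default 1000).
#' @param min_support strict bootstrap threshold: an aberrant topology is
#'   called converted only with support > min_support (default 0.70).
#' @param distance_model `"pdist"` (default, 1 - identity) or `"poisson"`
#'   (-ln(1 - p) correction).
#' @param seed integer seed consumed by [call_conversions()] for the
#'   bootstrap resampling.
#' @return list of class `pipeline_params`.
#' @export
pipeline_params <- function(max_gap_fraction = 0.5, min_identity = 0.40,
                            bootstrap_replicates = 1000L, min_support = 0.70,
                            distance_model = c("pdist", "poisson"),
                            seed = 1L) {
  distance_model <- match.arg(distance_model)
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1,
            min_identity >= 0, min_identity <= 1,
            bootstrap_replicates >= 1, min_support >= 0, min_support <= 1)
  structure(list(max_gap_fraction = max_gap_fraction,
                 min_identity = min_identity,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 min_support = min_support,
                 distance_model = distance_model,
                 seed = as.integer(seed)),
            class = "pipeline_params")
}

#' Pairwise identity of two aligned sequences
#'
#' Matches divided by the number of columns where both sequences are
#' non-gap; 0 when no such column exists.
#'
#' @param seq1,seq2 aligned sequences of equal length (`-` for gaps).
#' @return fraction in \[0, 1\].
#' @export
pairwise_identity <- function(seq1, seq2) {
  if (nchar(seq1) != nchar(seq2))
    .stopf("aligned lengths differ (%d vs %d)", nchar(seq1), nchar(seq2))
  a <- strsplit(seq1, "", fixed = TRUE)[[1]]
  b <- strsplit(seq2, "", fixed = TRUE)[[1]]
  both <- a != "-" & b != "-"
  if (!any(both)) return(0)
  sum(a[both] == b[both]) / sum(both)
}

#' Quality-control filter for a quartet alignment
#'
#' Fails with reason `gap_fraction` when any sequence's gap count exceeds
#' `max_gap_fraction` of the alignment length, or with `low_identity` when
#' the minimum of the six pairwise identities falls below `min_identity`
#' (strictest reading of the identity rule).
#'
#' @param aln a [quartet_alignment()].
#' @param params [pipeline_params()].
#' @return list(pass = TRUE) or list(pass = FALSE, reason = ...).
#' @export
qc_filter <- function(aln, params = pipeline_params()) {
  stopifnot(inherits(aln, "quartet_alignment"))
  L <- aln$length
  gaps <- vapply(aln$proteins,
                 function(s) sum(strsplit(s, "", fixed = TRUE)[[1]] == "-"),
                 integer(1))
  if (any(gaps > params$max_gap_fraction * L))
    return(list(pass = FALSE, reason = "gap_fraction"))
  cmb <- combn(4L, 2L)
  ids <- apply(cmb, 2L, function(p)
    pairwise_identity(aln$proteins[[p[1L]]], aln$proteins[[p[2L]]]))
  if (min(ids) < params$min_identity)
    return(list(pass = FALSE, reason = "low_identity"))
  list(pass = TRUE)
}

.dist_from_p <- function(p, model) {
  if (model == "pdist") return(p)
  pc <- pmin(p, 1 - 1e-6)
  if (any(p >= 1 - 1e-6))
    warning("Poisson distance capped at p = 1 - 1e-6")
  -log(1 - pc)
}

#' Pairwise distance matrix of a quartet alignment
#'
#' p-distance (1 - pairwise identity) or its Poisson correction
#' `-ln(1 - p)`, capped at p = 1 - 1e-6 with a warning.
#'
#' @param aln a [quartet_alignment()].
#' @param model `"pdist"` or `"poisson"`.
#' @return symmetric 4x4 matrix with zero diagonal, dimnames = roles.
#' @export
distance_matrix <- function(aln, model = c("pdist", "poisson")) {
  model <- match.arg(model)
  d <- matrix(0, 4, 4, dimnames = list(.QUARTET_ROLES, .QUARTET_ROLES))
  cmb <- combn(4L, 2L)
  for (k in seq_len(ncol(cmb))) {
    i <- cmb[1L, k]; j <- cmb[2L, k]
    p <- 1 - pairwise_identity(aln$proteins[[i]], aln$proteins[[j]])
    d[i, j] <- d[j, i] <- .dist_from_p(p, model)
  }
  d
}

# the three unrooted splits of taxa 1..4, as pairs partnered with taxon 1
.SPLITS <- list(c(2L, 3L, 4L),  # {1,2 | 3,4}
                c(3L, 2L, 4L),  # {1,3 | 2,4}
                c(4L, 2L, 3L))  # {1,4 | 2,3}

.split_pairs <- function(k, taxa) {
  s <- .SPLITS[[k]]
  list(sort(c(taxa[1L], taxa[s[1L]])), sort(c(taxa[s[2L]], taxa[s[3L]])))
}

# split sums d(pair1) + d(pair2); minimizing this is equivalent to the NJ
# Q-criterion for four taxa
.split_sums <- function(d) {
  c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
}

#' Neighbor-joining topology of a four-taxon distance matrix
#'
#' Runs the first neighbor-joining agglomeration step (minimum of the NJ
#' Q-matrix), which for four taxa fixes the unrooted split.  Ties (several
#' Q-minimal pairs implying different splits) are flagged and broken toward
#' the split containing the lexicographically smallest taxon pair.
#'
#' @param d symmetric non-negative 4x4 matrix with zero diagonal;
#'   dimnames give taxon names (defaults to the quartet roles).
#' @return list: `pair1`, `pair2` (character vectors of the joined taxa),
#'   `split` (index 1:3 in the fixed split order), `tied` (logical),
#'   `qmin` (the minimal Q value).
#' @export
nj_topology <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == 4L, ncol(d) == 4L)
  if (is.null(rownames(d))) dimnames(d) <- list(.QUARTET_ROLES, .QUARTET_ROLES)
  taxa <- rownames(d)
  r <- rowSums(d)
  n <- 4L
  cmb <- combn(n, 2L)
  q <- apply(cmb, 2L, function(p)
    (n - 2) * d[p[1L], p[2L]] - r[p[1L]] - r[p[2L]])
  qmin <- min(q)
  cand <- which(q <= qmin + 1e-12)
  # split index implied by each candidate join
  split_of_pair <- function(i, j) {
    pr <- sort(c(i, j))
    if (all(pr == c(1L, 2L)) || all(pr == c(3L, 4L))) 1L
    else if (all(pr == c(1L, 3L)) || all(pr == c(2L, 4L))) 2L
    else 3L
  }
  splits <- vapply(cand, function(k)
    split_of_pair(cmb[1L, k], cmb[2L, k]), integer(1))
  tied <- length(unique(splits)) > 1L
  if (tied) {
    # split containing the lexicographically smallest taxon pair
    keys <- vapply(unique(splits), function(s) {
      prs <- .split_pairs(s, taxa)
      min(paste(prs[[1L]], collapse = "|"), paste(prs[[2L]], collapse = "|"))
    }, character(1))
    split <- unique(splits)[order(keys)][1L]
  } else split <- splits[1L]
  prs <- .split_pairs(split, taxa)
  list(pair1 = prs[[1L]], pair2 = prs[[2L]], split = split, tied = tied,
       qmin = qmin)
}

# topology label for quartet roles
.topology_label <- function(nj) {
  lab <- c("expected", "homeolog", "cross")
  lab[nj$split]
}

#' Bootstrap support for a quartet split
#'
#' Resamples alignment columns with replacement (alignment-length draws per
#' replicate), recomputes the distance matrix and NJ split per replicate,
#' and returns the fraction of replicates whose (untied) split equals the
#' target.  Tied replicates are counted as unsupported.
#'
#' @param aln a [quartet_alignment()].
#' @param params [pipeline_params()] (replicates and distance model).
#' @param target target split: `"expected"` (each copy with its own
#'   outgroup), `"homeolog"` (the two polyploid copies together) or
#'   `"cross"`.
#' @param seed optional seed (NULL consumes the current RNG state, as done
#'   by [call_conversions()]).
#' @return support fraction in \[0, 1\].
#' @export
bootstrap_support <- function(aln, params = pipeline_params(),
                              target = c("homeolog", "expected", "cross"),
                              seed = NULL) {
  target <- match.arg(target)
  if (!is.null(seed)) set.seed(seed)
  L <- aln$length
  B <- params$bootstrap_replicates
  ch <- t(vapply(aln$proteins, function(s) strsplit(s, "", fixed = TRUE)[[1]],
                 character(L)))
  cmb <- combn(4L, 2L)
  idx <- matrix(sample.int(L, L * B, replace = TRUE), nrow = L, ncol = B)
  # per replicate pairwise p-distances
  pmat <- matrix(0, ncol(cmb), B)
  for (k in seq_len(ncol(cmb))) {
    a <- ch[cmb[1L, k], ]; b <- ch[cmb[2L, k], ]
    m <- (a == b) & a != "-" & b != "-"
    ng <- a != "-" & b != "-"
    msum <- colSums(matrix(m[idx], nrow = L))
    nsum <- colSums(matrix(ng[idx], nrow = L))
    p <- ifelse(nsum > 0, 1 - msum / nsum, 1)
    pmat[k, ] <- suppressWarnings(.dist_from_p(p, params$distance_model))
  }
  # rows of cmb: (1,2) (1,3) (1,4) (2,3) (2,4) (3,4)
  s1 <- pmat[1, ] + pmat[6, ]
  s2 <- pmat[2, ] + pmat[5, ]
  s3 <- pmat[3, ] + pmat[4, ]
  s <- rbind(s1, s2, s3)
  smin <- apply(s, 2L, min)
  is_min <- sweep(s, 2L, smin + 1e-12, "<=")
  untied <- colSums(is_min) == 1L
  ti <- match(target, c("expected", "homeolog", "cross"))
  mean(untied & is_min[ti, ])
}

#' Assign donor and acceptor for an aberrant quartet
#'
#' The acceptor copy was overwritten by the donor, so it resembles the
#' donor's outgroup ortholog: donor = hex_x when
#' d(hex_y, out_x) < d(hex_x, out_y), donor = hex_y on the reverse
#' inequality, undetermined on exact equality.
#'
#' @param d role-named 4x4 distance matrix.
#' @return list(donor, acceptor) with values `"hex_x"`/`"hex_y"` or both
#'   NA when undetermined.
#' @export
assign_donor <- function(d) {
  a <- d["hex_y", "out_x"]
  b <- d["hex_x", "out_y"]
  if (a < b) list(donor = "hex_x", acceptor = "hex_y")
  else if (b < a) list(donor = "hex_y", acceptor = "hex_x")
  else list(donor = NA_character_, acceptor = NA_character_)
}

#' Classify one quartet alignment into a conversion call
#'
#' QC failure gives status `filtered`.  Otherwise the NJ split of the
#' protein distance matrix is computed: the expected split gives
#' `expected`; the homeolog (aberrant) split with bootstrap support
#' strictly above `min_support` and a determined donor gives `converted`;
#' anything else (low support, the outgroup-crossing split, ties,
#' undetermined donor) is `unresolved`.
#'
#' @param aln a [quartet_alignment()] (with CDS for Ks annotation).
#' @param params [pipeline_params()].
#' @param quartet_id,comparison identifiers carried into the call row.
#' @return one-row data.frame: quartet_id, comparison, status,
#'   filter_reason, topology, tied, support, donor_role, acceptor_role and
#'   Ks columns (NA where not applicable).
#' @export
classify_call <- function(aln, params = pipeline_params(),
                          quartet_id = NA_character_,
                          comparison = NA_character_) {
  row <- data.frame(quartet_id = quartet_id, comparison = comparison,
                    status = NA_character_, filter_reason = NA_character_,
                    topology = NA_character_, tied = NA,
                    support = NA_real_,
                    donor_role = NA_character_, acceptor_role = NA_character_,
                    ks_hex = NA_real_, ka_hex = NA_real_,
                    ks_hx_ox = NA_real_, ks_hy_oy = NA_real_,
                    ks_hx_oy = NA_real_, ks_hy_ox = NA_real_,
                    stringsAsFactors = FALSE)
  qc <- qc_filter(aln, params)
  if (!qc$pass) {
    row$status <- "filtered"
    row$filter_reason <- qc$reason
    return(row)
  }
  d <- distance_matrix(aln, params$distance_model)
  nj <- nj_topology(d)
  row$topology <- .topology_label(nj)
  row$tied <- nj$tied
  row$support <- bootstrap_support(aln, params, target = row$topology)
  if (!is.null(aln$cds)) {
    kpair <- function(r1, r2) ks_nei_gojobori(aln$cds[[r1]], aln$cds[[r2]])
    kh <- kpair("hex_x", "hex_y")
    row$ks_hex <- kh$ks; row$ka_hex <- kh$ka
    row$ks_hx_ox <- kpair("hex_x", "out_x")$ks
    row$ks_hy_oy <- kpair("hex_y", "out_y")$ks
    row$ks_hx_oy <- kpair("hex_x", "out_y")$ks
    row$ks_hy_ox <- kpair("hex_y", "out_x")$ks
  }
  if (nj$tied) {
    row$status <- "unresolved"
  } else if (row$topology == "expected") {
    row$status <- "expected"
  } else if (row$topology == "homeolog" && row$support > params$min_support) {
    don <- assign_donor(d)
    if (is.na(don$donor)) {
      row$status <- "unresolved"
    } else {
      row$status <- "converted"
      row$donor_role <- don$donor
      row$acceptor_role <- don$acceptor
    }
  } else {
    row$status <- "unresolved"
  }
  row
}

#' Call conversion over a table of quartets
#'
#' Aligns each quartet's proteins, threads the CDS, and classifies the
#' call.  Seeds the RNG once from `params$seed` so the whole run is
#' reproducible.
#'
#' @param quartets data.frame from [extract_quartets()].
#' @param cds,proteins named character vectors covering all quartet genes.
#' @param params [pipeline_params()].
#' @return data.frame of calls, one row per quartet.
#' @export
call_conversions <- function(quartets, cds, proteins,
                             params = pipeline_params()) {
  set.seed(params$seed)
  rows <- vector("list", nrow(quartets))
  for (i in seq_len(nrow(quartets))) {
    ids <- c(out_x = quartets$gene_out_x[i], hex_x = quartets$gene_hex_x[i],
             out_y = quartets$gene_out_y[i], hex_y = quartets$gene_hex_y[i])
    miss <- ids[!(ids %in% names(proteins)) | !(ids %in% names(cds))]
    if (length(miss))
      .stopf("missing sequence(s) for quartet %s: %s",
             quartets$quartet_id[i], paste(miss, collapse = ", "))
    aln <- align_quartet(setNames(proteins[ids], names(ids)),
                         setNames(cds[ids], names(ids)))
    rows[[i]] <- classify_call(aln, params,
                               quartet_id = quartets$quartet_id[i],
                               comparison = quartets$comparison[i])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
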