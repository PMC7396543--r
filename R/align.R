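# Progressive protein alignment of a quartet with codon threading.
#
# Internal progressive aligner with fixed BLOSUM62 / affine-gap parameters
# (open 10, extend 0.5) so alignments are fully reproducible: the six
# global pairwise alignments pick the most-similar pair as the first join,
# the remaining two sequences form the second profile, and a
# profile-profile merge produces the final four-way alignment.
# Externally produced alignments can be supplied through
# `quartet_alignment()`.

.blosum62 <- function() {
  if (is.null(.hc_cache$blosum62)) {
    e <- new.env()
    data("BLOSUM62", package = "Biostrings", envir = e)
    .hc_cache$blosum62 <- e$BLOSUM62
  }
  .hc_cache$blosum62
}

.encode_aa <- function(s, alphabet) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  code <- match(ch, alphabet) - 1L
  bad <- is.na(code) & ch != "-"
  if (any(bad))
    .stopf("format error: invalid residue symbol(s): %s",
           paste(unique(ch[bad]), collapse = ""))
  code[ch == "-"] <- NA_integer_
  code
}

.QUARTET_ROLES <- c("out_x", "hex_x", "out_y", "hex_y")

#' Construct a quartet alignment object from aligned sequences
#'
#' Wraps four equal-length aligned protein sequences (and optionally the
#' codon-threaded CDS alignment) keyed by role, validating lengths and the
#' protein/CDS correspondence.  Use this to import an externally produced
#' alignment instead of [align_quartet()].
#'
#' @param proteins named character vector of aligned proteins
#'   (roles out_x, hex_x, out_y, hex_y; `-` for gaps).
#' @param cds optional named character vector of aligned CDS (gap codons
#'   `---`), threaded codon-by-codon through the protein alignment.
#' @return object of class `quartet_alignment`.
#' @export
quartet_alignment <- function(proteins, cds = NULL) {
  if (!all(.QUARTET_ROLES %in% names(proteins)))
    .stopf("proteins must be named by roles: %s",
           paste(.QUARTET_ROLES, collapse = ", "))
  proteins <- proteins[.QUARTET_ROLES]
  L <- unique(nchar(proteins))
  if (length(L) != 1L) .stopf("aligned proteins differ in length")
  if (!is.null(cds)) {
    cds <- cds[.QUARTET_ROLES]
    if (any(nchar(cds) != 3L * L))
      .stopf("aligned CDS length must be 3x the protein alignment length")
  }
  structure(list(proteins = proteins, cds = cds, length = L),
            class = "quartet_alignment")
}

# thread unaligned CDS through a gapped protein string
.thread_cds <- function(aligned_prot, cds) {
  ch <- strsplit(aligned_prot, "", fixed = TRUE)[[1]]
  n_res <- sum(ch != "-")
  if (nchar(cds) != 3L * n_res)
    .stopf("format error: CDS length %d does not match %d residues",
           nchar(cds), n_res)
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  out <- rep("---", length(ch))
  out[ch != "-"] <- codons
  paste(out, collapse = "")
}

#' Progressively align the four protein sequences of a quartet
#'
#' @param proteins named character vector (roles out_x, hex_x, out_y,
#'   hex_y) of unaligned protein sequences.
#' @param cds optional named character vector of the matching unaligned CDS
#'   (length 3x protein length), threaded through the protein alignment.
#' @param gap_open,gap_ext affine gap parameters of the BLOSUM62 scoring.
#' @return a [quartet_alignment()] object.
#' @export
align_quartet <- function(proteins, cds = NULL, gap_open = 10, gap_ext = 0.5) {
  if (!all(.QUARTET_ROLES %in% names(proteins)))
    .stopf("proteins must be named by roles: %s",
           paste(.QUARTET_ROLES, collapse = ", "))
  proteins <- proteins[.QUARTET_ROLES]
  if (any(nchar(proteins) == 0L)) .stopf("empty protein sequence")
  sm <- .blosum62()
  alphabet <- rownames(sm)
  enc <- lapply(proteins, .encode_aa, alphabet = alphabet)
  prof <- lapply(enc, function(e) matrix(e, nrow = 1L))

  pw_score <- function(i, j)
    nw_profile_align(prof[[i]], prof[[j]], sm, gap_open, gap_ext)$score

  cmb <- combn(4L, 2L)
  scores <- apply(cmb, 2L, function(p) pw_score(p[1L], p[2L]))
  best <- cmb[, which.max(scores)]          # ties: first pair in role order
  rest <- setdiff(1:4, best)

  merge_profiles <- function(pa, pb) {
    al <- nw_profile_align(pa$mat, pb$mat, sm, gap_open, gap_ext)
    take <- function(mat, cols) {
      out <- matrix(NA_integer_, nrow = nrow(mat), ncol = length(cols))
      nz <- cols > 0L
      out[, nz] <- mat[, cols[nz], drop = FALSE]
      out
    }
    list(mat = rbind(take(pa$mat, al$cols1), take(pb$mat, al$cols2)),
         rows = c(pa$rows, pb$rows))
  }
  pA <- merge_profiles(list(mat = prof[[best[1L]]], rows = best[1L]),
                       list(mat = prof[[best[2L]]], rows = best[2L]))
  pB <- merge_profiles(list(mat = prof[[rest[1L]]], rows = rest[1L]),
                       list(mat = prof[[rest[2L]]], rows = rest[2L]))
  full <- merge_profiles(pA, pB)

  mat <- full$mat[order(full$rows), , drop = FALSE]
  aligned <- apply(mat, 1L, function(code) {
    ch <- ifelse(is.na(code), "-", alphabet[code + 1L])
    paste(ch, collapse = "")
  })
  names(aligned) <- .QUARTET_ROLES
  cds_aln <- NULL
  if (!is.null(cds)) {
    cds <- cds[.QUARTET_ROLES]
    cds_aln <- setNames(mapply(.thread_cds, aligned, cds), .QUARTET_ROLES)
  }
  quartet_alignment(aligned, cds_aln)
}
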