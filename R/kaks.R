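# Nei-Gojobori (1986) synonymous / nonsynonymous substitution estimation.
#
# Synonymous site counts per codon are the per-position fractions of the
# three alternative bases that preserve the amino acid (changes to stop
# codons count as nonsynonymous); observed differences are averaged with
# equal weight over all substitution orders (pathways) of multi-difference
# codon pairs, excluding pathways passing through a stop codon (when every
# pathway does, all pathways are used).  Jukes-Cantor correction:
# K = -(3/4) ln(1 - (4/3) p); p >= 3/4 is reported as saturated (NA).

.codon_tables <- function() {
  if (!is.null(.hc_cache$codon)) return(.hc_cache$codon)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  bases <- c("A", "C", "G", "T")
  n <- length(codons)
  aa <- unname(gc)

  syn_sites <- setNames(numeric(n), codons)
  for (c1 in codons) {
    if (gc[[c1]] == "*") next
    s <- 0
    for (pos in 1:3) {
      cur <- substr(c1, pos, pos)
      for (b in bases[bases != cur]) {
        c2 <- c1
        substr(c2, pos, pos) <- b
        if (gc[[c2]] != "*" && gc[[c2]] == gc[[c1]]) s <- s + 1 / 3
      }
    }
    syn_sites[c1] <- s
  }

  # pathway-averaged synonymous / nonsynonymous difference counts
  sd <- matrix(0, n, n, dimnames = list(codons, codons))
  nd <- matrix(0, n, n, dimnames = list(codons, codons))
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    c1 <- codons[i]; c2 <- codons[j]
    if (gc[[c1]] == "*" || gc[[c2]] == "*") next
    diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    k <- length(diff_pos)
    res <- matrix(NA_real_, 0, 3)  # syn, nonsyn, valid
    for (ord in perms[[as.character(k)]]) {
      cur <- c1; s <- 0; v <- 1
      for (pos in diff_pos[ord]) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (gc[[nxt]] == "*") v <- 0
        else if (gc[[nxt]] == gc[[cur]]) s <- s + 1
        cur <- nxt
      }
      res <- rbind(res, c(s, k - s, v))
    }
    use <- res[res[, 3] == 1, , drop = FALSE]
    if (!nrow(use)) use <- res
    sd[i, j] <- mean(use[, 1])
    nd[i, j] <- mean(use[, 2])
  }
  .hc_cache$codon <- list(syn_sites = syn_sites, sd = sd, nd = nd,
                          stops = codons[aa == "*"])
  .hc_cache$codon
}

.split_codons <- function(s) {
  substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
}

#' Nei-Gojobori Ks and Ka of an aligned CDS pair
#'
#' Codon columns containing any gap are dropped before counting.
#'
#' @param cds1,cds2 aligned CDS sequences of equal length (multiple of 3,
#'   gap codons allowed).
#' @return list: `ks`, `ka` (Jukes-Cantor corrected, NA when saturated),
#'   `ps`, `pn` (proportions), `S`, `N` (site counts), `sd`, `nd`
#'   (difference counts), `saturated_ks`, `saturated_ka`.
#' @export
ks_nei_gojobori <- function(cds1, cds2) {
  if (nchar(cds1) != nchar(cds2))
    .stopf("input error: aligned CDS lengths differ")
  if (nchar(cds1) %% 3L != 0L)
    .stopf("input error: aligned CDS length not a multiple of 3")
  tb <- .codon_tables()
  co1 <- .split_codons(cds1)
  co2 <- .split_codons(cds2)
  keep <- !grepl("-", co1, fixed = TRUE) & !grepl("-", co2, fixed = TRUE)
  co1 <- co1[keep]; co2 <- co2[keep]
  if (!length(co1)) .stopf("input error: no gap-free codon columns")
  if (any(co1 %in% tb$stops) || any(co2 %in% tb$stops))
    .stopf("input error: internal stop codon")
  s1 <- tb$syn_sites[co1]; s2 <- tb$syn_sites[co2]
  if (anyNA(s1) || anyNA(s2)) .stopf("input error: invalid codon")
  S <- sum((s1 + s2) / 2)
  N <- 3 * length(co1) - S
  ix <- cbind(match(co1, names(tb$syn_sites)), match(co2, names(tb$syn_sites)))
  Sd <- sum(tb$sd[ix])
  Nd <- sum(tb$nd[ix])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -(3 / 4) * log(1 - (4 / 3) * p)
  list(ks = jc(ps), ka = jc(pn), ps = ps, pn = pn, S = S, N = N,
       sd = Sd, nd = Nd,
       saturated_ks = ps >= 3 / 4, saturated_ka = pn >= 3 / 4)
}
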