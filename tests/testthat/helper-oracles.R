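# Independent oracles and fixture builders used across the suite.

# ---- toy gene tables / hits --------------------------------------------

toy_genes <- function(genome, n, chrom = "1") {
  data.frame(gene_id = sprintf("%s.%s.g%02d", genome, chrom, seq_len(n)),
             genome = genome, chromosome = chrom,
             start = (seq_len(n) - 1L) * 1000L + 1L,
             end = (seq_len(n) - 1L) * 1000L + 500L,
             strand = "+", rank = seq_len(n),
             stringsAsFactors = FALSE)
}

toy_hits <- function(ga, gb, ia, ib, bitscore = 100) {
  data.frame(query_id = ga$gene_id[ia], subject_id = gb$gene_id[ib],
             percent_identity = 80, evalue = 1e-20, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

# ---- colinearity: exhaustive chain enumeration -------------------------

# longest valid chain by depth-first enumeration of every chain
oracle_longest_chain <- function(ra, rb, G, anti = FALSE) {
  n <- length(ra)
  if (!n) return(0L)
  best <- 0L
  succ <- function(i) {
    da <- ra - ra[i]
    db <- if (anti) rb[i] - rb else rb - rb[i]
    which(da > 0 & da <= G & db > 0 & db <= G)
  }
  walk <- function(i, len) {
    if (len > best) best <<- len
    for (j in succ(i)) walk(j, len + 1L)
  }
  for (i in seq_len(n)) walk(i, 1L)
  best
}

oracle_best_chain_len <- function(ra, rb, G) {
  max(oracle_longest_chain(ra, rb, G, FALSE),
      oracle_longest_chain(ra, rb, G, TRUE))
}

# ---- four-point condition / NJ ------------------------------------------

# split index minimizing d(i,j) + d(k,l) over the three pairings;
# NA when tied
oracle_fourpoint_split <- function(d) {
  s <- c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
  mins <- which(s <= min(s) + 1e-12)
  if (length(mins) > 1L) NA_integer_ else mins
}

# additive distance matrix for a 4-leaf tree with the given split
# (1 = {1,2|3,4}, 2 = {1,3|2,4}, 3 = {1,4|2,3}), tip branches v, internal b
oracle_additive_matrix <- function(split, v, b) {
  pairs <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L))
  p1 <- pairs[[split]]
  p2 <- setdiff(1:4, p1)
  d <- matrix(0, 4, 4)
  for (i in 1:3) for (j in (i + 1):4) {
    same <- (i %in% p1 && j %in% p1) || (i %in% p2 && j %in% p2)
    d[i, j] <- d[j, i] <- v[i] + v[j] + if (same) 0 else b
  }
  dimnames(d) <- list(c("out_x", "hex_x", "out_y", "hex_y"),
                      c("out_x", "hex_x", "out_y", "hex_y"))
  d
}

# split of an ape::nj tree (cherry membership), as an index 1:3 in the
# order of oracle_additive_matrix; assumes 4 tips labelled t1..t4 in order
ape_nj_split <- function(d) {
  dimnames(d) <- list(paste0("t", 1:4), paste0("t", 1:4))
  tr <- ape::nj(as.dist(d))
  e <- tr$edge
  for (n in unique(e[, 1])) {
    tips <- e[e[, 1] == n & e[, 2] <= 4, 2]
    if (length(tips) == 2) {
      pr <- sort(tips)
      if (1 %in% pr) {
        return(match(pr[2], 2:4))
      } else {
        other <- sort(setdiff(1:4, pr))
        return(match(other[2], 2:4))
      }
    }
  }
  NA_integer_
}

# ---- Nei-Gojobori pathway enumeration ----------------------------------

oracle_ng_kaks <- function(cds1, cds2) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons1 <- substring(cds1, seq(1, nchar(cds1), 3), seq(3, nchar(cds1), 3))
  codons2 <- substring(cds2, seq(1, nchar(cds2), 3), seq(3, nchar(cds2), 3))
  syn_frac <- function(codon) {
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(codon, pos, pos))) {
        mut <- codon
        substr(mut, pos, pos) <- b
        if (gc[[mut]] != "*" && gc[[mut]] == gc[[codon]]) s <- s + 1 / 3
      }
    }
    s
  }
  S <- 0; Sd <- 0; Nd <- 0
  for (k in seq_along(codons1)) {
    c1 <- codons1[k]; c2 <- codons2[k]
    S <- S + (syn_frac(c1) + syn_frac(c2)) / 2
    dp <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(dp)) next
    perms <- if (length(dp) == 1) list(dp)
             else if (length(dp) == 2) list(dp, rev(dp))
             else {
               ix <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                          c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
               lapply(ix, function(o) dp[o])
             }
    res <- lapply(perms, function(path) {
      cur <- c1; s <- 0; valid <- TRUE
      for (pos in path) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (gc[[nxt]] == "*") valid <- FALSE
        else if (gc[[nxt]] == gc[[cur]]) s <- s + 1
        cur <- nxt
      }
      c(s = s, n = length(dp) - s, valid = as.numeric(valid))
    })
    res <- do.call(rbind, res)
    use <- res[res[, "valid"] == 1, , drop = FALSE]
    if (!nrow(use)) use <- res
    Sd <- Sd + mean(use[, "s"])
    Nd <- Nd + mean(use[, "n"])
  }
  N <- 3 * length(codons1) - S
  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -(3 / 4) * log(1 - (4 / 3) * p)
  list(ks = jc(ps), ka = jc(pn), S = S, N = N, sd = Sd, nd = Nd)
}

random_sense_cds <- function(n_codons) {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sense <- setdiff(all64, c("TAA", "TAG", "TGA"))
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# ---- two-sided Fisher tail by direct hypergeometric enumeration --------

oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  x <- lo:hi
  logp <- lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k)
  probs <- exp(logp)
  pobs <- probs[a - lo + 1]
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# ---- quartet sequences ---------------------------------------------------

# simulate one quartet of CDS/protein pairs directly from branch lengths
toy_quartet_seqs <- function(n_codons = 200, deep = 0.3, shallow = 0.02,
                             converted = FALSE, donor = "hex_y",
                             post = 0.005) {
  anc <- random_sense_cds(n_codons)
  linX <- mutate_sequence(anc, deep / 2)
  linY <- mutate_sequence(anc, deep / 2)
  s <- c(out_x = mutate_sequence(linX, shallow / 2),
         hex_x = mutate_sequence(linX, shallow / 2),
         out_y = mutate_sequence(linY, shallow / 2),
         hex_y = mutate_sequence(linY, shallow / 2))
  if (converted) {
    acceptor <- if (donor == "hex_y") "hex_x" else "hex_y"
    s[acceptor] <- impose_conversion(s[donor], s[acceptor])
    s["hex_x"] <- mutate_sequence(s["hex_x"], post)
    s["hex_y"] <- mutate_sequence(s["hex_y"], post)
  }
  prot <- vapply(s, function(x)
    as.character(Biostrings::translate(Biostrings::DNAString(x),
                                       no.init.codon = TRUE)), character(1))
  list(cds = s, protein = prot)
}
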