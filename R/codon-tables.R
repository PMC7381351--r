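# Codon bookkeeping shared by the simulator and the divergence estimators.
#
# Codons are indexed 1..64 as 16*(n1-1) + 4*(n2-1) + n3 with nucleotides
# ordered A=1, C=2, G=3, T=4 (the order used throughout the package).

.NT <- c("A", "C", "G", "T")

.codon_string <- function(idx) {
  i1 <- (idx - 1L) %/% 16L
  i2 <- ((idx - 1L) %/% 4L) %% 4L
  i3 <- (idx - 1L) %% 4L
  paste0(.NT[i1 + 1L], .NT[i2 + 1L], .NT[i3 + 1L])
}

.codon_index <- function(n1, n2, n3) 16L * (n1 - 1L) + 4L * (n2 - 1L) + n3

# nucleotide string -> integer vector (A=1..T=4, anything else NA)
.nt_to_int <- function(s) {
  m <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], .NT)
  m
}

.int_to_nt <- function(v) paste(.NT[v], collapse = "")

# cached tables built on first use
.codon_env <- new.env(parent = emptyenv())

.codon_tables <- function() {
  if (!is.null(.codon_env$aa)) {
    return(.codon_env)
  }
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- vapply(1:64, .codon_string, character(1))
  aa <- unname(gc_tab[codons])
  is_stop <- aa == "*"

  # Per-position synonymous-site fractions, stop-creating changes excluded
  # from the denominator; stop codons themselves get NA (they are skipped
  # when counting sites).
  syn_sites <- rep(NA_real_, 64)
  for (c0 in 1:64) {
    if (is_stop[c0]) next
    nts <- c((c0 - 1L) %/% 16L, ((c0 - 1L) %/% 4L) %% 4L, (c0 - 1L) %% 4L) + 1L
    s <- 0
    for (pos in 1:3) {
      nsyn <- 0L
      nvalid <- 0L
      for (alt in (1:4)[-nts[pos]]) {
        nn <- nts
        nn[pos] <- alt
        c1 <- .codon_index(nn[1], nn[2], nn[3])
        if (is_stop[c1]) next
        nvalid <- nvalid + 1L
        if (aa[c1] == aa[c0]) nsyn <- nsyn + 1L
      }
      if (nvalid > 0L) s <- s + nsyn / nvalid
    }
    syn_sites[c0] <- s
  }

  # Pairwise synonymous/nonsynonymous difference counts, averaged over all
  # minimal substitution pathways; pathways through stop codons excluded
  # (falling back to all pathways if every one is blocked).
  sd_tab <- matrix(0, 64, 64)
  nd_tab <- matrix(0, 64, 64)
  for (ca in 1:64) {
    if (is_stop[ca]) next
    for (cb in 1:64) {
      if (is_stop[cb] || ca == cb) next
      d <- .pathway_average(ca, cb, aa, is_stop)
      sd_tab[ca, cb] <- d[1]
      nd_tab[ca, cb] <- d[2]
    }
  }

  .codon_env$aa <- aa
  .codon_env$is_stop <- is_stop
  .codon_env$syn_sites <- syn_sites
  .codon_env$sd_tab <- sd_tab
  .codon_env$nd_tab <- nd_tab
  .codon_env$codons <- codons
  .codon_env
}

# average (Sd, Nd) over minimal pathways between two codons
.pathway_average <- function(ca, cb, aa, is_stop) {
  na_ <- c((ca - 1L) %/% 16L, ((ca - 1L) %/% 4L) %% 4L, (ca - 1L) %% 4L) + 1L
  nb_ <- c((cb - 1L) %/% 16L, ((cb - 1L) %/% 4L) %% 4L, (cb - 1L) %% 4L) + 1L
  diff_pos <- which(na_ != nb_)
  k <- length(diff_pos)
  if (k == 0L) return(c(0, 0))
  perms <- .permutations(diff_pos)
  res <- matrix(NA_real_, nrow(perms), 2)
  ok <- logical(nrow(perms))
  for (p in seq_len(nrow(perms))) {
    cur <- na_
    sd <- 0
    nd <- 0
    blocked <- FALSE
    for (pos in perms[p, ]) {
      nxt <- cur
      nxt[pos] <- nb_[pos]
      c_from <- .codon_index(cur[1], cur[2], cur[3])
      c_to <- .codon_index(nxt[1], nxt[2], nxt[3])
      if (is_stop[c_to]) blocked <- TRUE
      if (identical(aa[c_from], aa[c_to])) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    res[p, ] <- c(sd, nd)
    ok[p] <- !blocked
  }
  if (any(ok)) colMeans(res[ok, , drop = FALSE]) else colMeans(res)
}

.permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- .permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}
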