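# Independent brute-force oracles. These deliberately avoid the
# package's internal lookup tables and vectorized paths: everything is
# recomputed from first principles (genetic code straight from
# Biostrings::GENETIC_CODE, explicit enumeration of positions,
# pathways, tables, and rank arrangements).

oracle_code <- Biostrings::GENETIC_CODE

oracle_codons <- function(s) {
  s <- gsub("-", "N", s)
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

# per-codon synonymous site count, stop-creating changes excluded from
# the denominator
oracle_syn_sites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  aa0 <- oracle_code[[codon]]
  total <- 0
  for (p in 1:3) {
    nsyn <- 0
    nvalid <- 0
    for (nt in setdiff(nts, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- nt
      if (oracle_code[[alt]] == "*") next
      nvalid <- nvalid + 1
      if (oracle_code[[alt]] == aa0) nsyn <- nsyn + 1
    }
    if (nvalid > 0) total <- total + nsyn / nvalid
  }
  total
}

# average (Sd, Nd) over minimal pathways, explicit permutation walk
oracle_pathways <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (length(pos) == 0) return(c(0, 0))
  perms <- if (length(pos) == 1) {
    matrix(pos, 1)
  } else {
    m <- NULL
    for (p in pos) {
      sub <- Recall_perm(setdiff(pos, p))
      m <- rbind(m, cbind(p, sub))
    }
    m
  }
  acc <- NULL
  for (r in seq_len(nrow(perms))) {
    cur <- ca
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in perms[r, ]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (oracle_code[[nxt]] == "*") blocked <- TRUE
      if (oracle_code[[cur]] == oracle_code[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    acc <- rbind(acc, c(sd, nd, blocked))
  }
  ok <- acc[, 3] == 0
  if (any(ok)) colMeans(acc[ok, 1:2, drop = FALSE]) else colMeans(acc[, 1:2, drop = FALSE])
}

Recall_perm <- function(x) {
  if (length(x) == 1) return(matrix(x, 1))
  m <- NULL
  for (p in x) {
    sub <- Recall_perm(setdiff(x, p))
    m <- rbind(m, cbind(p, sub))
  }
  m
}

oracle_ng86 <- function(seq_a, seq_b) {
  ca <- oracle_codons(seq_a)
  cb <- oracle_codons(seq_b)
  keep <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb) &
    oracle_code[ca] != "*" & oracle_code[cb] != "*"
  ca <- ca[keep]; cb <- cb[keep]
  S <- (sum(vapply(ca, oracle_syn_sites, 0)) +
          sum(vapply(cb, oracle_syn_sites, 0))) / 2
  N <- 3 * length(ca) - S
  sdnd <- rowSums(vapply(seq_along(ca),
                         function(i) oracle_pathways(ca[i], cb[i]),
                         numeric(2)))
  jc <- function(p) if (1 - 4 * p / 3 <= 0) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = sdnd[1], Nd = sdnd[2],
       Ks = jc(sdnd[1] / S), Ka = jc(sdnd[2] / N))
}

# Fisher two-sided by explicit enumeration of all tables with the
# observed margins, probabilities from choose()
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(xs, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }, 0)
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney by enumerating all assignments of the
# pooled values to the first sample (no ties assumed)
oracle_mw_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  u_stat <- function(xi, yi) sum(outer(xi, yi, ">"))
  u_obs <- u_stat(x, y)
  idx <- utils::combn(length(pool), n1)
  us <- apply(idx, 2, function(ii) u_stat(pool[ii], pool[-ii]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# plain Smith-Waterman with affine gaps, for the best-hit frame oracle
oracle_sw <- function(a, b, mat, gap_open = 11, gap_ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- X <- Y <- matrix(0, n + 1, m + 1)
  X[, 1] <- -Inf; Y[1, ] <- -Inf
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- mat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(0,
                             M[i, j] + s, X[i, j] + s, Y[i, j] + s)
      X[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                             X[i + 1, j] - gap_ext)
      Y[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                             Y[i, j + 1] - gap_ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# translate in a given forward frame with the plain genetic code
oracle_translate <- function(seq, frame) {
  s <- substr(seq, frame, nchar(seq))
  s <- substr(s, 1, nchar(s) - nchar(s) %% 3)
  cods <- oracle_codons(s)
  paste(ifelse(grepl("[^ACGT]", cods), "X", oracle_code[cods]), collapse = "")
}

random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  all_cod <- names(oracle_code)
  ok <- setdiff(all_cod, stops)
  paste(sample(ok, n_codons, replace = TRUE), collapse = "")
}

# mutate a sequence at k random positions (any change, for fixtures)
mutate_seq <- function(seq, k) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(length(v), k)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}
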