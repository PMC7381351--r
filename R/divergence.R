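# Codon-alignment handling, windowed synonymous divergence, and the
# distribution/rate tests built on it.

#' Construct a codon alignment
#'
#' @param seqs Named character vector of aligned sequences (gaps `-`);
#'   all must have equal length.
#' @param id Optional alignment identifier.
#' @return Object of class `codon_alignment`.
#' @export
codon_alignment <- function(seqs, id = NULL) {
  if (length(seqs) == 0L) stop("empty alignment")
  if (is.null(names(seqs)) || anyNA(names(seqs))) {
    stop("sequences must be named by taxon")
  }
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("ragged alignment: unequal sequence lengths")
  structure(list(seqs = seqs, length = len,
                 multiple_of_three = len %% 3L == 0L, id = id),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("Codon alignment%s: %d taxa x %d columns (%smultiple of three)\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              length(x$seqs), x$length,
              if (x$multiple_of_three) "" else "NOT "))
  invisible(x)
}

#' Stack per-family gene sequences into alignments
#'
#' Convenience aligner for simulated strain sets: within a family the
#' copy-1 genes across strains derive from a common ancestor without
#' indels, so equal-length members stack directly into a codon
#' alignment. Members whose lengths disagree (single-nucleotide
#' frameshift insertions) are padded with trailing gaps to the longest
#' member, which yields a non-multiple-of-three alignment — exactly the
#' signature the frameshift filter removes, mirroring how indel-broken
#' nucleotide alignments are screened out of real data.
#'
#' @param genes GeneRecord data.frame from [simulate_strain_set()].
#' @return Named list of `codon_alignment` objects, one per family
#'   present in two or more strains, named `FAM<k>`.
#' @export
align_families <- function(genes) {
  g <- genes[genes$copy == 1L, , drop = FALSE]
  fams <- sort(unique(g$family))
  out <- list()
  for (fam in fams) {
    gf <- g[g$family == fam, ]
    if (nrow(gf) < 2L) next
    seqs <- gsub("-", "", gf$sequence)
    maxlen <- max(nchar(seqs))
    seqs <- vapply(seqs, function(s) {
      paste0(s, strrep("-", maxlen - nchar(s)))
    }, character(1), USE.NAMES = FALSE)
    names(seqs) <- gf$strain_id
    id <- sprintf("FAM%03d", fam)
    out[[id]] <- codon_alignment(seqs, id = id)
  }
  out
}

#' Drop alignments whose length is not a multiple of three
#'
#' A nucleotide alignment length that is not divisible by three
#' indicates that at least one member carries a frameshift; such
#' alignments are excluded from codon-level analysis.
#'
#' @param alignments List of `codon_alignment` objects.
#' @return List with `kept` (sublist) and `dropped` (data.frame `id`,
#'   `length`, `reason`).
#' @export
filter_multiple_of_three <- function(alignments) {
  is_ok <- vapply(alignments, function(a) a$multiple_of_three, logical(1))
  dropped <- data.frame(
    id = vapply(alignments[!is_ok], function(a) a$id %||% NA_character_,
                character(1)),
    length = vapply(alignments[!is_ok], function(a) a$length, numeric(1)),
    reason = "length not a multiple of three (frameshift)",
    stringsAsFactors = FALSE
  )
  rownames(dropped) <- NULL
  list(kept = alignments[is_ok], dropped = dropped)
}

#' Concatenate codon alignments sharing the same taxa
#'
#' @param alignments List of multiple-of-three `codon_alignment`
#'   objects over identical taxon sets.
#' @param ordering Optional character vector of alignment names giving
#'   the concatenation order (default: list order).
#' @return A single `codon_alignment`.
#' @export
concatenate_alignments <- function(alignments, ordering = NULL) {
  if (length(alignments) == 0L) stop("no alignments to concatenate")
  if (!is.null(ordering)) {
    if (!all(ordering %in% names(alignments))) {
      stop("ordering refers to unknown alignments")
    }
    alignments <- alignments[ordering]
  }
  taxa <- sort(names(alignments[[1L]]$seqs))
  for (a in alignments) {
    if (!identical(sort(names(a$seqs)), taxa)) {
      stop("alignments do not share the same taxa")
    }
    if (!a$multiple_of_three) stop("all alignments must be multiple of three")
  }
  seqs <- vapply(taxa, function(tx) {
    paste(vapply(alignments, function(a) unname(a$seqs[tx]), character(1)),
          collapse = "")
  }, character(1))
  codon_alignment(seqs, id = "concatenated")
}

#' Ks over non-overlapping windows of synonymous sites
#'
#' Scans the concatenated alignment codon by codon for one taxon pair,
#' accumulating pairwise synonymous sites; a window closes at the first
#' codon that pushes the cumulative count to at least
#' `window_syn_sites` (windows may slightly exceed the target), Ks is
#' computed within each closed window, and the trailing partial window
#' is discarded.
#'
#' @param concatenated A multiple-of-three `codon_alignment`.
#' @param taxon_a,taxon_b Taxon names of the pair.
#' @param window_syn_sites Synonymous sites per window (default 500).
#' @param source Label recorded on the series (e.g. `"all"` or
#'   `"pair:<strain>"`).
#' @return data.frame of class `ks_window_series`: `index`,
#'   `syn_sites`, `Sd`, `Ks` (NA where the Jukes-Cantor log is
#'   undefined); empty with a warning when the total synonymous count
#'   is below one window.
#' @export
windowed_ks <- function(concatenated, taxon_a, taxon_b,
                        window_syn_sites = 500, source = "all") {
  stopifnot(inherits(concatenated, "codon_alignment"),
            concatenated$multiple_of_three)
  sq <- concatenated$seqs
  if (!all(c(taxon_a, taxon_b) %in% names(sq))) {
    stop("taxa not present in alignment")
  }
  tb <- .codon_tables()
  a <- .nt_to_int(gsub("-", "0", sq[[taxon_a]]))
  b <- .nt_to_int(gsub("-", "0", sq[[taxon_b]]))
  nc <- length(a) %/% 3L
  i1 <- seq(1L, by = 3L, length.out = nc)
  ca <- .codon_index(a[i1], a[i1 + 1L], a[i1 + 2L])
  cb <- .codon_index(b[i1], b[i1 + 1L], b[i1 + 2L])
  comp <- !is.na(ca) & !is.na(cb)
  comp[comp] <- !tb$is_stop[ca[comp]] & !tb$is_stop[cb[comp]]
  s_cod <- sd_cod <- nd_cod <- numeric(nc)
  s_cod[comp] <- (tb$syn_sites[ca[comp]] + tb$syn_sites[cb[comp]]) / 2
  sd_cod[comp] <- tb$sd_tab[cbind(ca[comp], cb[comp])]
  nd_cod[comp] <- tb$nd_tab[cbind(ca[comp], cb[comp])]

  win_idx <- integer(0); win_s <- win_sd <- numeric(0)
  cs <- 0; csd <- 0; w <- 0L
  for (i in seq_len(nc)) {
    cs <- cs + s_cod[i]
    csd <- csd + sd_cod[i]
    # small tolerance so fractional site counts that sum to the target
    # exactly in real arithmetic still close the window
    if (cs >= window_syn_sites - 1e-9) {
      w <- w + 1L
      win_idx <- c(win_idx, w); win_s <- c(win_s, cs); win_sd <- c(win_sd, csd)
      cs <- 0; csd <- 0
    }
  }
  if (w == 0L) {
    warning("total synonymous sites below one window; empty series")
  }
  p_s <- ifelse(win_s > 0, win_sd / win_s, NA_real_)
  arg <- 1 - 4 * p_s / 3
  ks <- ifelse(!is.na(arg) & arg > 0, -0.75 * log(arg), NA_real_)
  out <- data.frame(index = win_idx, syn_sites = win_s, Sd = win_sd, Ks = ks)
  attr(out, "source") <- source
  attr(out, "pair") <- c(taxon_a, taxon_b)
  class(out) <- c("ks_window_series", "data.frame")
  out
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two Ks samples
#'
#' Exact enumeration (via the Wilcoxon distribution) when the combined
#' sample size is at most 20 and there are no ties, with the two-sided
#' p obtained by doubling the smaller tail; otherwise the normal
#' approximation with tie-corrected variance.
#'
#' @param x,y Numeric samples (e.g. window Ks values for "All" vs
#'   "Pair" gene sets).
#' @param alternative `"two.sided"`, `"less"` (x stochastically
#'   smaller), or `"greater"`.
#' @return List with `U` (number of (x, y) pairs with x > y, ties
#'   counted 1/2), `p_value`, and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (n1 + n2 <= 20L && !ties) {
    p_le <- stats::pwilcox(U, n1, n2)
    p_ge <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le, greater = p_ge)
    return(list(U = U, p_value = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  nn <- n1 + n2
  tie_tab <- table(c(x, y))
  sig2 <- n1 * n2 / 12 * ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
  if (sig2 <= 0) {
    p <- switch(alternative, two.sided = 1, less = 1, greater = 1)
    return(list(U = U, p_value = p, method = "normal"))
  }
  z <- (U - mu) / sqrt(sig2)
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              less = stats::pnorm(z),
              greater = stats::pnorm(z, lower.tail = FALSE))
  list(U = U, p_value = min(1, p), method = "normal")
}

#' Tajima relative rate test
#'
#' Three-taxon test of rate equality between lineages A and B using an
#' outgroup: m1 counts sites where A differs from both B and the
#' outgroup while B equals the outgroup, m2 symmetrically; under equal
#' rates (m1 - m2)^2 / (m1 + m2) is chi-square with 1 df.
#'
#' @param seq_a,seq_b,outgroup Aligned nucleotide strings of equal,
#'   multiple-of-three length.
#' @param mode `"third_codon"` (third codon positions of codons
#'   comparable in all three sequences) or `"amino_acid"` (translated
#'   codons).
#' @return List of class `rate_test`: `m1`, `m2`, `chi_square`,
#'   `p_value`, `mode`, `sites_used`.
#' @export
tajima_rrt <- function(seq_a, seq_b, outgroup,
                       mode = c("third_codon", "amino_acid")) {
  mode <- match.arg(mode)
  if (length(unique(nchar(c(seq_a, seq_b, outgroup)))) != 1L) {
    stop("sequences must have equal aligned length")
  }
  if (nchar(seq_a) %% 3L != 0L) stop("alignment length must be multiple of three")
  tb <- .codon_tables()
  ints <- lapply(c(seq_a, seq_b, outgroup),
                 function(s) .nt_to_int(gsub("-", "0", s)))
  nc <- length(ints[[1]]) %/% 3L
  i1 <- seq(1L, by = 3L, length.out = nc)
  cod <- lapply(ints, function(v) .codon_index(v[i1], v[i1 + 1L], v[i1 + 2L]))
  comp <- !is.na(cod[[1]]) & !is.na(cod[[2]]) & !is.na(cod[[3]])
  if (mode == "third_codon") {
    a <- ints[[1]][i1 + 2L][comp]
    b <- ints[[2]][i1 + 2L][comp]
    o <- ints[[3]][i1 + 2L][comp]
  } else {
    a <- tb$aa[cod[[1]][comp]]
    b <- tb$aa[cod[[2]][comp]]
    o <- tb$aa[cod[[3]][comp]]
  }
  m1 <- sum(a != b & a != o & b == o)
  m2 <- sum(b != a & b != o & a == o)
  if (m1 + m2 == 0L) {
    chi <- 0
    p <- 1
  } else {
    chi <- (m1 - m2)^2 / (m1 + m2)
    p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  }
  structure(list(m1 = m1, m2 = m2, chi_square = chi, p_value = p,
                 mode = mode, sites_used = length(a)),
            class = "rate_test")
}

#' @export
print.rate_test <- function(x, ...) {
  cat(sprintf("Tajima relative rate test (%s sites, n = %d)\n",
              x$mode, x$sites_used))
  cat(sprintf("  m1 = %d  m2 = %d  chi-square = %.4f  p = %.5g\n",
              x$m1, x$m2, x$chi_square, x$p_value))
  invisible(x)
}
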