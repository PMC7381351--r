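# Plasmid-location screening: probability thresholding, genome plasmid
# fractions, and Fisher exact enrichment of pair-specific genes.

#' Apply a plasmid-probability threshold to compartment calls
#'
#' A record is labeled `plasmid` when its plasmid probability reaches
#' the threshold, `chromosome` when its chromosome probability does,
#' and `unclassified` otherwise. The effective label folds
#' `unclassified` into `chromosome` (unclassified sequences are assumed
#' chromosomal).
#'
#' @param calls data.frame with `id`, `plasmid_prob`,
#'   `chromosome_prob`.
#' @param threshold Probability threshold in \[0.5, 1\] (default 0.7).
#' @return data.frame `id`, `plasmid_prob`, `chromosome_prob`, `label`,
#'   `effective_label`.
#' @export
apply_threshold <- function(calls, threshold = 0.7) {
  if (threshold < 0.5 || threshold > 1) {
    stop("threshold must be in [0.5, 1]")
  }
  label <- ifelse(calls$plasmid_prob >= threshold, "plasmid",
                  ifelse(calls$chromosome_prob >= threshold, "chromosome",
                         "unclassified"))
  data.frame(id = calls$id,
             plasmid_prob = calls$plasmid_prob,
             chromosome_prob = calls$chromosome_prob,
             label = label,
             effective_label = ifelse(label == "plasmid", "plasmid",
                                      "chromosome"),
             stringsAsFactors = FALSE)
}

#' Fraction of genome base pairs on plasmid-labeled sequences
#'
#' @param calls data.frame with `id` and `effective_label` (from
#'   [apply_threshold()] or pre-labeled with `label`).
#' @param weights Named numeric vector of base-pair lengths (names =
#'   `id`), or a single unnamed value recycled to all records.
#' @return Plasmid base pairs / total base pairs.
#' @export
plasmid_fraction <- function(calls, weights) {
  lab <- if ("effective_label" %in% names(calls)) {
    calls$effective_label
  } else {
    ifelse(calls$label == "plasmid", "plasmid", "chromosome")
  }
  w <- if (length(weights) == 1L && is.null(names(weights))) {
    rep(weights, nrow(calls))
  } else {
    unname(weights[calls$id])
  }
  if (anyNA(w)) stop("missing length for a record")
  tot <- sum(w)
  if (tot <= 0) stop("zero total length")
  sum(w[lab == "plasmid"]) / tot
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The two-sided p-value sums the hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed
#' that of the observed table (minimum-likelihood rule). The odds
#' ratio is the sample cross-product a*d / (b*c), flagged infinite when
#' b*c = 0.
#'
#' @param a,b,c,d Counts: rows are gene sets (e.g. pair-specific vs
#'   all-strain orthologs), columns are locations (plasmid,
#'   chromosome).
#' @return List of class `fisher_result`: `p_two_sided`, `odds_ratio`,
#'   `infinite_or`, `table`.
#' @export
fisher_exact <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 + r2 == 0 || (r1 == 0 || r2 == 0) || (c1 == 0 || b + d == 0)) {
    stop("all-zero margin: table is degenerate")
  }
  x <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(x, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  structure(list(p_two_sided = min(1, p), odds_ratio = or,
                 infinite_or = is.infinite(or),
                 table = matrix(counts, 2, byrow = TRUE,
                                dimnames = list(c("set1", "set2"),
                                                c("plasmid", "chromosome")))),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("Fisher exact test (two-sided, minimum-likelihood rule)\n")
  print(x$table)
  cat(sprintf("  p = %.4g   odds ratio = %s\n", x$p_two_sided,
              if (x$infinite_or) "Inf" else sprintf("%.3f", x$odds_ratio)))
  invisible(x)
}

#' Plasmid-location enrichment of pair-specific genes
#'
#' For each subject strain, builds the 2x2 table (pair-specific
#' plasmid / pair-specific chromosome / all-ortholog plasmid /
#' all-ortholog chromosome) using effective compartment labels
#' (unclassified folded into chromosome) and tests it with the Fisher
#' exact test.
#'
#' @param pair_sets Named list (by subject strain) of character vectors
#'   of pair-specific gene ids (present in the focal strain and that
#'   strain only).
#' @param all_orthologs Character vector of gene ids present in all
#'   strains.
#' @param compartments data.frame with `id` and `effective_label` (or
#'   `label`) covering every gene in both sets.
#' @return data.frame: per strain the four counts, `odds_ratio`,
#'   `p_two_sided`.
#' @export
enrichment_pipeline <- function(pair_sets, all_orthologs, compartments) {
  lab <- if ("effective_label" %in% names(compartments)) {
    stats::setNames(compartments$effective_label, compartments$id)
  } else {
    stats::setNames(ifelse(compartments$label == "plasmid", "plasmid",
                           "chromosome"), compartments$id)
  }
  need <- unique(c(unlist(pair_sets), all_orthologs))
  if (!all(need %in% names(lab))) {
    stop("compartment missing for some genes")
  }
  ao_lab <- lab[all_orthologs]
  out <- do.call(rbind, lapply(names(pair_sets), function(s) {
    ps <- pair_sets[[s]]
    if (length(intersect(ps, all_orthologs)) > 0L) {
      stop("a gene cannot be both pair-specific and all-strain")
    }
    pl <- lab[ps]
    a <- sum(pl == "plasmid"); b <- sum(pl == "chromosome")
    cc <- sum(ao_lab == "plasmid"); d <- sum(ao_lab == "chromosome")
    fr <- fisher_exact(a, b, cc, d)
    data.frame(subject_strain = s,
               pair_plasmid = a, pair_chromosome = b,
               all_plasmid = cc, all_chromosome = d,
               odds_ratio = fr$odds_ratio, p_two_sided = fr$p_two_sided,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
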