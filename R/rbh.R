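# Reciprocal-best-hit homology classification.
#
# The built-in scorer emulates a translated (tblastx-like) comparison:
# both nucleotide sequences are translated in all three forward frames
# and the best local-alignment score over the nine frame pairs is taken,
# under BLOSUM62 with affine gaps (open 11, extend 1). CDS inputs are
# assumed stranded; `reverse_frames = TRUE` adds the three
# reverse-complement frames for non-CDS input.

.aa_matrix <- function() {
  if (is.null(.codon_env$blosum)) {
    mat <- get(utils::data("BLOSUM62", package = "Biostrings",
                           envir = environment()))
    # ambiguous translations (X) carry no signal
    mat["X", ] <- 0L
    mat[, "X"] <- 0L
    .codon_env$blosum <- mat
  }
  .codon_env$blosum
}

# translate an integer nucleotide vector; codons with ambiguity -> X
.translate_ints <- function(v) {
  n <- length(v) - length(v) %% 3L
  if (n < 3L) stop("sequence shorter than one codon after frame trimming")
  tb <- .codon_tables()
  i1 <- seq(1L, n, by = 3L)
  idx <- .codon_index(v[i1], v[i1 + 1L], v[i1 + 2L])
  aa <- ifelse(is.na(idx), "X", tb$aa[ifelse(is.na(idx), 1L, idx)])
  paste(aa, collapse = "")
}

# translate one nucleotide string in 3 (or 6) frames
.translate_frames <- function(seq, reverse_frames = FALSE) {
  v <- .nt_to_int(gsub("-", "", seq))
  strands <- list(v)
  if (reverse_frames) strands <- c(strands, list(rev(5L - v)))
  out <- character(0)
  for (d in strands) {
    for (f in 1:3) {
      out <- c(out, .translate_ints(d[f:length(d)]))
    }
  }
  Biostrings::AAStringSet(out)
}

# best frame-pair local-alignment score matrix between two gene sets
.score_matrix <- function(query_set, subject_set, reverse_frames = FALSE) {
  stopifnot(nrow(subject_set) > 0L, nrow(query_set) > 0L)
  mat <- .aa_matrix()
  sub_frames <- lapply(subject_set$sequence, .translate_frames, reverse_frames)
  nf <- lengths(sub_frames)
  sub_all <- do.call(c, sub_frames)
  sub_gene <- rep(seq_len(nrow(subject_set)), nf)
  scores <- matrix(-Inf, nrow(query_set), nrow(subject_set),
                   dimnames = list(query_set$gene_id, subject_set$gene_id))
  for (i in seq_len(nrow(query_set))) {
    qf <- .translate_frames(query_set$sequence[i], reverse_frames)
    for (f in seq_along(qf)) {
      sc <- Biostrings::pairwiseAlignment(
        pattern = sub_all, subject = qf[[f]], type = "local",
        substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
        scoreOnly = TRUE)
      best <- tapply(sc, sub_gene, max)
      scores[i, ] <- pmax(scores[i, ], best[as.character(seq_len(ncol(scores)))])
    }
  }
  scores
}

# argmax with lexicographically-smallest-id tie break
.best_of <- function(scores, ids) {
  o <- order(-scores, ids)[1L]
  list(id = ids[o], score = unname(scores[o]))
}

#' Best translated-similarity hit of a query gene in a subject gene set
#'
#' Translates query and subjects in all three forward frames, scores
#' every frame pair by local alignment (BLOSUM62, gap open 11, extend
#' 1), and returns the subject gene with the maximal score; ties are
#' broken by lexicographically smallest gene id.
#'
#' @param query A one-row GeneRecord data.frame (needs `gene_id`,
#'   `sequence`).
#' @param subject_set GeneRecord data.frame of candidate subjects.
#' @param score_threshold Minimum raw score to report a hit (default
#'   50); below it the result is `NA`.
#' @param reverse_frames Also scan reverse-complement frames.
#' @return List with `gene_id` (or `NA_character_`) and `score`.
#' @export
best_hit <- function(query, subject_set, score_threshold = 50,
                     reverse_frames = FALSE) {
  sc <- .score_matrix(query, subject_set, reverse_frames)
  b <- .best_of(sc[1L, ], colnames(sc))
  if (b$score < score_threshold) {
    list(gene_id = NA_character_, score = b$score)
  } else {
    b <- list(gene_id = b$id, score = b$score)
    b
  }
}

#' Classify one query gene against a subject strain by reciprocal best hits
#'
#' Forward best hit of the query into the subject set; no hit means
#' `no_similarity`. Otherwise the forward best subject is searched back
#' into the query strain's gene set: if its best reverse hit is the
#' original query the label is `ortholog`, otherwise `paralog`.
#'
#' @param query One-row GeneRecord data.frame.
#' @param query_strain_set GeneRecord data.frame of the query strain
#'   (must contain the query).
#' @param subject_set GeneRecord data.frame of the subject strain.
#' @inheritParams best_hit
#' @return One-row data.frame: `query_gene`, `subject_strain`, `label`,
#'   `forward_best`, `reverse_best`, `forward_score`.
#' @export
classify_rbh <- function(query, query_strain_set, subject_set,
                         score_threshold = 50, reverse_frames = FALSE) {
  stopifnot(query$gene_id %in% query_strain_set$gene_id)
  fw <- best_hit(query, subject_set, score_threshold, reverse_frames)
  strain <- subject_set$strain_id[1L]
  if (is.na(fw$gene_id)) {
    return(data.frame(query_gene = query$gene_id, subject_strain = strain,
                      label = "no_similarity", forward_best = NA_character_,
                      reverse_best = NA_character_, forward_score = fw$score,
                      stringsAsFactors = FALSE))
  }
  rv <- best_hit(subject_set[subject_set$gene_id == fw$gene_id, , drop = FALSE],
                 query_strain_set, score_threshold, reverse_frames)
  label <- if (identical(rv$gene_id, query$gene_id)) "ortholog" else "paralog"
  data.frame(query_gene = query$gene_id, subject_strain = strain,
             label = label, forward_best = fw$gene_id,
             reverse_best = rv$gene_id, forward_score = fw$score,
             stringsAsFactors = FALSE)
}

#' Reciprocal-best-hit calls for all query genes against one subject strain
#'
#' Batch form of [classify_rbh()]: computes the full query-by-subject
#' score matrix once (scores are symmetric under the local-alignment
#' scorer) and derives forward and reverse best hits from it.
#'
#' @param query_set GeneRecord data.frame (one strain).
#' @param subject_set GeneRecord data.frame (another strain).
#' @inheritParams best_hit
#' @return HomologyCall data.frame, one row per query gene.
#' @export
rbh_strain <- function(query_set, subject_set, score_threshold = 50,
                       reverse_frames = FALSE) {
  sc <- .score_matrix(query_set, subject_set, reverse_frames)
  # the reverse search runs against the focal strain's CDS set only,
  # and the local-alignment score is symmetric, so the one matrix
  # serves both directions.
  strain <- subject_set$strain_id[1L]
  n <- nrow(query_set)
  out <- data.frame(query_gene = query_set$gene_id,
                    subject_strain = rep(strain, n),
                    label = character(n), forward_best = NA_character_,
                    reverse_best = NA_character_, forward_score = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    fb <- .best_of(sc[i, ], colnames(sc))
    out$forward_score[i] <- fb$score
    if (fb$score < score_threshold) {
      out$label[i] <- "no_similarity"
      next
    }
    out$forward_best[i] <- fb$id
    rb <- .best_of(sc[, fb$id], rownames(sc))
    out$reverse_best[i] <- rb$id
    out$label[i] <- if (identical(rb$id, query_set$gene_id[i]))
      "ortholog" else "paralog"
  }
  out
}

#' Reciprocal-best-hit calls of a focal strain against every other strain
#'
#' @param genes GeneRecord data.frame covering all strains.
#' @param focal_strain Query strain id.
#' @inheritParams best_hit
#' @return HomologyCall data.frame over all (query gene, subject
#'   strain) pairs.
#' @export
rbh_all <- function(genes, focal_strain, score_threshold = 50,
                    reverse_frames = FALSE) {
  stopifnot(focal_strain %in% genes$strain_id)
  qs <- genes[genes$strain_id == focal_strain, , drop = FALSE]
  others <- setdiff(unique(genes$strain_id), focal_strain)
  do.call(rbind, lapply(others, function(s) {
    rbh_strain(qs, genes[genes$strain_id == s, , drop = FALSE],
               score_threshold, reverse_frames)
  }))
}

#' Reciprocal-best-hit calls from precomputed tabular hits
#'
#' Alternate input path for users substituting real search output for
#' the built-in scorer. Both tables need columns `query`, `subject`,
#' `score`; ties are broken by lexicographically smallest subject id.
#'
#' @param forward_hits Hits of focal-strain queries against one subject
#'   strain.
#' @param reverse_hits Hits of subject-strain genes against the focal
#'   strain.
#' @param query_genes Character vector of all focal query gene ids
#'   (queries without any forward hit become `no_similarity`).
#' @param subject_strain Label recorded in the calls.
#' @return HomologyCall data.frame, one row per query gene.
#' @export
rbh_from_hits <- function(forward_hits, reverse_hits, query_genes,
                          subject_strain) {
  best_by <- function(hits) {
    hits <- hits[order(hits$query, -hits$score, hits$subject), ]
    hits[!duplicated(hits$query), c("query", "subject", "score")]
  }
  fb <- best_by(forward_hits)
  rb <- best_by(reverse_hits)
  out <- data.frame(query_gene = query_genes,
                    subject_strain = subject_strain,
                    label = "no_similarity", forward_best = NA_character_,
                    reverse_best = NA_character_, forward_score = NA_real_,
                    stringsAsFactors = FALSE)
  m <- match(out$query_gene, fb$query)
  hit <- !is.na(m)
  out$forward_best[hit] <- fb$subject[m[hit]]
  out$forward_score[hit] <- fb$score[m[hit]]
  rm_ <- match(out$forward_best[hit], rb$query)
  rev_best <- ifelse(is.na(rm_), NA_character_, rb$subject[rm_])
  out$reverse_best[hit] <- rev_best
  out$label[hit] <- ifelse(!is.na(rev_best) & rev_best == out$query_gene[hit],
                           "ortholog", "paralog")
  out
}

#' Per-strain homology summary (ortholog / paralog / no-similarity counts)
#'
#' @param calls HomologyCall data.frame covering one call per (query
#'   gene, subject strain).
#' @param total_query_genes Total focal-strain gene count the
#'   percentages refer to.
#' @return data.frame with per-strain counts and percentages (one
#'   decimal) of `total_query_genes`; counts partition the total.
#' @export
summarize_homology <- function(calls, total_query_genes) {
  if (anyDuplicated(calls[, c("query_gene", "subject_strain")])) {
    stop("duplicate calls for a (gene, strain) pair")
  }
  strains <- unique(calls$subject_strain)
  out <- do.call(rbind, lapply(strains, function(s) {
    cs <- calls[calls$subject_strain == s, ]
    if (nrow(cs) != total_query_genes) {
      stop(sprintf("strain %s has %d calls but %d query genes expected",
                   s, nrow(cs), total_query_genes))
    }
    n_o <- sum(cs$label == "ortholog")
    n_p <- sum(cs$label == "paralog")
    n_n <- sum(cs$label == "no_similarity")
    data.frame(subject_strain = s, orthologs = n_o, paralogs = n_p,
               no_similarity = n_n,
               pct_orthologs = round(100 * n_o / total_query_genes, 1),
               pct_paralogs = round(100 * n_p / total_query_genes, 1),
               pct_no_similarity = round(100 * n_n / total_query_genes, 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Genes with no similarity to any strain
#'
#' The focal genes labeled `no_similarity` against every subject strain
#' (strain-specific genes when all strains are pooled).
#'
#' @param calls HomologyCall data.frame covering every (gene, strain)
#'   pair.
#' @return Character vector of gene ids.
#' @export
union_no_similarity <- function(calls) {
  strains <- unique(calls$subject_strain)
  per_gene <- table(calls$query_gene[calls$label == "no_similarity"])
  cover <- table(calls$query_gene)
  if (any(cover != length(strains))) {
    stop("calls do not cover every (gene, strain) pair")
  }
  sort(names(per_gene)[per_gene == length(strains)])
}
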