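# Taxonomic contig binning from translated-similarity hit profiles.
#
# A contig's profile is its top hits (at most 20, descending score)
# against a mixed reference of cyanobacterial and contaminant
# (proteobacterial / CFB / other) proteomes, plus its fold coverage.
# Decision rules: a contig whose hits are all cyanobacterial is
# retained outright; a contig with a strict majority of cyanobacterial
# hits is retained after curation when its coverage exceeds the gate
# and its best cyanobacterial identity clears the best non-cyano
# identity by a configurable margin; everything else is discarded.

.TAXON_GROUPS <- c("cyanobacteria", "proteobacteria", "cfb", "other")

#' Classify one contig from its hit profile
#'
#' @param hits data.frame with columns `taxon_group` (one of
#'   `cyanobacteria`, `proteobacteria`, `cfb`, `other`),
#'   `percent_identity` in \[0, 100\], `score` (nonnegative, sorted
#'   descending; at most 20 rows). May have zero rows.
#' @param coverage Fold coverage of the contig.
#' @param contig_id Contig identifier carried into the decision.
#' @param coverage_min Coverage gate for curated retention (strict
#'   `>`, default 70).
#' @param identity_margin Required margin (percentage points) of best
#'   cyanobacterial identity over best non-cyanobacterial identity for
#'   curated retention (default 10).
#' @return One-row data.frame: `contig_id`, `decision` (one of
#'   `retain_all_cyano`, `retain_curated`, `discard`,
#'   `excluded_ambiguous` — the last only assigned by
#'   [congruence_filter()]), `reason`.
#' @export
classify_contig <- function(hits, coverage, contig_id = "contig",
                            coverage_min = 70, identity_margin = 10) {
  if (coverage < 0) stop("coverage must be nonnegative")
  dec <- function(d, reason) {
    data.frame(contig_id = contig_id, decision = d, reason = reason,
               stringsAsFactors = FALSE)
  }
  if (nrow(hits) == 0L) return(dec("discard", "no hits"))
  if (nrow(hits) > 20L) stop("at most 20 hits per contig")
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100)) {
    stop("percent identity outside [0, 100]")
  }
  if (!all(hits$taxon_group %in% .TAXON_GROUPS)) {
    stop("unknown taxon group in hit profile")
  }
  is_cy <- hits$taxon_group == "cyanobacteria"
  if (all(is_cy)) return(dec("retain_all_cyano", "all hits cyanobacterial"))
  if (sum(is_cy) > nrow(hits) / 2) {
    best_cy <- max(hits$percent_identity[is_cy])
    best_non <- max(hits$percent_identity[!is_cy])
    if (coverage > coverage_min && best_cy - best_non >= identity_margin) {
      return(dec("retain_curated",
                 sprintf("majority cyano, coverage %.1f > %.0f, identity margin %.1f",
                         coverage, coverage_min, best_cy - best_non)))
    }
    if (coverage <= coverage_min) {
      return(dec("discard", sprintf("coverage %.1f <= %.0f", coverage,
                                    coverage_min)))
    }
    return(dec("discard", sprintf("identity margin %.1f < %.0f",
                                  best_cy - best_non, identity_margin)))
  }
  dec("discard", "majority of hits non-cyanobacterial")
}

#' Classify a table of contig hit profiles
#'
#' @param hit_table data.frame with `contig_id`, `taxon_group`,
#'   `percent_identity`, `score` (long form, one row per hit).
#' @param contig_meta data.frame with `contig_id`, `length_bp`,
#'   `coverage`; contigs without hits are allowed.
#' @inheritParams classify_contig
#' @return BinDecision data.frame, one row per contig in
#'   `contig_meta`.
#' @export
classify_contigs <- function(hit_table, contig_meta, coverage_min = 70,
                             identity_margin = 10) {
  out <- do.call(rbind, lapply(seq_len(nrow(contig_meta)), function(i) {
    cid <- contig_meta$contig_id[i]
    h <- hit_table[hit_table$contig_id == cid, , drop = FALSE]
    h <- h[order(-h$score), , drop = FALSE]
    classify_contig(h, contig_meta$coverage[i], contig_id = cid,
                    coverage_min = coverage_min,
                    identity_margin = identity_margin)
  }))
  rownames(out) <- NULL
  out
}

#' Reconcile hit-rule decisions with a second binner's labels
#'
#' Contigs retained by the hit rules but labeled non-cyanobacterial by
#' the second binner are kept and flagged (the hit evidence wins);
#' contigs labeled cyanobacterial by the second binner but discarded by
#' the hit rules *because both top identities were high and close*
#' (margin below `identity_margin` with both best identities at least
#' `ambiguity_identity`) are marked `excluded_ambiguous` and dropped,
#' so that mixed-signal contigs cannot seed spurious transfer calls.
#'
#' @param decisions BinDecision data.frame from [classify_contigs()].
#' @param hit_table,contig_meta The inputs used for the decisions
#'   (needed to re-inspect identities of discarded contigs).
#' @param binner2_labels Named character vector or data.frame
#'   (`contig_id`, `label`) with labels `cyanobacterial` / `other`,
#'   covering every decided contig.
#' @param identity_margin Margin used by the hit rules.
#' @param ambiguity_identity Both best identities must reach this value
#'   for a conflict to count as ambiguous (default 70).
#' @return List: `retained` (character vector of contig ids),
#'   `flagged` (retained despite a non-cyano second-binner label),
#'   `excluded` (ambiguous, dropped), `congruence_fraction`, and the
#'   annotated `decisions` table (with `excluded_ambiguous` decisions
#'   applied).
#' @export
congruence_filter <- function(decisions, hit_table, contig_meta,
                              binner2_labels, identity_margin = 10,
                              ambiguity_identity = 70) {
  if (is.data.frame(binner2_labels)) {
    binner2_labels <- stats::setNames(binner2_labels$label,
                                      binner2_labels$contig_id)
  }
  if (!all(decisions$contig_id %in% names(binner2_labels))) {
    stop("second binner label missing for a decided contig")
  }
  lab <- binner2_labels[decisions$contig_id]
  retained_rule <- decisions$decision %in% c("retain_all_cyano",
                                             "retain_curated")
  cy2 <- lab == "cyanobacterial"

  # ambiguous: second binner says cyano, hit rules discarded with both
  # identities high and close
  ambiguous <- logical(nrow(decisions))
  for (i in which(!retained_rule & cy2)) {
    cid <- decisions$contig_id[i]
    h <- hit_table[hit_table$contig_id == cid, , drop = FALSE]
    is_cy <- h$taxon_group == "cyanobacteria"
    if (!any(is_cy) || all(is_cy)) next
    best_cy <- max(h$percent_identity[is_cy])
    best_non <- max(h$percent_identity[!is_cy])
    if (best_cy >= ambiguity_identity && best_non >= ambiguity_identity &&
        abs(best_cy - best_non) < identity_margin) {
      ambiguous[i] <- TRUE
    }
  }
  decisions$decision[ambiguous] <- "excluded_ambiguous"
  decisions$reason[ambiguous] <-
    "second binner cyanobacterial but identities high and close"

  retained <- decisions$contig_id[retained_rule]
  flagged <- decisions$contig_id[retained_rule & !cy2]
  excluded <- decisions$contig_id[ambiguous]
  either <- retained_rule | cy2
  agree <- retained_rule == cy2
  congruence_fraction <- if (any(either)) {
    sum(agree & either) / sum(either)
  } else {
    NA_real_
  }
  list(retained = retained, flagged = flagged, excluded = excluded,
       congruence_fraction = congruence_fraction, decisions = decisions)
}

#' Simulate contig hit profiles with known origin
#'
#' Mock translated-search profiles for exercising the binning rules
#' without a real search: true cyanobacterial contigs draw
#' cyano-dominant hits with high identity, contaminant contigs draw
#' contaminant-dominant profiles, and coverage is drawn around
#' plausible per-origin levels.
#'
#' @param n_cyano,n_contam Number of contigs of each origin.
#' @param seed Integer seed.
#' @return List: `hit_table`, `contig_meta`, `truth` (data.frame
#'   `contig_id`, `origin`).
#' @export
simulate_hit_profiles <- function(n_cyano = 50, n_contam = 50, seed = 1L) {
  set.seed(seed)
  rows <- list()
  meta <- list()
  truth <- list()
  k <- 0L
  for (origin in c("cyano", "contam")) {
    n <- if (origin == "cyano") n_cyano else n_contam
    for (i in seq_len(n)) {
      k <- k + 1L
      cid <- sprintf("contig_%03d", k)
      nh <- sample(5:20, 1L)
      if (origin == "cyano") {
        n_cy <- stats::rbinom(1L, nh, 0.9)
        n_cy <- max(n_cy, ceiling(nh / 2) + 1L)  # cyano-dominant
        n_cy <- min(n_cy, nh)
        id_cy <- stats::runif(n_cy, 80, 99)
        id_non <- stats::runif(nh - n_cy, 40, 65)
        cov <- stats::runif(1, 80, 140)
      } else {
        n_cy <- stats::rbinom(1L, nh, 0.15)
        id_cy <- stats::runif(n_cy, 40, 70)
        id_non <- stats::runif(nh - n_cy, 75, 99)
        cov <- stats::runif(1, 10, 60)
      }
      grp <- c(rep("cyanobacteria", n_cy),
               sample(c("proteobacteria", "cfb"), nh - n_cy, replace = TRUE))
      ident <- c(id_cy, id_non)
      score <- sort(stats::runif(nh, 50, 500), decreasing = TRUE)
      rows[[k]] <- data.frame(contig_id = cid, taxon_group = grp,
                              percent_identity = ident, score = score,
                              stringsAsFactors = FALSE)
      meta[[k]] <- data.frame(contig_id = cid,
                              length_bp = sample(1000:30000, 1L),
                              coverage = cov, stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(contig_id = cid, origin = origin,
                               stringsAsFactors = FALSE)
    }
  }
  list(hit_table = do.call(rbind, rows),
       contig_meta = do.call(rbind, meta),
       truth = do.call(rbind, truth))
}
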