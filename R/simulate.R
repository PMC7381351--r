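# Multi-strain codon-evolution simulator.
#
# Genes evolve along a guide tree under a minimal codon model:
# candidate mutations are uniform per nucleotide over the three
# alternatives, events that would create a stop codon are rejected and
# redrawn, and nonsynonymous events are accepted with probability
# omega. Branch lengths are expected substitution attempts per site, so
# realized synonymous divergence per synonymous site tracks path length
# closely (synonymous changes are always accepted).

# Evolve an integer nucleotide sequence along one branch; returns the
# new sequence plus a log of accepted substitutions.
.evolve <- function(seq, blen, omega, tb) {
  L <- length(seq)
  n_ev <- stats::rpois(1L, blen * L)
  pos_v <- integer(n_ev); from_v <- integer(n_ev)
  to_v <- integer(n_ev); syn_v <- logical(n_ev)
  n_acc <- 0L
  if (n_ev > 0L) {
    for (e in seq_len(n_ev)) {
      repeat {
        pos <- sample.int(L, 1L)
        cur <- seq[pos]
        alt <- (1:4)[-cur][sample.int(3L, 1L)]
        o <- pos - 1L - (pos - 1L) %% 3L   # codon offset
        w <- pos - o                        # position within codon 1..3
        c_old <- .codon_index(seq[o + 1L], seq[o + 2L], seq[o + 3L])
        c_new <- c_old + (alt - cur) * c(16L, 4L, 1L)[w]
        if (tb$is_stop[c_new]) next        # stop-creating: redraw event
        syn <- tb$aa[c_new] == tb$aa[c_old]
        if (!syn && stats::runif(1L) > omega) {
          break                            # nonsynonymous event not accepted
        }
        seq[pos] <- alt
        n_acc <- n_acc + 1L
        pos_v[n_acc] <- pos; from_v[n_acc] <- cur
        to_v[n_acc] <- alt; syn_v[n_acc] <- syn
        break
      }
    }
  }
  list(seq = seq,
       pos = pos_v[seq_len(n_acc)], from = from_v[seq_len(n_acc)],
       to = to_v[seq_len(n_acc)], syn = syn_v[seq_len(n_acc)])
}

.random_root_gene <- function(n_codons, tb) {
  ok <- which(!tb$is_stop)
  cods <- ok[sample.int(length(ok), n_codons, replace = TRUE)]
  i1 <- (cods - 1L) %/% 16L + 1L
  i2 <- ((cods - 1L) %/% 4L) %% 4L + 1L
  i3 <- (cods - 1L) %% 4L + 1L
  as.integer(rbind(i1, i2, i3))
}

#' Simulate a multi-strain coding-sequence set with known ground truth
#'
#' Evolves `n_families` gene families along the configured guide tree
#' and emits per-strain gene sets together with a truth log: per-gene
#' family, copy, compartment, HGT and frameshift flags, plus the
#' pairwise relationship (ortholog / paralog / absent) of every gene to
#' every other strain and the complete substitution event log.
#'
#' Structural events layered on the tree: a fraction of families is
#' duplicated in the focal strain (a recent duplicate of the tip
#' sequence, `dup_divergence` further attempts/site); each non-focal
#' strain loses a fraction of families; a fraction of families is
#' restricted to the donor/recipient pair, with the recipient's copy
#' re-sourced from the donor lineage so that the pair's divergence is
#' `hgt_divergence_scale` times the tree-path expectation. Frameshift
#' corruption (one inserted nucleotide, uniform position) is applied
#' after evolution, so truth relationships are unaffected.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `strain_set` with elements:
#'   \describe{
#'     \item{genes}{data.frame of emitted genes: `gene_id`, `strain_id`,
#'       `family`, `copy`, `sequence`, `compartment`, `plasmid_prob`,
#'       `chromosome_prob`, `annotation_category`, `hgt_flag`,
#'       `frameshift_flag`.}
#'     \item{relations}{long data.frame `gene_id`, `other_strain`,
#'       `relation` in \{ortholog, paralog, absent\}.}
#'     \item{events}{substitution log: `family`, `edge` (child node
#'       label, `dup`, or `hgt`), `strain` (tip label for terminal
#'       edges), `pos`, `from`, `to`, `syn`.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' ss <- simulate_strain_set(sim_config(n_families = 5, codon_length = 30))
#' head(ss$genes[, c("gene_id", "strain_id", "compartment")])
#' @export
simulate_strain_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tb <- .codon_tables()
  phy <- stats::reorder(config$phy, "cladewise")
  tips <- phy$tip.label
  ntip <- length(tips)
  F <- config$n_families
  Lnt <- 3L * config$codon_length
  focal <- config$focal_strain

  # family roles
  n_hgt <- round(config$hgt_fraction * F)
  hgt_fams <- if (n_hgt > 0) sort(sample.int(F, n_hgt)) else integer(0)
  rest <- setdiff(seq_len(F), hgt_fams)
  n_dup <- min(round(config$dup_fraction * F), length(rest))
  dup_fams <- if (n_dup > 0) sort(sample(rest, n_dup)) else integer(0)
  loss <- matrix(FALSE, F, ntip, dimnames = list(NULL, tips))
  n_loss <- round(config$loss_fraction * F)
  for (s in setdiff(tips, focal)) {
    if (n_loss > 0 && length(rest) > 0) {
      loss[sample(rest, min(n_loss, length(rest))), s] <- TRUE
    }
  }
  categories <- sample(names(config$category_probs), F, replace = TRUE,
                       prob = config$category_probs)

  pat <- ape::cophenetic.phylo(phy)
  hgt_path <- pat[config$hgt_donor, config$hgt_recipient]

  edge <- phy$edge
  elen <- phy$edge.length
  root <- ntip + 1L

  # per-family evolution
  tip_seqs <- vector("list", F)     # list of named lists of int vectors
  dup_seqs <- vector("list", F)
  ev_fam <- list(); ev_edge <- list(); ev_strain <- list()
  ev_pos <- list(); ev_from <- list(); ev_to <- list(); ev_syn <- list()
  k <- 0L
  push_ev <- function(fam, lab, strain, ev) {
    if (length(ev$pos) == 0L) return(invisible())
    k <<- k + 1L
    ev_fam[[k]] <<- rep.int(fam, length(ev$pos))
    ev_edge[[k]] <<- rep.int(lab, length(ev$pos))
    ev_strain[[k]] <<- rep.int(strain, length(ev$pos))
    ev_pos[[k]] <<- ev$pos; ev_from[[k]] <<- ev$from
    ev_to[[k]] <<- ev$to; ev_syn[[k]] <<- ev$syn
  }

  for (fam in seq_len(F)) {
    node_seq <- vector("list", max(edge))
    node_seq[[root]] <- .random_root_gene(config$codon_length, tb)
    for (i in seq_len(nrow(edge))) {
      par <- edge[i, 1L]; chd <- edge[i, 2L]
      ev <- .evolve(node_seq[[par]], elen[i], config$omega, tb)
      node_seq[[chd]] <- ev$seq
      lab <- if (chd <= ntip) tips[chd] else paste0("node", chd)
      push_ev(fam, lab, if (chd <= ntip) tips[chd] else NA_character_, ev)
    }
    ts <- stats::setNames(node_seq[seq_len(ntip)], tips)
    if (fam %in% hgt_fams) {
      # recipient copy re-sourced from the donor tip; pair divergence
      # becomes hgt_divergence_scale x the tree-path expectation
      ev <- .evolve(ts[[config$hgt_donor]],
                    config$hgt_divergence_scale * hgt_path,
                    config$omega, tb)
      ts[[config$hgt_recipient]] <- ev$seq
      push_ev(fam, "hgt", config$hgt_recipient, ev)
    }
    tip_seqs[[fam]] <- ts
    if (fam %in% dup_fams) {
      ev <- .evolve(ts[[focal]], config$dup_divergence, config$omega, tb)
      dup_seqs[[fam]] <- ev$seq
      push_ev(fam, "dup", focal, ev)
    }
  }

  # presence: which strains carry which family
  present <- matrix(TRUE, F, ntip, dimnames = list(NULL, tips))
  present[loss] <- FALSE
  if (length(hgt_fams) > 0) {
    present[hgt_fams, ] <- FALSE
    present[hgt_fams, c(config$hgt_donor, config$hgt_recipient)] <- TRUE
  }
  present[, focal] <- TRUE
  present[hgt_fams, focal] <- focal %in% c(config$hgt_donor, config$hgt_recipient)

  # emit genes strain by strain, family order
  rows <- list()
  r <- 0L
  for (s in tips) {
    for (fam in seq_len(F)) {
      if (!present[fam, s]) next
      ncopy <- if (s == focal && fam %in% dup_fams) 2L else 1L
      for (cp in seq_len(ncopy)) {
        sq <- if (cp == 1L) tip_seqs[[fam]][[s]] else dup_seqs[[fam]]
        r <- r + 1L
        rows[[r]] <- list(
          gene_id = sprintf("FAM%03d_%d|%s", fam, cp, s),
          strain_id = s, family = fam, copy = cp,
          seq_int = sq,
          hgt_flag = fam %in% hgt_fams,
          annotation_category = categories[fam]
        )
      }
    }
  }
  n <- length(rows)
  genes <- data.frame(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    strain_id = vapply(rows, `[[`, "", "strain_id"),
    family = vapply(rows, `[[`, 0L, "family"),
    copy = vapply(rows, `[[`, 0L, "copy"),
    hgt_flag = vapply(rows, `[[`, TRUE, "hgt_flag"),
    annotation_category = vapply(rows, `[[`, "", "annotation_category"),
    stringsAsFactors = FALSE
  )

  # compartments and PlasFlow-like probabilities
  p_pl <- pmin(1, config$plasmid_fraction *
                 ifelse(genes$hgt_flag, config$hgt_plasmid_enrichment, 1))
  is_pl <- stats::runif(n) < p_pl
  plasmid_prob <- numeric(n)
  plasmid_prob[is_pl] <- stats::runif(sum(is_pl), 0.75, 0.98)
  lowconf <- stats::runif(n) < 0.2
  chp <- !is_pl & !lowconf
  plasmid_prob[chp] <- stats::runif(sum(chp), 0.02, 0.28)
  unc <- !is_pl & lowconf
  plasmid_prob[unc] <- stats::runif(sum(unc), 0.55, 0.69)
  genes$compartment <- ifelse(is_pl, "plasmid", "chromosome")
  genes$plasmid_prob <- plasmid_prob
  genes$chromosome_prob <- 1 - plasmid_prob

  # frameshift corruption: one inserted nucleotide, uniform position
  fs <- stats::runif(n) < config$frameshift_fraction
  seq_chr <- character(n)
  for (i in seq_len(n)) {
    sq <- rows[[i]]$seq_int
    if (fs[i]) {
      at <- sample.int(length(sq) + 1L, 1L)
      sq <- append(sq, sample.int(4L, 1L), after = at - 1L)
    }
    seq_chr[i] <- .int_to_nt(sq)
  }
  genes$sequence <- seq_chr
  genes$frameshift_flag <- fs

  # pairwise relationships: per gene x other strain
  rel <- expand.grid(i = seq_len(n), other_strain = tips,
                     stringsAsFactors = FALSE)
  rel <- rel[genes$strain_id[rel$i] != rel$other_strain, ]
  pres_ij <- present[cbind(genes$family[rel$i], match(rel$other_strain, tips))]
  rel$relation <- ifelse(!pres_ij, "absent",
                         ifelse(genes$copy[rel$i] == 2L, "paralog", "ortholog"))
  relations <- data.frame(gene_id = genes$gene_id[rel$i],
                          other_strain = rel$other_strain,
                          relation = rel$relation,
                          stringsAsFactors = FALSE)
  rownames(relations) <- NULL

  events <- data.frame(
    family = unlist(ev_fam, use.names = FALSE) %||% integer(0),
    edge = unlist(ev_edge, use.names = FALSE) %||% character(0),
    strain = unlist(ev_strain, use.names = FALSE) %||% character(0),
    pos = unlist(ev_pos, use.names = FALSE) %||% integer(0),
    from = unlist(ev_from, use.names = FALSE) %||% integer(0),
    to = unlist(ev_to, use.names = FALSE) %||% integer(0),
    syn = unlist(ev_syn, use.names = FALSE) %||% logical(0),
    stringsAsFactors = FALSE
  )

  genes <- genes[, c("gene_id", "strain_id", "family", "copy", "sequence",
                     "compartment", "plasmid_prob", "chromosome_prob",
                     "annotation_category", "hgt_flag", "frameshift_flag")]
  structure(list(genes = genes, relations = relations, events = events,
                 config = config),
            class = "strain_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.strain_set <- function(x, ...) {
  cat("Simulated strain set\n")
  cat(sprintf("  %d genes over %d strains, %d families (seed %d)\n",
              nrow(x$genes), length(unique(x$genes$strain_id)),
              x$config$n_families, x$config$seed))
  cat(sprintf("  HGT genes: %d  duplicates: %d  frameshifts: %d\n",
              sum(x$genes$hgt_flag), sum(x$genes$copy == 2L),
              sum(x$genes$frameshift_flag)))
  invisible(x)
}
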