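#' Default seven-strain guide tree for the simulator
#'
#' A rooted binary tree over seven baeocyte-forming strains, with branch
#' lengths in expected nucleotide substitution attempts per site. The
#' lengths are calibrated so that realized pairwise synonymous
#' divergences span roughly Ks 0.28 (the two Stanieria) to Ks 1.8 (the
#' Myxosarcina/Pleurocapsa pair), with the focal Hyella strain at
#' intermediate divergence from Chroococcidiopsis.
#'
#' @return A newick string.
#' @export
default_sim_tree <- function() {
  paste0(
    "((Hyella:0.35,(Chroococcidiopsis:0.35,Xenococcus:0.45):0.20):0.15,",
    "((Myxosarcina:0.90,Pleurocapsa:0.90):0.10,",
    "(Stanieria_PCC7437:0.14,Stanieria_NIES3757:0.14):0.30):0.15);"
  )
}

#' Simulator configuration
#'
#' Bundles all tunable parameters of the multi-strain codon-evolution
#' simulator. Defaults describe a seven-strain set whose pairwise
#' synonymous divergence, duplicate fraction, and gene-sharing structure
#' mirror a baeocyte-forming cyanobacterial strain panel.
#'
#' @param n_strains Number of strains (leaves of `tree`).
#' @param tree Rooted binary newick tree with branch lengths in expected
#'   substitution attempts per nucleotide site.
#' @param n_families Number of gene families at the root.
#' @param codon_length Codons per gene (>= 10).
#' @param omega Nonsynonymous/synonymous acceptance ratio in (0, 1].
#' @param dup_fraction Fraction of families duplicated in the focal
#'   strain (recent duplicate of the tip sequence).
#' @param dup_divergence Extra branch length applied to the duplicate
#'   copy, in substitution attempts per site.
#' @param loss_fraction Fraction of families lost in each non-focal
#'   strain.
#' @param hgt_fraction Fraction of families restricted to the
#'   donor/recipient pair and transferred between them.
#' @param hgt_divergence_scale Multiplier < 1 applied to the
#'   donor-recipient divergence of transferred genes.
#' @param hgt_donor,hgt_recipient Strain labels of the transfer pair;
#'   defaults are the most-shared marine pair (Pleurocapsa -> Hyella).
#' @param plasmid_fraction Probability that a gene is plasmid-borne.
#' @param hgt_plasmid_enrichment Multiplier on `plasmid_fraction` for
#'   transferred genes (capped at 1), letting the enrichment stage see
#'   signal.
#' @param frameshift_fraction Fraction of emitted sequences corrupted by
#'   a single 1-nt insertion at a uniform position.
#' @param category_probs Named probabilities for annotation categories
#'   `conserved_or_function`, `transposase`, `nonconserved_unknown`,
#'   `unannotated`, drawn i.i.d. per family.
#' @param focal_strain Focal (query) strain label; defaults to the first
#'   tip of `tree`.
#' @param seed Integer seed; all stochastic draws flow from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 7L,
                       tree = default_sim_tree(),
                       n_families = 120L,
                       codon_length = 150L,
                       omega = 0.1,
                       dup_fraction = 0.25,
                       dup_divergence = 0.05,
                       loss_fraction = 0.08,
                       hgt_fraction = 0.08,
                       hgt_divergence_scale = 0.3,
                       hgt_donor = NULL,
                       hgt_recipient = NULL,
                       plasmid_fraction = 0.12,
                       hgt_plasmid_enrichment = 1,
                       frameshift_fraction = 0.05,
                       category_probs = c(conserved_or_function = 0.70,
                                          transposase = 0.05,
                                          nonconserved_unknown = 0.20,
                                          unannotated = 0.05),
                       focal_strain = NULL,
                       seed = 1L) {
  phy <- ape::read.tree(text = tree)
  if (is.null(phy)) stop("tree is not parseable newick")
  if (length(phy$tip.label) != n_strains) {
    stop(sprintf("tree has %d leaves but n_strains = %d",
                 length(phy$tip.label), n_strains))
  }
  if (is.null(phy$edge.length)) stop("tree must carry branch lengths")
  if (codon_length < 10L) stop("codon_length must be >= 10")
  fracs <- c(dup_fraction, loss_fraction, hgt_fraction, plasmid_fraction,
             frameshift_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must be in [0, 1]")
  if (omega <= 0 || omega > 1) stop("omega must be in (0, 1]")
  if (hgt_divergence_scale <= 0 || hgt_divergence_scale >= 1) {
    stop("hgt_divergence_scale must be in (0, 1)")
  }
  if (abs(sum(category_probs) - 1) > 1e-8) {
    stop("category_probs must sum to 1")
  }
  if (is.null(focal_strain)) focal_strain <- phy$tip.label[1]
  if (!focal_strain %in% phy$tip.label) stop("focal_strain not in tree")
  if (is.null(hgt_recipient)) hgt_recipient <- focal_strain
  if (is.null(hgt_donor)) {
    # default donor: the non-focal tip with the largest terminal branch
    # among the opposite root clade, or simply the last tip
    cand <- setdiff(phy$tip.label, hgt_recipient)
    hgt_donor <- if ("Pleurocapsa" %in% cand) "Pleurocapsa" else cand[length(cand)]
  }
  if (!all(c(hgt_donor, hgt_recipient) %in% phy$tip.label) ||
      hgt_donor == hgt_recipient) {
    stop("hgt_donor/hgt_recipient must be two distinct tree tips")
  }
  structure(
    list(
      n_strains = as.integer(n_strains), tree = tree, phy = phy,
      n_families = as.integer(n_families),
      codon_length = as.integer(codon_length), omega = omega,
      dup_fraction = dup_fraction, dup_divergence = dup_divergence,
      loss_fraction = loss_fraction, hgt_fraction = hgt_fraction,
      hgt_divergence_scale = hgt_divergence_scale,
      hgt_donor = hgt_donor, hgt_recipient = hgt_recipient,
      plasmid_fraction = plasmid_fraction,
      hgt_plasmid_enrichment = hgt_plasmid_enrichment,
      frameshift_fraction = frameshift_fraction,
      category_probs = category_probs,
      focal_strain = focal_strain, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Codon-evolution simulator configuration\n")
  cat(sprintf("  strains: %d (focal: %s)  families: %d  codons/gene: %d\n",
              x$n_strains, x$focal_strain, x$n_families, x$codon_length))
  cat(sprintf("  omega: %.3g  dup: %.2f  loss: %.2f  hgt: %.2f (scale %.2f, %s -> %s)\n",
              x$omega, x$dup_fraction, x$loss_fraction, x$hgt_fraction,
              x$hgt_divergence_scale, x$hgt_donor, x$hgt_recipient))
  cat(sprintf("  plasmid: %.2f  frameshift: %.2f  seed: %d\n",
              x$plasmid_fraction, x$frameshift_fraction, x$seed))
  invisible(x)
}
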