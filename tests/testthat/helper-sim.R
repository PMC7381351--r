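# Shared small simulator configurations for the test suite. Problem
# sizes are scaled down from the package defaults so the whole suite
# runs quickly; the methods vignette documents the sizes used.

two_strain_config <- function(total_branch = 0.5, n_families = 50,
                              codon_length = 100, omega = 0.1, seed = 1,
                              ...) {
  sim_config(n_strains = 2,
             tree = sprintf("(A:%f,B:%f);", total_branch / 2,
                            total_branch / 2),
             n_families = n_families, codon_length = codon_length,
             omega = omega, dup_fraction = 0, loss_fraction = 0,
             hgt_fraction = 0, frameshift_fraction = 0,
             plasmid_fraction = 0, seed = seed, ...)
}

# three-strain scenario with pair-restricted transfers between A and B
hgt_scenario_config <- function(seed, hgt_divergence_scale = 0.3) {
  sim_config(n_strains = 3,
             tree = "((A:0.3,B:0.3):0.2,C:0.5);",
             n_families = 40, codon_length = 150, omega = 0.1,
             dup_fraction = 0, loss_fraction = 0,
             hgt_fraction = 0.3, hgt_divergence_scale = hgt_divergence_scale,
             hgt_donor = "B", hgt_recipient = "A",
             frameshift_fraction = 0, plasmid_fraction = 0.1,
             focal_strain = "A", seed = seed)
}

small_default_config <- function(seed = 1, ...) {
  sim_config(n_families = 40, codon_length = 100, seed = seed, ...)
}

# per-family Ks between two strains (copy-1, untouched families)
family_ks <- function(ss, strain_a, strain_b, families = NULL) {
  g <- ss$genes[ss$genes$copy == 1L & !ss$genes$frameshift_flag, ]
  if (!is.null(families)) g <- g[g$family %in% families, ]
  fams <- intersect(g$family[g$strain_id == strain_a],
                    g$family[g$strain_id == strain_b])
  vapply(fams, function(f) {
    a <- g$sequence[g$family == f & g$strain_id == strain_a]
    b <- g$sequence[g$family == f & g$strain_id == strain_b]
    ng86(a, b)$Ks
  }, numeric(1))
}

# homology calls derived directly from the simulator's truth relations
calls_from_truth <- function(ss) {
  focal <- ss$config$focal_strain
  rel <- ss$relations
  rel <- rel[grepl(paste0("\\|", focal, "$"), rel$gene_id), ]
  data.frame(query_gene = rel$gene_id,
             subject_strain = rel$other_strain,
             label = ifelse(rel$relation == "absent", "no_similarity",
                            rel$relation),
             forward_best = NA_character_, reverse_best = NA_character_,
             forward_score = NA_real_, stringsAsFactors = FALSE)
}
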