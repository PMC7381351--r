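# End-to-end orchestration: simulate -> bin -> homology -> divergence
# -> presence classes -> plasmid enrichment, with logged, checksummed,
# seed-reproducible outputs.

#' Pipeline run configuration
#'
#' @param out_dir Output directory.
#' @param seed Integer seed driving every stochastic stage.
#' @param sim A [sim_config()]; its own seed is overridden by `seed`.
#' @param coverage_min,identity_margin Binning thresholds.
#' @param score_min RBH score threshold.
#' @param window_syn_sites Synonymous sites per Ks window.
#' @param plasmid_threshold Plasmid-probability threshold.
#' @param stages Character vector of stages to run, in dependency
#'   order; later stages require earlier ones.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       sim = sim_config(n_families = 60, codon_length = 100,
                                        hgt_fraction = 0.15,
                                        hgt_plasmid_enrichment = 4,
                                        seed = seed),
                       coverage_min = 70, identity_margin = 10,
                       score_min = 50, window_syn_sites = 200,
                       plasmid_threshold = 0.7,
                       stages = c("simulate", "bin", "rbh", "divergence",
                                  "classes", "plasmid-test")) {
  known <- c("simulate", "bin", "rbh", "divergence", "classes",
             "plasmid-test")
  if (!all(stages %in% known)) stop("unknown stage name")
  sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 coverage_min = coverage_min,
                 identity_margin = identity_margin, score_min = score_min,
                 window_syn_sites = window_syn_sites,
                 plasmid_threshold = plasmid_threshold,
                 stages = known[known %in% stages]),
            class = "run_config")
}

#' Run the full inference chain on a simulated strain set
#'
#' Executes the configured stages in dependency order, writing
#' tab-separated tables and JSON summaries under `out_dir`, a run log,
#' and a manifest listing every output file with its md5 checksum.
#' Identical configuration and seed give byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `manifest` data.frame and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir)) stop("cannot create ", config$out_dir)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  cat("", file = log_path)
  logf("# pipeline run, seed %d", config$seed)
  logf("# R %s, baeocomp %s", getRversion(),
       as.character(utils::packageVersion("baeocomp")))
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, path)
    path
  }
  res <- list()
  run <- function(s) s %in% config$stages

  if (run("simulate")) {
    logf("stage simulate: %d families x %d strains",
         config$sim$n_families, config$sim$n_strains)
    ss <- simulate_strain_set(config$sim)
    fx <- write_fixture(ss, file.path(config$out_dir, "fixture"))
    written <- c(written,
                 file.path(config$out_dir, "fixture", fx$file),
                 file.path(config$out_dir, "fixture", "manifest.json"))
    res$strain_set <- ss
    logf("  %d genes emitted", nrow(ss$genes))
  }

  if (run("bin")) {
    prof <- simulate_hit_profiles(n_cyano = 40, n_contam = 40,
                                  seed = config$seed + 1L)
    dec <- classify_contigs(prof$hit_table, prof$contig_meta,
                            coverage_min = config$coverage_min,
                            identity_margin = config$identity_margin)
    b2 <- data.frame(contig_id = prof$truth$contig_id,
                     label = ifelse(prof$truth$origin == "cyano",
                                    "cyanobacterial", "other"))
    cg <- congruence_filter(dec, prof$hit_table, prof$contig_meta, b2,
                            identity_margin = config$identity_margin)
    emit(cg$decisions, "bin_decisions.tsv")
    emit(data.frame(contig_id = cg$retained), "bin_retained.tsv")
    res$binning <- cg
    logf("stage bin: %d retained, congruence %.3f",
         length(cg$retained), cg$congruence_fraction)
  }

  if (run("rbh")) {
    g <- res$strain_set$genes
    focal <- config$sim$focal_strain
    calls <- rbh_all(g, focal, score_threshold = config$score_min)
    summ <- summarize_homology(calls, sum(g$strain_id == focal))
    uniq <- union_no_similarity(calls)
    emit(calls, "homology_calls.tsv")
    emit(summ, "homology_summary.tsv")
    emit(data.frame(gene_id = uniq), "strain_specific_genes.tsv")
    res$calls <- calls
    res$homology_summary <- summ
    res$strain_specific <- uniq
    logf("stage rbh: %d calls, %d strain-specific genes",
         nrow(calls), length(uniq))
  }

  if (run("divergence")) {
    ss <- res$strain_set
    focal <- config$sim$focal_strain
    alns <- align_families(ss$genes)
    flt <- filter_multiple_of_three(alns)
    emit(flt$dropped, "alignments_dropped.tsv")
    strains <- unique(ss$genes$strain_id)
    n_taxa <- vapply(flt$kept, function(a) length(a$seqs), integer(1))
    all_set <- flt$kept[n_taxa == length(strains)]
    pair_strain <- config$sim$hgt_donor
    pair_set <- Filter(function(a) {
      setequal(names(a$seqs), c(focal, pair_strain))
    }, flt$kept)
    logf("stage divergence: %d all-strain families, %d pair families (%s)",
         length(all_set), length(pair_set), pair_strain)
    div_rows <- do.call(rbind, lapply(names(all_set), function(id) {
      a <- all_set[[id]]
      d <- ng86(a$seqs[[focal]], a$seqs[[pair_strain]])
      data.frame(family = id, S = d$S, N = d$N, Sd = d$Sd, Nd = d$Nd,
                 Ks = d$Ks, Ka = d$Ka)
    }))
    emit(div_rows, "divergence_all_families.tsv")
    conc_all <- concatenate_alignments(all_set)
    w_all <- withCallingHandlers(
      windowed_ks(conc_all, focal, pair_strain,
                  config$window_syn_sites, source = "all"),
      warning = function(w) {
        logf("  note: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    res$windows_all <- w_all
    emit(as.data.frame(w_all), "ks_windows_all.tsv")
    mw <- NULL
    if (length(pair_set) >= 1L) {
      conc_pair <- concatenate_alignments(pair_set)
      w_pair <- suppressWarnings(
        windowed_ks(conc_pair, focal, pair_strain,
                    config$window_syn_sites,
                    source = paste0("pair:", pair_strain)))
      res$windows_pair <- w_pair
      emit(as.data.frame(w_pair), "ks_windows_pair.tsv")
      if (nrow(w_pair) > 0L && nrow(w_all) > 0L) {
        mw <- mann_whitney(w_pair$Ks, w_all$Ks, alternative = "less")
        logf("  Mann-Whitney pair-vs-all: U = %.1f, one-sided p = %.4g",
             mw$U, mw$p_value)
      }
    }
    # rate test on the concatenated all-strain alignment: focal vs its
    # HGT partner, most distant strain as outgroup
    other <- setdiff(strains, c(focal, pair_strain))
    outg <- other[length(other)]
    rrt3 <- tajima_rrt(conc_all$seqs[[focal]], conc_all$seqs[[pair_strain]],
                       conc_all$seqs[[outg]], mode = "third_codon")
    rrta <- tajima_rrt(conc_all$seqs[[focal]], conc_all$seqs[[pair_strain]],
                       conc_all$seqs[[outg]], mode = "amino_acid")
    res$mann_whitney <- mw
    res$rate_tests <- list(third_codon = rrt3, amino_acid = rrta)
    test_json <- list(
      mann_whitney = if (is.null(mw)) NULL else
        list(U = mw$U, p_one_sided = mw$p_value),
      tajima_third_codon = list(m1 = rrt3$m1, m2 = rrt3$m2,
                                chi_square = rrt3$chi_square,
                                p = rrt3$p_value),
      tajima_amino_acid = list(m1 = rrta$m1, m2 = rrta$m2,
                               chi_square = rrta$chi_square,
                               p = rrta$p_value)
    )
    tp <- file.path(config$out_dir, "divergence_tests.json")
    jsonlite::write_json(test_json, tp, auto_unbox = TRUE, digits = NA)
    written <- c(written, tp)
  }

  if (run("classes")) {
    pm <- build_matrix(res$calls, res$strain_set$genes)
    prof <- withCallingHandlers(
      class_category_profile(pm),
      warning = function(w) {
        logf("  note: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    freq <- strain_absence_frequency(pm)
    emit(data.frame(gene_id = rownames(pm$presence), class = pm$class,
                    pm$presence, check.names = FALSE),
         "presence_matrix.tsv")
    emit(prof, "class_category_profile.tsv")
    emit(freq$absence, "strain_absence_frequency.tsv")
    res$presence <- pm
    logf("stage classes: class sizes %s",
         paste(sprintf("%d:%d", sort(unique(pm$class)),
                       as.integer(table(pm$class))), collapse = " "))
  }

  if (run("plasmid-test")) {
    g <- res$strain_set$genes
    focal <- config$sim$focal_strain
    comp <- apply_threshold(
      data.frame(id = g$gene_id, plasmid_prob = g$plasmid_prob,
                 chromosome_prob = g$chromosome_prob),
      config$plasmid_threshold)
    lens <- stats::setNames(nchar(g$sequence), g$gene_id)
    sweep <- vapply(c(0.7, 0.75, 0.8, 0.85), function(th) {
      plasmid_fraction(apply_threshold(
        data.frame(id = g$gene_id, plasmid_prob = g$plasmid_prob,
                   chromosome_prob = g$chromosome_prob), th), lens)
    }, numeric(1))
    emit(data.frame(threshold = c(0.7, 0.75, 0.8, 0.85),
                    plasmid_fraction = sweep),
         "plasmid_fraction_sweep.tsv")
    pm <- res$presence
    K <- ncol(pm$presence)
    focal_genes <- rownames(pm$presence)
    all_orth <- focal_genes[pm$class == 0L]
    top <- focal_genes[pm$class == K - 1L]
    pair_sets <- list()
    for (s in colnames(pm$presence)) {
      ids <- top[pm$presence[top, s]]
      if (length(ids) > 0L) pair_sets[[s]] <- ids
    }
    res$compartments <- comp
    if (length(pair_sets) > 0L && length(all_orth) > 0L) {
      enr <- enrichment_pipeline(pair_sets, all_orth, comp)
      emit(enr, "plasmid_enrichment.tsv")
      res$enrichment <- enr
      logf("stage plasmid-test: %d pair sets, min p = %.4g",
           nrow(enr), min(enr$p_two_sided))
    } else {
      logf("stage plasmid-test: no pair-specific sets; enrichment skipped")
    }
  }

  manifest <- data.frame(file = sub(paste0("^", config$out_dir, "/?"), "",
                                    written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  logf("done: %d files written", nrow(manifest))
  res$manifest <- manifest
  invisible(res)
}
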