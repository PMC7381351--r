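#' Write a simulated strain set to disk as plain-text fixtures
#'
#' Emits one nucleotide FASTA per strain (gene ids encode family, copy,
#' and strain as `FAM<k>_<copy>|<strain>`), a tab-separated truth table,
#' a tab-separated compartment table with PlasFlow-style probabilities,
#' and a JSON manifest listing every file with its md5 checksum.
#'
#' @param strain_set Output of [simulate_strain_set()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest as a data.frame (`file`, `md5`,
#'   `n_records`); also written to `manifest.json`.
#' @export
write_fixture <- function(strain_set, out_dir) {
  stopifnot(inherits(strain_set, "strain_set"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create ", out_dir)
  }
  g <- strain_set$genes
  files <- character(0)
  nrec <- integer(0)
  for (s in unique(g$strain_id)) {
    gs <- g[g$strain_id == s, ]
    fa <- Biostrings::DNAStringSet(gs$sequence)
    names(fa) <- gs$gene_id
    path <- file.path(out_dir, paste0(s, ".fasta"))
    Biostrings::writeXStringSet(fa, path)
    files <- c(files, path)
    nrec <- c(nrec, length(fa))
  }

  # relation map packed per gene: "strain:relation;..."
  rel <- strain_set$relations
  rel_str <- vapply(split(paste0(rel$other_strain, ":", rel$relation),
                          rel$gene_id),
                    paste, character(1), collapse = ";")
  truth <- data.frame(
    gene_id = g$gene_id, strain = g$strain_id, family = g$family,
    copy = g$copy,
    relation_map = unname(rel_str[g$gene_id]),
    hgt_flag = g$hgt_flag, compartment = g$compartment,
    frameshift_flag = g$frameshift_flag,
    annotation_category = g$annotation_category,
    stringsAsFactors = FALSE
  )
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  comp <- data.frame(
    id = g$gene_id,
    chromosome_prob = round(g$chromosome_prob, 4),
    plasmid_prob = round(g$plasmid_prob, 4),
    label = g$compartment,
    stringsAsFactors = FALSE
  )
  comp_path <- file.path(out_dir, "compartments.tsv")
  utils::write.table(comp, comp_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, truth_path, comp_path)
  nrec <- c(nrec, nrow(truth), nrow(comp))

  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    n_records = nrec,
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture directory back into GeneRecord form
#'
#' @param dir Directory written by [write_fixture()].
#' @return A list with `genes` (gene_id, strain_id, sequence plus truth
#'   columns) and `relations` (long form), mirroring
#'   [simulate_strain_set()] output.
#' @export
read_fixture <- function(dir) {
  truth <- utils::read.delim(file.path(dir, "truth.tsv"),
                             stringsAsFactors = FALSE)
  fastas <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  seqs <- character(0)
  for (f in fastas) {
    x <- Biostrings::readDNAStringSet(f)
    seqs <- c(seqs, stats::setNames(as.character(x), names(x)))
  }
  truth$sequence <- unname(seqs[truth$gene_id])
  truth$strain_id <- truth$strain
  pieces <- strsplit(truth$relation_map, ";", fixed = TRUE)
  relations <- do.call(rbind, lapply(seq_along(pieces), function(i) {
    kv <- strsplit(pieces[[i]], ":", fixed = TRUE)
    data.frame(gene_id = truth$gene_id[i],
               other_strain = vapply(kv, `[`, "", 1L),
               relation = vapply(kv, `[`, "", 2L),
               stringsAsFactors = FALSE)
  }))
  list(genes = truth, relations = relations)
}
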