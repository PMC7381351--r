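# Presence/absence inventory of focal-strain genes across the
# comparison strains, with absence classes and annotation-category
# profiles.

#' Build the presence/absence matrix and absence classes
#'
#' A focal gene is "present" in a subject strain when its homology
#' label there is `ortholog` or `paralog` (no-similarity is the
#' complement of that union). A gene's class is the number of strains
#' it is absent from: class 0 genes are present everywhere, class K
#' (K = number of strains) genes are focal-specific and coincide with
#' [union_no_similarity()].
#'
#' @param calls HomologyCall data.frame covering every (gene, strain)
#'   pair.
#' @param genes Optional GeneRecord data.frame supplying
#'   `annotation_category` per gene.
#' @return List of class `presence_matrix`: `presence` (logical genes x
#'   strains matrix), `class` (named integer vector), `category`
#'   (named character vector or NULL).
#' @export
build_matrix <- function(calls, genes = NULL) {
  strains <- sort(unique(calls$subject_strain))
  gene_ids <- sort(unique(calls$query_gene))
  cover <- table(calls$query_gene)
  if (length(unique(cover)) != 1L || cover[1] != length(strains) ||
      anyDuplicated(calls[, c("query_gene", "subject_strain")])) {
    stop("calls must cover every (gene, strain) pair exactly once")
  }
  pres <- matrix(NA, length(gene_ids), length(strains),
                 dimnames = list(gene_ids, strains))
  pres[cbind(match(calls$query_gene, gene_ids),
             match(calls$subject_strain, strains))] <-
    calls$label != "no_similarity"
  cls <- rowSums(!pres)
  category <- NULL
  if (!is.null(genes)) {
    category <- stats::setNames(genes$annotation_category, genes$gene_id)
    category <- category[gene_ids]
  }
  structure(list(presence = pres, class = cls, category = category),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("Presence/absence matrix: %d genes x %d strains\n",
              nrow(x$presence), ncol(x$presence)))
  print(table(class = x$class))
  invisible(x)
}

#' Annotation-category profile per absence class
#'
#' For each absence class, the fraction of genes annotated as
#' conserved/recognizable-function, transposase, or non-conserved
#' protein of unknown function. Unannotated genes are excluded with a
#' warning; rows sum to 1 over the included categories (empty classes
#' give empty rows, not division errors).
#'
#' @param matrix A `presence_matrix` built with gene categories.
#' @return data.frame: `class`, `n_genes`, `conserved_or_function`,
#'   `transposase`, `nonconserved_unknown`.
#' @export
class_category_profile <- function(matrix) {
  stopifnot(inherits(matrix, "presence_matrix"))
  if (is.null(matrix$category)) stop("matrix was built without categories")
  cats <- c("conserved_or_function", "transposase", "nonconserved_unknown")
  cat_v <- matrix$category
  drop <- is.na(cat_v) | cat_v == "unannotated"
  if (any(drop)) {
    warning(sprintf("%d unannotated genes excluded from category profile",
                    sum(drop)))
  }
  cls <- matrix$class[!drop]
  cat_v <- cat_v[!drop]
  out <- do.call(rbind, lapply(sort(unique(matrix$class)), function(k) {
    sel <- cls == k
    n <- sum(sel)
    fr <- if (n > 0) {
      as.numeric(table(factor(cat_v[sel], levels = cats))) / n
    } else {
      rep(NA_real_, length(cats))
    }
    data.frame(class = k, n_genes = n,
               conserved_or_function = fr[1], transposase = fr[2],
               nonconserved_unknown = fr[3])
  }))
  rownames(out) <- NULL
  out
}

#' Per-strain absence frequencies for classes 1 to K-1
#'
#' For class k, counts per strain of membership in the absent set
#' (frequencies sum to k x class size across strains). For the top
#' informative class (absent in all strains but one) a complementary
#' presence view is also returned: the single other strain retaining
#' each gene.
#'
#' @param matrix A `presence_matrix`.
#' @return List: `absence` (long data.frame `class`, `strain`,
#'   `n_absent`), `presence_top_class` (data.frame `strain`,
#'   `n_present` for the class-(K-1) genes), `top_class` (its class
#'   number).
#' @export
strain_absence_frequency <- function(matrix) {
  stopifnot(inherits(matrix, "presence_matrix"))
  pres <- matrix$presence
  K <- ncol(pres)
  strains <- colnames(pres)
  rows <- list()
  for (k in seq_len(K - 1L)) {
    sel <- matrix$class == k
    n_abs <- if (any(sel)) {
      colSums(!pres[sel, , drop = FALSE])
    } else {
      stats::setNames(rep(0L, K), strains)
    }
    rows[[k]] <- data.frame(class = k, strain = strains,
                            n_absent = as.integer(n_abs),
                            stringsAsFactors = FALSE)
  }
  absence <- do.call(rbind, rows)
  rownames(absence) <- NULL
  top <- K - 1L
  sel <- matrix$class == top
  n_pres <- if (any(sel)) {
    colSums(pres[sel, , drop = FALSE])
  } else {
    stats::setNames(rep(0L, K), strains)
  }
  list(absence = absence,
       presence_top_class = data.frame(strain = strains,
                                       n_present = as.integer(n_pres),
                                       stringsAsFactors = FALSE),
       top_class = top)
}
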