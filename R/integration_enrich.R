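#' Transcriptome-proteome consistency report
#'
#' Intersects the differential protein set with (1) the differential mRNA
#' set, (2) the cis-target genes of lncRNAs and (3) the origin genes of
#' circRNAs, after case-insensitive symbol harmonisation. For every
#' overlapping gene with a fold change in both layers, a direction
#' concordance flag records whether the mRNA and protein log2 fold changes
#' share a sign.
#'
#' @param de_mrna DE table for the mRNA layer (from \code{\link{nb_test}}).
#' @param de_protein DE table for the protein layer (from
#'   \code{\link{protein_test}}).
#' @param links link table (from \code{\link{cis_targets}} /
#'   \code{\link{origin_genes}}, possibly rbind-ed); may be NULL.
#' @return list of class \code{consistency_report} with data.frames
#'   \code{mrna_dep} (gene, lfc_mrna, lfc_protein, concordant),
#'   \code{lnc_target_dep} and \code{circ_origin_dep} (gene, source_id,
#'   lfc_protein, lfc_mrna, concordant; lfc_mrna NA when the gene has no
#'   mRNA record).
#' @export
overlap_sets <- function(de_mrna, de_protein, links = NULL) {
  harmon <- function(x) toupper(as.character(x))
  dep <- de_protein[de_protein$is_de, , drop = FALSE]
  dep_genes <- harmon(dep$feature_id)
  dem <- de_mrna[de_mrna$is_de, , drop = FALSE]
  dem_genes <- harmon(dem$feature_id)
  mrna_lfc <- stats::setNames(de_mrna$log2FoldChange, harmon(de_mrna$feature_id))
  prot_lfc <- stats::setNames(dep$log2FoldChange, dep_genes)

  ov <- intersect(dem_genes, dep_genes)
  mrna_dep <- data.frame(
    gene = ov,
    lfc_mrna = unname(mrna_lfc[ov]),
    lfc_protein = unname(prot_lfc[ov]),
    stringsAsFactors = FALSE
  )
  mrna_dep$concordant <- sign(mrna_dep$lfc_mrna) == sign(mrna_dep$lfc_protein)

  link_overlap <- function(type) {
    if (is.null(links) || nrow(links) == 0L) {
      return(data.frame(gene = character(), source_id = character(),
                        lfc_protein = numeric(), lfc_mrna = numeric(),
                        concordant = logical()))
    }
    lk <- links[links$link_type == type, , drop = FALSE]
    lk$gene <- harmon(lk$target_gene)
    lk <- lk[lk$gene %in% dep_genes, , drop = FALSE]
    out <- data.frame(
      gene = lk$gene,
      source_id = lk$source_id,
      lfc_protein = unname(prot_lfc[lk$gene]),
      lfc_mrna = ifelse(lk$gene %in% names(mrna_lfc),
                        unname(mrna_lfc[lk$gene]), NA_real_),
      stringsAsFactors = FALSE
    )
    out$concordant <- ifelse(is.na(out$lfc_mrna), NA,
                             sign(out$lfc_mrna) == sign(out$lfc_protein))
    unique(out)
  }

  structure(list(
    mrna_dep = mrna_dep,
    lnc_target_dep = link_overlap("cis_target"),
    circ_origin_dep = link_overlap("origin")
  ), class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("consistency_report:\n")
  cat("  DE mRNA n DEP:         ", nrow(x$mrna_dep), "gene(s)\n")
  cat("  lncRNA cis-target n DEP:", nrow(x$lnc_target_dep), "gene(s)\n")
  cat("  circRNA origin n DEP:  ", nrow(x$circ_origin_dep), "gene(s)\n")
  invisible(x)
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, with universe size N, set size K (after intersection
#' with the universe), query size n and overlap k, the enrichment p-value is
#' the upper tail \code{P[X >= k]} of the hypergeometric distribution.
#' BH-adjusted q-values are computed across the collection and results are
#' sorted by p. Sets with no member in the universe are skipped.
#'
#' @param query character vector of query genes (subset of universe; genes
#'   outside the universe are dropped with a warning).
#' @param collection named list of character vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param universe character vector of background genes.
#' @param p_threshold significance threshold on the raw p-value reported in
#'   the \code{significant} column (default 0.05).
#' @return data.frame: set, k, K, n, N, pvalue, qvalue, significant.
#' @export
hypergeom_enrich <- function(query, collection, universe,
                             p_threshold = 0.05) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(toupper(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe were dropped",
                    length(outside)))
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(toupper(collection[[nm]])), universe)
    K <- length(set)
    if (K == 0L) return(NULL)
    k <- length(intersect(set, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, pvalue = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), pvalue = numeric(),
                      qvalue = numeric(), significant = logical()))
  }
  out <- do.call(rbind, rows)
  out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
  out$significant <- out$pvalue < p_threshold
  out <- out[order(out$pvalue, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
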