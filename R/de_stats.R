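#' Feature-by-sample omics matrix
#'
#' Light container for a numeric feature-by-sample matrix (raw counts or LFQ
#' intensities) with per-sample group labels and a layer tag.
#'
#' @param values numeric matrix, features in rows, samples in columns;
#'   no negative values.
#' @param groups character vector of group labels, one per column
#'   (e.g. "stable"/"unstable").
#' @param layer one of "mrna", "lncrna", "circrna", "protein".
#' @return object of class \code{omics_matrix}.
#' @export
omics_matrix <- function(values, groups,
                         layer = c("mrna", "lncrna", "circrna", "protein")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) stop("omics values must be non-negative")
  if (length(groups) != ncol(values)) {
    stop("one group label per sample column is required")
  }
  structure(list(values = values, groups = as.character(groups),
                 layer = layer),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples (%s)\n",
              x$layer, nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$groups)),
                            table(x$groups)), collapse = ", ")))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed as the median, over features
#' with all-positive counts, of the ratio of each count to the feature's
#' geometric mean across samples; factors are rescaled to geometric mean 1.
#' When no feature is positive in every sample, library-size ratios are used
#' instead (with a warning).
#'
#' @param counts an \code{\link{omics_matrix}} or numeric matrix.
#' @return numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "omics_matrix")) counts$values else as.matrix(counts)
  if (ncol(m) == 1L) return(stats::setNames(1, colnames(m)))
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    warning("no feature with all-positive counts; using library-size ratios")
    sf <- colSums(m)
    if (any(sf == 0)) stop("cannot derive size factors: empty library")
  } else {
    mm <- m[all_pos, , drop = FALSE]
    log_geo <- rowMeans(log(mm))
    sf <- apply(mm, 2, function(col) exp(stats::median(log(col) - log_geo)))
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(m))
}

#' FPKM normalisation
#'
#' Fragments per kilobase of feature per million mapped reads:
#' \code{fpkm_ij = count_ij * 1e9 / (length_i * library_size_j)} with
#' library size the raw column sum. A zero library size yields an all-zero
#' column.
#'
#' @param counts an \code{\link{omics_matrix}} or matrix of raw counts.
#' @param lengths positive feature lengths in nt, recycled over rows.
#' @return numeric matrix of FPKM values.
#' @export
fpkm <- function(counts, lengths) {
  m <- if (inherits(counts, "omics_matrix")) counts$values else as.matrix(counts)
  lengths <- rep_len(lengths, nrow(m))
  if (any(lengths <= 0)) stop("feature lengths must be positive")
  lib <- colSums(m)
  out <- m * 1e9 / outer(lengths, ifelse(lib == 0, 1, lib))
  out[, lib == 0] <- 0
  out
}

# Resolve the reference (denominator) group of a two-group matrix.
two_group_split <- function(om, reference_group = NULL) {
  groups <- om$groups
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two sample groups are required")
  ref <- reference_group %||% if ("stable" %in% lv) "stable" else lv[1]
  if (!ref %in% lv) stop("reference group not present in sample labels")
  list(ref = which(groups == ref), alt = which(groups != ref),
       ref_name = ref, alt_name = setdiff(lv, ref))
}

#' Negative-binomial Wald test for two-group count data
#'
#' Median-of-ratios normalisation, followed by a per-feature two-group
#' comparison under the NB variance model \code{var = mu + alpha * mu^2}.
#' The dispersion \code{alpha} is estimated by method of moments within each
#' group and pooled across both groups (floored at
#' \code{dispersion_floor}). The Wald statistic on the difference of log
#' group means (delta-method standard error) is referred to a t distribution
#' with \code{n1 + n2 - 2} degrees of freedom, which keeps the test
#' calibrated at the small group sizes the design targets. The fold change
#' is \code{log2((mean_alt + pc) / (mean_ref + pc))} on normalised counts.
#' A feature is flagged differential when \code{|log2FoldChange| > 1} and
#' raw \code{p < 0.05} (strict inequalities); the BH-adjusted q-value is
#' reported alongside but takes no part in the flag.
#'
#' @param counts an \code{\link{omics_matrix}} of raw counts with two
#'   groups of at least two samples each.
#' @param pseudocount added to group means before the ratio (default 0.5
#'   normalised counts).
#' @param dispersion_floor lower bound for the pooled dispersion.
#' @param lfc_threshold,p_threshold the differential-expression criterion.
#' @param reference_group denominator group; defaults to "stable" when
#'   present.
#' @return data.frame with feature_id, baseMean, log2FoldChange, pvalue,
#'   qvalue, is_de.
#' @export
nb_test <- function(counts, pseudocount = 0.5, dispersion_floor = 1e-8,
                    lfc_threshold = 1.0, p_threshold = 0.05,
                    reference_group = NULL) {
  stopifnot(inherits(counts, "omics_matrix"))
  gs <- two_group_split(counts, reference_group)
  if (length(gs$ref) < 2L || length(gs$alt) < 2L) {
    stop("each group needs at least two samples")
  }
  sf <- size_factors(counts)
  norm <- sweep(counts$values, 2, sf, "/")
  x1 <- norm[, gs$ref, drop = FALSE]
  x2 <- norm[, gs$alt, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, stats::var)
  v2 <- apply(x2, 1, stats::var)
  a1 <- (v1 - m1) / pmax(m1, dispersion_floor)^2
  a2 <- (v2 - m2) / pmax(m2, dispersion_floor)^2
  alpha <- pmax(((n1 - 1) * a1 + (n2 - 1) * a2) / (n1 + n2 - 2),
                dispersion_floor)
  lfc <- log2((m2 + pseudocount) / (m1 + pseudocount))
  se <- sqrt((1 / (m1 + pseudocount) + alpha) / n1 +
               (1 / (m2 + pseudocount) + alpha) / n2)
  w <- (log(m2 + pseudocount) - log(m1 + pseudocount)) / se
  p <- 2 * stats::pt(-abs(w), df = n1 + n2 - 2)
  zero <- rowSums(counts$values) == 0
  p[zero] <- 1
  lfc[zero] <- 0
  q <- stats::p.adjust(p, method = "BH")
  data.frame(
    feature_id = rownames(counts$values) %||% sprintf("F%05d", seq_along(p)),
    baseMean = rowMeans(norm),
    log2FoldChange = lfc,
    pvalue = p,
    qvalue = q,
    is_de = abs(lfc) > lfc_threshold & p < p_threshold,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Welch test for label-free proteomic intensities
#'
#' Intensities are log2-transformed (zeros treated as missing), each protein
#' is compared between groups with a Welch two-sample t test, and the fold
#' change is the difference of group means in log2 space. Proteins with
#' fewer than two observed values in either group get p = 1 and a
#' \code{low_n} flag; proteins with no observed value at all are excluded
#' from the BH adjustment (q = NA). The differential criterion is the same
#' as for the count layers: \code{|log2FoldChange| > 1} and raw
#' \code{p < 0.05}.
#'
#' @param lfq an \code{\link{omics_matrix}} of positive intensities
#'   (layer "protein"); zeros/NA are missing values.
#' @param lfc_threshold,p_threshold the differential criterion.
#' @param reference_group denominator group; defaults to "stable".
#' @return data.frame with feature_id, baseMean, log2FoldChange, pvalue,
#'   qvalue, is_de, low_n.
#' @export
protein_test <- function(lfq, lfc_threshold = 1.0, p_threshold = 0.05,
                         reference_group = NULL) {
  stopifnot(inherits(lfq, "omics_matrix"))
  gs <- two_group_split(lfq, reference_group)
  vals <- lfq$values
  vals[vals == 0] <- NA
  lv <- log2(vals)
  n <- nrow(lv)
  p <- rep(1, n); lfc <- rep(0, n); low_n <- logical(n); all_na <- logical(n)
  base <- rowMeans(vals, na.rm = TRUE)
  for (i in seq_len(n)) {
    y1 <- lv[i, gs$ref]; y1 <- y1[!is.na(y1)]
    y2 <- lv[i, gs$alt]; y2 <- y2[!is.na(y2)]
    if (length(y1) == 0L && length(y2) == 0L) {
      all_na[i] <- TRUE; low_n[i] <- TRUE
      next
    }
    lfc[i] <- mean(y2) - mean(y1)
    if (length(y1) < 2L || length(y2) < 2L) {
      low_n[i] <- TRUE
      next
    }
    if (stats::sd(y1) == 0 && stats::sd(y2) == 0) {
      p[i] <- if (isTRUE(all.equal(mean(y1), mean(y2)))) 1 else 0
    } else {
      p[i] <- stats::t.test(y2, y1, var.equal = FALSE)$p.value
    }
  }
  lfc[all_na] <- NA_real_
  q <- rep(NA_real_, n)
  q[!all_na] <- stats::p.adjust(p[!all_na], method = "BH")
  data.frame(
    feature_id = rownames(vals) %||% sprintf("P%05d", seq_len(n)),
    baseMean = base,
    log2FoldChange = lfc,
    pvalue = p,
    qvalue = q,
    is_de = !all_na & abs(lfc) > lfc_threshold & p < p_threshold,
    low_n = low_n,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Relative qPCR quantification (2^-ddCt)
#'
#' For each sample, \code{dCt = Ct_target - Ct_reference}; then
#' \code{ddCt = mean(dCt unstable) - mean(dCt stable)} and the fold change
#' of the unstable group relative to the stable group (set to 1) is
#' \code{2^-ddCt}. Samples missing the reference gene Ct are dropped with a
#' warning.
#'
#' @param ct data.frame with columns \code{sample}, \code{group},
#'   \code{gene}, \code{ct}.
#' @param target target gene name(s); defaults to every non-reference gene.
#' @param reference reference (housekeeping) gene name.
#' @param reference_group group set to fold 1 (default "stable").
#' @return data.frame with target, ddct, fold.
#' @export
ddct <- function(ct, target = NULL, reference, reference_group = "stable") {
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(ct)))
  if (!reference %in% ct$gene) stop("reference gene absent from the Ct table")
  target <- target %||% setdiff(unique(ct$gene), reference)
  ref_ct <- ct[ct$gene == reference, ]
  out <- lapply(target, function(tg) {
    tgt <- ct[ct$gene == tg, ]
    merged <- merge(tgt, ref_ct, by = c("sample", "group"),
                    suffixes = c("_t", "_r"))
    dropped <- setdiff(tgt$sample, merged$sample)
    if (length(dropped)) {
      warning(sprintf("dropping sample(s) without reference Ct: %s",
                      paste(dropped, collapse = ", ")))
    }
    dct <- merged$ct_t - merged$ct_r
    is_ref_grp <- merged$group == reference_group
    if (!any(is_ref_grp) || all(is_ref_grp)) {
      stop("both groups must be present after dropping incomplete samples")
    }
    ddct_val <- mean(dct[!is_ref_grp]) - mean(dct[is_ref_grp])
    data.frame(target = tg, ddct = ddct_val, fold = 2^(-ddct_val),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
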