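# Expression quantification and DEG set logic: TPM, the symmetric signed
# fold-change convention, Welch t + Benjamini-Hochberg calling, annotation
# filtering, and the two-context Venn partition.

#' Simulate a two-group RNA-seq count matrix with planted fold changes
#'
#' Negative-binomial counts (mean `baseline_mean`, dispersion `dispersion`,
#' variance \eqn{\mu + \phi \mu^2}) for two groups of samples. Planted
#' genes have their group-B mean scaled according to the signed fold-change
#' convention (`fc >= 1` multiplies by `fc`; `fc <= -1` divides by `|fc|`).
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group.
#' @param baseline_mean expected count of an unperturbed gene.
#' @param dispersion NB dispersion (> 0).
#' @param planted data frame with columns `gene` (index in `1:n_genes`) and
#'   `fc` (signed fold change, `|fc| >= 1`); may be empty.
#' @param gene_lengths transcript lengths, bp (scalar or length `n_genes`).
#' @param seed integer seed.
#' @return list of class `expression_sim`: `counts` (genes x samples),
#'   `gene_lengths`, `groups` (sample to group map), `truth` (data frame
#'   `gene_id`, `signed_fc`, `direction`).
#' @export
simulate_counts <- function(n_genes = 2000L, n_per_group = 3L,
                            baseline_mean = 100, dispersion = 0.1,
                            planted = NULL, gene_lengths = 1000,
                            seed = NULL) {
  n_genes <- check_count(n_genes, "n_genes")
  n_per_group <- check_count(n_per_group, "n_per_group")
  baseline_mean <- check_positive(baseline_mean, "baseline_mean")
  dispersion <- check_positive(dispersion, "dispersion")
  if (length(gene_lengths) == 1L) gene_lengths <- rep(gene_lengths, n_genes)
  if (length(gene_lengths) != n_genes || any(gene_lengths <= 0))
    stop_param("'gene_lengths' must be positive, one per gene")
  if (is.null(planted))
    planted <- data.frame(gene = integer(0), fc = numeric(0))
  if (!all(c("gene", "fc") %in% names(planted)))
    stop_param("'planted' needs columns gene and fc")
  if (anyDuplicated(planted$gene))
    stop_param("each gene may be planted at most once")
  if (any(planted$gene < 1L | planted$gene > n_genes))
    stop_param("planted gene index out of range")
  if (any(abs(planted$fc) < 1))
    stop_param("planted signed fold changes must satisfy |fc| >= 1")

  with_seed(seed, {
    gene_id <- sprintf("gene%04d", seq_len(n_genes))
    mu_b <- rep(baseline_mean, n_genes)
    mult <- ifelse(planted$fc >= 1, planted$fc, 1 / abs(planted$fc))
    mu_b[planted$gene] <- baseline_mean * mult
    size <- 1 / dispersion
    counts_a <- matrix(stats::rnbinom(n_genes * n_per_group,
                                      mu = baseline_mean, size = size),
                       n_genes, n_per_group)
    counts_b <- matrix(stats::rnbinom(n_genes * n_per_group,
                                      mu = mu_b, size = size),
                       n_genes, n_per_group)
    counts <- cbind(counts_a, counts_b)
    rownames(counts) <- gene_id
    colnames(counts) <- c(paste0("A", seq_len(n_per_group)),
                          paste0("B", seq_len(n_per_group)))
    groups <- stats::setNames(rep(c("A", "B"), each = n_per_group),
                              colnames(counts))
    truth <- data.frame(gene_id = gene_id[planted$gene],
                        signed_fc = planted$fc,
                        direction = ifelse(planted$fc >= 1, "up", "down"))
    structure(list(counts = counts, gene_lengths = gene_lengths,
                   groups = groups, truth = truth),
              class = "expression_sim")
  })
}

#' Transcripts per million
#'
#' Length-normalised expression: per sample, `rate = count / length_kb`,
#' then `TPM = rate / sum(rate) * 1e6`, so every sample column sums to one
#' million.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @param gene_lengths transcript lengths, bp, one per gene.
#' @return genes x samples TPM matrix.
#' @examples
#' tpm(matrix(c(10, 30), 2, 1), c(1000, 3000))  # both rows 5e5
#' @export
tpm <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_param("counts must be >= 0")
  if (length(gene_lengths) != nrow(counts) || any(gene_lengths <= 0))
    stop_param("'gene_lengths' must be positive, one per gene")
  rate <- counts / (gene_lengths / 1000)
  denom <- colSums(rate)
  if (any(denom == 0)) stop_param("sample with all-zero counts")
  sweep(rate, 2L, denom, `/`) * 1e6
}

#' Symmetric signed fold change
#'
#' Expression ratio `r = (mean_b + c) / (mean_a + c)` reported on the
#' symmetric scale used for DEG screening: `r` when `r >= 1`, `-1/r`
#' otherwise, so a doubling is +2 and a halving is -2 and
#' `signed_fold_change(x, y) == -signed_fold_change(y, x)`. The pseudocount
#' `c` is applied only when either mean is zero, keeping the statistic
#' finite without perturbing well-measured genes; two zero means give 1
#' (uninformative).
#'
#' @param mean_a,mean_b group means (>= 0); vectorised.
#' @param pseudocount `c`, raw-count units, used when either mean is 0.
#' @return signed fold change(s), `|fc| >= 1`.
#' @export
signed_fold_change <- function(mean_a, mean_b, pseudocount = 0.5) {
  if (any(mean_a < 0) || any(mean_b < 0)) stop_param("means must be >= 0")
  zero <- mean_a == 0 | mean_b == 0
  c0 <- ifelse(zero, pseudocount, 0)
  r <- (mean_b + c0) / (mean_a + c0)
  out <- ifelse(r >= 1, r, -1 / r)
  out[mean_a == 0 & mean_b == 0] <- 1
  out
}

#' Call differentially expressed genes
#'
#' Per-gene two-sided Welch t-test on `log2(TPM + 1)` between two sample
#' groups, Benjamini-Hochberg FDR across all tested genes, and the signed
#' fold change of the group mean TPM. A gene is a DEG when
#' `|signed FC| >= fc_threshold` and `q <= q_threshold` (defaults: fold
#' change at least 2-fold in either direction, FDR at most 0.05). Genes
#' with zero variance in both groups and equal means are untestable and
#' flagged. With a single sample per group (`single_sample = TRUE`) only
#' fold changes are emitted, with NA p/q and no DEG flags.
#'
#' @param counts genes x samples count matrix (rownames = gene ids).
#' @param gene_lengths transcript lengths, bp.
#' @param groups named vector mapping sample (column) names to group labels.
#' @param group_a,group_b the two group labels to compare (B over A).
#' @param fc_threshold,q_threshold DEG thresholds.
#' @param pseudocount passed to [signed_fold_change()].
#' @param single_sample allow 1-sample groups (fold change only).
#' @return a `deg_table` data frame: `gene_id`, `mean_tpm_a`, `mean_tpm_b`,
#'   `signed_fc`, `p_value`, `q_value`, `direction`, `is_deg`.
#' @export
call_degs <- function(counts, gene_lengths, groups,
                      group_a = "A", group_b = "B",
                      fc_threshold = 2, q_threshold = 0.05,
                      pseudocount = 0.5, single_sample = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%04d", seq_len(nrow(counts)))
  if (is.null(names(groups)) || !all(colnames(counts) %in% names(groups)))
    stop_param("'groups' must name every sample column")
  sel_a <- colnames(counts)[groups[colnames(counts)] == group_a]
  sel_b <- colnames(counts)[groups[colnames(counts)] == group_b]
  if (length(sel_a) == 0L || length(sel_b) == 0L)
    stop_param("both groups must be present")
  if (!single_sample && (length(sel_a) < 2L || length(sel_b) < 2L))
    stop_param("need >= 2 samples per group (or set single_sample = TRUE)")
  if (fc_threshold < 1) stop_param("'fc_threshold' must be >= 1")

  x <- tpm(counts, gene_lengths)
  ma <- rowMeans(x[, sel_a, drop = FALSE])
  mb <- rowMeans(x[, sel_b, drop = FALSE])
  fc <- signed_fold_change(ma, mb, pseudocount = pseudocount)

  if (length(sel_a) >= 2L && length(sel_b) >= 2L) {
    la <- log2(x[, sel_a, drop = FALSE] + 1)
    lb <- log2(x[, sel_b, drop = FALSE] + 1)
    va <- apply(la, 1L, stats::var)
    vb <- apply(lb, 1L, stats::var)
    wt <- welch_t_rows(rowMeans(la), va, length(sel_a),
                       rowMeans(lb), vb, length(sel_b))
    p <- wt$p
    degenerate <- va == 0 & vb == 0
    p[degenerate & rowMeans(la) == rowMeans(lb)] <- 1
    p[degenerate & rowMeans(la) != rowMeans(lb)] <- NA_real_
    q <- rep(NA_real_, length(p))
    q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  } else {
    p <- q <- rep(NA_real_, nrow(counts))
  }

  out <- data.frame(gene_id = rownames(counts),
                    mean_tpm_a = ma, mean_tpm_b = mb,
                    signed_fc = fc, p_value = p, q_value = q,
                    direction = ifelse(fc >= 1, "up", "down"),
                    is_deg = !is.na(q) & abs(fc) >= fc_threshold &
                      q <= q_threshold,
                    row.names = NULL)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' @export
print.deg_table <- function(x, ...) {
  cat(sprintf("DEG table: %d genes, %d DEGs (%d up, %d down)\n",
              nrow(x), sum(x$is_deg),
              sum(x$is_deg & x$direction == "up"),
              sum(x$is_deg & x$direction == "down")))
  NextMethod()
}

#' Drop genes without functional annotation
#'
#' @param genes character vector of gene ids.
#' @param annotation either a character vector of annotated gene ids, or a
#'   data frame with columns `gene_id` and logical `annotated`.
#' @return the annotated subset, with attribute `n_removed`; warns when the
#'   annotation is empty.
#' @export
filter_unannotated <- function(genes, annotation) {
  if (is.data.frame(annotation)) {
    if (!all(c("gene_id", "annotated") %in% names(annotation)))
      stop_param("annotation data frame needs columns gene_id, annotated")
    annotation <- annotation$gene_id[as.logical(annotation$annotated)]
  }
  if (length(annotation) == 0L && length(genes) > 0L)
    warning("empty annotation: all genes removed", call. = FALSE)
  kept <- genes[genes %in% annotation]
  attr(kept, "n_removed") <- length(genes) - length(kept)
  kept
}

#' Venn partition of two gene sets
#'
#' Splits two DEG sets into exclusive and common parts; the three parts are
#' pairwise disjoint and their union is the union of the inputs.
#'
#' @param set_a,set_b character vectors of gene ids (e.g. the DEGs of two
#'   variant contexts).
#' @return a `venn_partition` list: `exclusive_a`, `exclusive_b`, `common`,
#'   `counts` (named integer vector).
#' @examples
#' venn_partition(c("a", "b", "c", "d"), c("c", "d", "e"))$counts  # 2 1 2
#' @export
venn_partition <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  out <- list(exclusive_a = setdiff(set_a, set_b),
              exclusive_b = setdiff(set_b, set_a),
              common = intersect(set_a, set_b))
  out$counts <- c(exclusive_a = length(out$exclusive_a),
                  exclusive_b = length(out$exclusive_b),
                  common = length(out$common))
  class(out) <- "venn_partition"
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("Venn partition: %d exclusive to A, %d exclusive to B, %d common\n",
              x$counts["exclusive_a"], x$counts["exclusive_b"],
              x$counts["common"]))
  invisible(x)
}
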