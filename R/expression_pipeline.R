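#' Intensity-based probe filtering
#'
#' Keeps probes whose proportion of above-background samples, pooled over all
#' donors, is at least `min_prop` (inclusive at the boundary).
#'
#' @param bundle an `expression_bundle` (or any list with `probes`,
#'   `intensity` and `flags` of matching shape).
#' @param min_prop minimum above-background proportion (default 0.5).
#' @return the bundle with sub-threshold probes removed; retained probe ids
#'   in attribute `"retained"`.
#' @export
filter_probes_intensity <- function(bundle, min_prop = 0.5) {
  prop <- rowMeans(bundle$flags)
  keep <- prop >= min_prop
  bundle$probes <- bundle$probes[keep, , drop = FALSE]
  bundle$intensity <- bundle$intensity[keep, , drop = FALSE]
  bundle$flags <- bundle$flags[keep, , drop = FALSE]
  attr(bundle, "retained") <- rownames(bundle$intensity)
  bundle
}

#' RNA-seq-guided representative probe selection
#'
#' The RNA-seq reference is resolved at donor-structure level. For every gene
#' present on both platforms, each of its probes is aggregated to
#' donor-structure mean intensities over the samples whose donor and
#' structure match a reference unit; the matched (probe mean, reference)
#' pairs are pooled across donors and structures into one Pearson
#' correlation. Probes with `r < min_r` are discarded (undefined correlations
#' count as below threshold) and the highest-correlating probe represents
#' the gene; genes without a qualifying probe are dropped.
#'
#' @param bundle an `expression_bundle` (after [filter_probes_intensity()]).
#' @param min_r minimum probe-to-RNA-seq correlation (default 0.2).
#' @return data frame (gene, probe_id, r) of selected probes.
#' @export
select_probes_by_rnaseq <- function(bundle, min_r = 0.2) {
  genes_both <- intersect(unique(bundle$probes$gene), rownames(bundle$rnaseq))
  unit_key <- colnames(bundle$rnaseq)
  sample_key <- paste(bundle$samples$donor, bundle$samples$structure,
                      sep = ":")
  usable <- sample_key %in% unit_key
  if (!any(usable)) stop("no samples match the RNA-seq reference units")
  key <- sample_key[usable]
  # probe x unit mean intensities over matched samples
  sums <- t(rowsum(t(bundle$intensity[, usable, drop = FALSE]), key))
  counts <- as.numeric(table(key)[colnames(sums)])
  agg <- sums / rep(counts, each = nrow(sums))
  unit_cols <- match(colnames(sums), unit_key)
  rows_of_gene <- split(seq_len(nrow(bundle$probes)), bundle$probes$gene)
  sel_gene <- character(); sel_probe <- character(); sel_r <- numeric()
  for (g in genes_both) {
    ref <- bundle$rnaseq[g, unit_cols]
    rows <- rows_of_gene[[g]]
    rs <- vapply(rows, function(i) {
      x <- agg[i, ]
      if (stats::sd(x) == 0 || stats::sd(ref) == 0) return(-Inf)
      stats::cor(x, ref)
    }, numeric(1))
    ok <- rs >= min_r
    if (!any(ok)) next
    best <- rows[ok][which.max(rs[ok])]
    sel_gene <- c(sel_gene, g)
    sel_probe <- c(sel_probe, bundle$probes$probe_id[best])
    sel_r <- c(sel_r, max(rs[ok]))
  }
  data.frame(gene = sel_gene, probe_id = sel_probe, r = sel_r,
             stringsAsFactors = FALSE)
}

#' Restrict samples to the left cerebral cortex inside a gray-matter mask
#'
#' Keeps samples labelled left-hemisphere AND cortical whose nearest voxel in
#' the mask volume is in-mask. Samples whose coordinate falls outside the
#' mask bounding box are dropped (counted in attribute `"n_outside"`).
#'
#' @param samples sample annotation data frame (columns `sample_id`,
#'   `hemisphere`, `cortical`, `mni_x`, `mni_y`, `mni_z`).
#' @param mask logical/0-1 3D gray-matter array.
#' @param affine 4x4 voxel-to-mm transform of the mask grid.
#' @return character vector of retained sample ids.
#' @export
restrict_samples <- function(samples, mask, affine) {
  dims <- dim(mask)
  ijk <- round(mm_to_voxel(affine, as.matrix(samples[, c("mni_x", "mni_y",
                                                         "mni_z")])))
  inside <- ijk[, 1] >= 1 & ijk[, 1] <= dims[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= dims[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= dims[3]
  in_mask <- rep(FALSE, nrow(samples))
  lin <- ijk[inside, 1] + dims[1] * (ijk[inside, 2] - 1) +
    dims[1] * dims[2] * (ijk[inside, 3] - 1)
  in_mask[inside] <- as.logical(mask)[lin]
  keep <- samples$hemisphere == "left" & samples$cortical & in_mask
  out <- samples$sample_id[keep]
  attr(out, "n_outside") <- sum(!inside)
  out
}

srs_vector <- function(x) {
  # single-sort median and type-7 IQR (hot path: called per gene per donor)
  xs <- sort.int(x, method = "quick")
  n <- length(xs)
  q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
  }
  med <- q(0.5)
  iqr <- q(0.75) - q(0.25)
  if (iqr == 0) return(structure(rep(0.5, length(x)), degenerate = TRUE))
  s <- 1 / (1 + exp(-(x - med) / (iqr / 1.35)))
  rng <- range(s)
  if (rng[1] == rng[2]) return(structure(rep(0.5, length(x)),
                                         degenerate = TRUE))
  (s - rng[1]) / (rng[2] - rng[1])
}

#' Scaled robust sigmoid (SRS) normalization
#'
#' Each vector `x` along the chosen margin is mapped through the outlier
#' robust sigmoid `1 / (1 + exp(-(x - median(x)) / (IQR(x) / 1.35)))` (1.35
#' is the normal-consistency constant relating IQR to SD) and then min-max
#' rescaled to `[0, 1]`. The map is strictly monotone, so within-vector rank
#' order is preserved. Vectors with zero IQR become constant 0.5 and are
#' counted in attribute `"n_degenerate"`.
#'
#' @param mat numeric matrix.
#' @param margin 1 to normalize each row, 2 each column.
#' @return normalized matrix of the same shape.
#' @export
srs_normalize <- function(mat, margin = 1) {
  stopifnot(margin %in% c(1, 2))
  n_degen <- 0L
  f <- function(x) {
    y <- srs_vector(x)
    if (isTRUE(attr(y, "degenerate"))) n_degen <<- n_degen + 1L
    as.numeric(y)
  }
  out <- if (margin == 1) t(apply(mat, 1, f)) else apply(mat, 2, f)
  dimnames(out) <- dimnames(mat)
  attr(out, "n_degenerate") <- n_degen
  out
}

#' Differential stability (DS) of genes across donors
#'
#' For each gene: average its expression within each structure per donor,
#' then take the mean over donor pairs of the Spearman correlation between
#' the two donors' structure-mean vectors over structures they share. Donor
#' pairs sharing fewer than 3 structures are skipped. High DS marks genes
#' with spatially conserved expression, a prerequisite for transcriptome
#' neuroimaging correlation.
#'
#' @param donor_matrices named list (one per donor) of samples x genes
#'   matrices, all with the same gene columns.
#' @param structure_labels named list of per-sample structure label vectors,
#'   aligned with each donor matrix's rows.
#' @return named numeric vector of per-gene DS values.
#' @export
differential_stability <- function(donor_matrices, structure_labels) {
  if (length(donor_matrices) < 2L) stop("need at least 2 donors")
  stopifnot(identical(names(donor_matrices), names(structure_labels)))
  struct_means <- lapply(names(donor_matrices), function(d) {
    m <- donor_matrices[[d]]
    lab <- structure_labels[[d]]
    sm <- rowsum(m, lab) / as.vector(table(lab)[sort(unique(lab))])
    sm
  })
  names(struct_means) <- names(donor_matrices)
  genes <- colnames(donor_matrices[[1]])
  pairs <- utils::combn(names(donor_matrices), 2, simplify = FALSE)
  acc <- matrix(0, nrow = length(genes), ncol = 0)
  # column ranks (average ties) for a small number of rows, vectorized
  # across thousands of gene columns by pairwise comparison counting
  col_ranks <- function(m) {
    r <- matrix(0, nrow(m), ncol(m))
    for (j in seq_len(nrow(m)))
      r[j, ] <- 1 + colSums(m < rep(m[j, ], each = nrow(m))) +
        (colSums(m == rep(m[j, ], each = nrow(m))) - 1) / 2
    r
  }
  for (pr in pairs) {
    a <- struct_means[[pr[1]]]; b <- struct_means[[pr[2]]]
    shared <- intersect(rownames(a), rownames(b))
    if (length(shared) < 3L) next
    ra <- col_ranks(a[shared, genes, drop = FALSE])
    rb <- col_ranks(b[shared, genes, drop = FALSE])
    ra <- scale(ra); rb <- scale(rb)
    rho <- colSums(ra * rb) / (length(shared) - 1)
    rho[!is.finite(rho)] <- 0  # constant structure profile: no evidence
    acc <- cbind(acc, rho)
  }
  if (ncol(acc) == 0L)
    stop("no donor pair shares at least 3 structures")
  ds <- rowMeans(acc)
  names(ds) <- genes
  ds
}

#' Keep the genes with the highest differential stability
#'
#' Retains genes whose DS is at least the value of the k-th largest DS,
#' `k = ceiling(fraction * n)`; ties at the cut are all retained.
#'
#' @param ds named numeric vector of DS values.
#' @param fraction fraction of genes to keep (default 0.5).
#' @return character vector of retained gene names.
#' @export
select_top_ds <- function(ds, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  k <- ceiling(fraction * length(ds))
  thr <- sort(ds, decreasing = TRUE)[k]
  names(ds)[ds >= thr]
}

#' Full expression-processing pipeline
#'
#' Bundle to normalized sample x gene matrix, in fixed order: intensity-based
#' probe filtering, RNA-seq-guided probe selection, left-cortex gray-matter
#' sample restriction, per-donor SRS normalization (within-sample cross-gene,
#' then within-gene cross-sample), differential-stability computation and
#' top-DS gene selection.
#'
#' @param bundle an `expression_bundle`.
#' @param gm_mask gray-matter 3D mask for sample restriction.
#' @param affine 4x4 voxel-to-mm transform of the mask grid.
#' @param min_prop intensity-filter proportion (default 0.5).
#' @param min_r probe-selection correlation threshold (default 0.2).
#' @param ds_fraction DS retention fraction (default 0.5).
#' @return an object of class `gene_expression_matrix`: `values` (samples x
#'   genes in `[0, 1]`, no missing entries), `samples` (annotations of
#'   retained samples), `ds` (per-gene DS of retained genes), `probe_map`
#'   (gene to selected probe).
#' @export
process_expression_bundle <- function(bundle, gm_mask, affine,
                                      min_prop = 0.5, min_r = 0.2,
                                      ds_fraction = 0.5) {
  stopifnot(inherits(bundle, "expression_bundle") ||
              is.list(bundle))
  filtered <- filter_probes_intensity(bundle, min_prop)
  probe_map <- select_probes_by_rnaseq(filtered, min_r)
  keep_samples <- restrict_samples(bundle$samples, gm_mask, affine)
  ann <- bundle$samples[match(keep_samples, bundle$samples$sample_id), ]
  expr <- t(filtered$intensity[probe_map$probe_id, keep_samples,
                               drop = FALSE])        # samples x genes
  colnames(expr) <- probe_map$gene

  donors <- unique(ann$donor)
  norm <- expr
  for (d in donors) {
    rows <- ann$donor == d
    block <- expr[rows, , drop = FALSE]
    block <- srs_normalize(block, margin = 1)   # within-sample across genes
    block <- srs_normalize(block, margin = 2)   # within-gene across samples
    norm[rows, ] <- block
  }

  ds <- differential_stability(
    donor_matrices = stats::setNames(
      lapply(donors, function(d) norm[ann$donor == d, , drop = FALSE]),
      donors),
    structure_labels = stats::setNames(
      lapply(donors, function(d) ann$structure[ann$donor == d]), donors))
  keep_genes <- select_top_ds(ds, ds_fraction)
  structure(list(values = norm[, keep_genes, drop = FALSE],
                 samples = ann, ds = ds[keep_genes],
                 probe_map = probe_map[probe_map$gene %in% keep_genes, ]),
            class = "gene_expression_matrix")
}

#' @export
print.gene_expression_matrix <- function(x, ...) {
  cat(sprintf("<gene_expression_matrix> %d samples x %d genes (normalized to [0, 1])\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
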