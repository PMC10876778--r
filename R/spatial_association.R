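#' Sample a statistic map in spheres at tissue-sample coordinates
#'
#' For each MNI coordinate, averages the map over in-mask voxels whose centre
#' lies within `radius_mm` (Euclidean distance in mm). Coordinates with no
#' in-mask voxel in the sphere yield `NA` and should be excluded downstream.
#' The map should be the uncorrected (pre-cluster-threshold) t-map.
#'
#' @param tmap an [activity_map()] (e.g. t-statistics).
#' @param coords n x 3 matrix of MNI mm coordinates.
#' @param radius_mm sphere radius in mm (default 3; must be positive).
#' @param mask logical/0-1 3D array (defaults to the map's mask, else all
#'   voxels).
#' @return numeric vector of per-sample mean values (NA where empty).
#' @export
sample_tmap_spheres <- function(tmap, coords, radius_mm = 3, mask = NULL) {
  stopifnot(inherits(tmap, "activity_map"))
  if (radius_mm <= 0) stop("`radius_mm` must be positive")
  coords <- matrix(as.numeric(coords), ncol = 3L)
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  dims <- dim(tmap$data)
  if (is.null(mask)) mask <- tmap$mask
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  mask <- array(as.logical(mask), dim = dims)
  idx <- which(mask)
  xyz <- grid_coordinates_mm(dims, tmap$affine)[idx, , drop = FALSE]
  vals <- tmap$data[idx]
  r2 <- radius_mm^2
  vapply(seq_len(nrow(coords)), function(i) {
    d2 <- (xyz[, 1] - coords[i, 1])^2 + (xyz[, 2] - coords[i, 2])^2 +
      (xyz[, 3] - coords[i, 3])^2
    hit <- d2 <= r2
    if (!any(hit)) return(NA_real_)
    mean(vals[hit])
  }, numeric(1))
}

#' Gene-wise correlation between expression and sampled map values
#'
#' Pearson correlation of every gene's cross-sample expression with the
#' per-sample map values, with two-sided p-values from the t distribution on
#' n - 2 degrees of freedom. Samples with missing map values are dropped
#' (pairwise n reported). Zero-variance genes get `r = NA`, `p = 1` and a
#' degenerate flag.
#'
#' @param mat a `gene_expression_matrix` (or plain samples x genes matrix).
#' @param t_values per-sample map values aligned with the matrix rows.
#' @return data frame (gene, r, p, n, degenerate), one row per gene.
#' @export
genewise_correlation <- function(mat, t_values) {
  values <- if (inherits(mat, "gene_expression_matrix")) mat$values else mat
  if (length(t_values) != nrow(values))
    stop("`t_values` must align with the matrix rows")
  use <- is.finite(t_values)
  values <- values[use, , drop = FALSE]
  tv <- t_values[use]
  n <- length(tv)
  if (n < 3L) stop("need at least 3 samples with map values")
  tz <- (tv - mean(tv))
  sdt <- sqrt(sum(tz^2))
  gz <- sweep(values, 2, colMeans(values))
  sdg <- sqrt(colSums(gz^2))
  r <- as.numeric(crossprod(gz, tz)) / (sdg * sdt)
  degenerate <- sdg == 0 | sdt == 0
  r[degenerate] <- NA_real_
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[degenerate] <- 1
  p[!degenerate & abs(r) >= 1] <- 0
  data.frame(gene = colnames(values), r = r, p = p, n = n,
             degenerate = degenerate, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (n_tests < 1) stop("`n_tests` must be at least 1")
  alpha / n_tests
}

#' Intersect significant genes with a risk-gene list
#'
#' Final target genes are those passing the Bonferroni-corrected correlation
#' threshold AND appearing on the risk list (symbols compared after
#' upper-case normalization). The sign of r is carried along: a negative
#' correlation means lower expression where the case-control difference is
#' larger.
#'
#' @param result data frame from [genewise_correlation()] with a
#'   `significant` column (see [run_spatial_association()]), or one to which
#'   `alpha` is applied here.
#' @param risk_genes character vector of risk-gene symbols (nonempty).
#' @param alpha family-wise alpha used if `result` lacks a `significant`
#'   column (Bonferroni over the result's genes).
#' @return the rows of `result` forming the final gene set, with a
#'   `direction` column; zero rows (with a warning) when the risk list does
#'   not meet the result's genes.
#' @export
intersect_risk_genes <- function(result, risk_genes, alpha = 0.05) {
  if (!length(risk_genes)) stop("empty risk-gene list")
  risk <- unique(toupper(trimws(risk_genes)))
  if (is.null(result$significant)) {
    thr <- bonferroni_threshold(alpha, nrow(result))
    result$significant <- result$p < thr
  }
  result$risk_gene <- toupper(result$gene) %in% risk
  if (!any(result$risk_gene))
    warning("risk-gene list is disjoint from the expression genes")
  final <- result[result$significant & result$risk_gene, , drop = FALSE]
  final$direction <- ifelse(final$r > 0, "positive", "negative")
  final
}

#' Transcriptome-neuroimaging association stage
#'
#' Samples the uncorrected t-map in spheres at the expression matrix's sample
#' coordinates, correlates every gene with the sampled values, applies the
#' Bonferroni threshold `alpha / n_genes`, and intersects the significant
#' genes with the risk list.
#'
#' @param mat a `gene_expression_matrix` (with sample annotations).
#' @param tmap uncorrected t [activity_map()].
#' @param risk_genes character vector of risk-gene symbols.
#' @param alpha family-wise alpha (default 0.05).
#' @param radius_mm sampling sphere radius (default 3).
#' @param mask optional mask for sphere sampling.
#' @return list: `result` (per-gene data frame with `significant` and
#'   `risk_gene` flags), `final` (final gene set rows), `threshold`, and the
#'   per-sample `t_values`.
#' @export
run_spatial_association <- function(mat, tmap, risk_genes, alpha = 0.05,
                                    radius_mm = 3, mask = NULL) {
  stopifnot(inherits(mat, "gene_expression_matrix"))
  coords <- as.matrix(mat$samples[, c("mni_x", "mni_y", "mni_z")])
  tv <- sample_tmap_spheres(tmap, coords, radius_mm = radius_mm, mask = mask)
  result <- genewise_correlation(mat, tv)
  thr <- bonferroni_threshold(alpha, nrow(result))
  result$significant <- result$p < thr
  final <- intersect_risk_genes(result, risk_genes)
  list(result = result, final = final, threshold = thr, t_values = tv)
}

#' Read a risk-gene list (one symbol per line)
#'
#' @param path text file path; blank lines and `#` comments are ignored.
#' @return character vector of unique symbols.
#' @export
read_risk_genes <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("risk-gene file contains no symbols")
  unique(lines)
}
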