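#' Specification of a synthetic two-group resting-state cohort
#'
#' Defines the study conditions for a simulated case-control resting-state
#' experiment: two groups of 4D BOLD-like volumes in which group B carries a
#' planted increase of local temporal coherence (hence ReHo) inside a sphere.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param grid_shape length-3 voxel grid dimensions.
#' @param n_volumes time points per subject (pre-discard).
#' @param tr_seconds repetition time in seconds.
#' @param voxel_mm isotropic voxel size in mm.
#' @param planted_center_mm MNI centre of the planted coherence sphere.
#' @param planted_radius_mm radius of the planted sphere in mm.
#' @param planted_effect_d target Cohen's d of the group difference in mean
#'   in-sphere ReHo (computed on bandpassed data; see [reho_effect_weight()]).
#' @param seed integer seed; identical specs with identical seeds generate
#'   bit-identical cohorts.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 15, grid_shape = c(16, 16, 16),
                        n_volumes = 240, tr_seconds = 2, voxel_mm = 3,
                        planted_center_mm = c(-9, 0, 0),
                        planted_radius_mm = 7.5, planted_effect_d = 0,
                        seed = 1) {
  if (n_per_group < 2) stop("`n_per_group` must be at least 2")
  if (planted_radius_mm <= 0) stop("`planted_radius_mm` must be positive")
  if (tr_seconds <= 0) stop("`tr_seconds` must be positive")
  if (n_volumes < 2) stop("`n_volumes` must be at least 2")
  structure(list(n_per_group = as.integer(n_per_group),
                 grid_shape = as.integer(grid_shape),
                 n_volumes = as.integer(n_volumes),
                 tr_seconds = tr_seconds, voxel_mm = voxel_mm,
                 planted_center_mm = planted_center_mm,
                 planted_radius_mm = planted_radius_mm,
                 planted_effect_d = planted_effect_d,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

ball_mask <- function(dims, affine, center_mm, radius_mm) {
  xyz <- grid_coordinates_mm(dims, affine)
  d2 <- (xyz[, 1] - center_mm[1])^2 + (xyz[, 2] - center_mm[2])^2 +
    (xyz[, 3] - center_mm[3])^2
  array(d2 <= radius_mm^2, dim = dims)
}

# mapping from target in-sphere ReHo effect size d to the latent-signal
# mixing weight, calibrated by a pilot simulation under the default cohort
# conditions (15+15 subjects, 16^3 grid of 3 mm voxels, 240 volumes at
# TR = 2 s, 7.5 mm sphere, metric pipeline bandpass -> ReHo); monotone
# interpolation between pilot points; requests beyond the calibrated range
# are clamped to the largest pilot weight (the achievable d saturates as
# the shared latent component starts to dominate between-subject variance)
.reho_weight_pilot <- data.frame(
  weight = c(0, 0.05, 0.06, 0.077, 0.09, 0.10, 0.15, 0.20, 0.25, 0.30),
  d      = c(0, 0.607, 0.904, 1.168, 1.684, 1.707, 2.599, 4.351, 5.770,
             7.919)
)

#' Latent-signal mixing weight for a target in-sphere ReHo effect size
#'
#' The planted coherence mechanism adds a shared latent time series to every
#' in-sphere voxel of group-B subjects with this mixing weight. The weight to
#' effect-size mapping is not analytically tractable, so it was calibrated by
#' a pilot simulation at the default cohort conditions and is interpolated
#' monotonically here. Effect sizes are approximate away from the defaults.
#'
#' @param d target Cohen's d (>= 0) of the group difference in mean
#'   in-sphere ReHo.
#' @return mixing weight (0 for d = 0).
#' @export
reho_effect_weight <- function(d) {
  if (d < 0) stop("`d` must be nonnegative")
  if (d == 0) return(0)
  tab <- .reho_weight_pilot
  stats::approx(tab$d, tab$weight, xout = d, rule = 2)$y
}

ar1_series <- function(n_series, n_time, phi) {
  x <- matrix(stats::rnorm(n_series * n_time), nrow = n_time)
  for (t in 2:n_time)
    x[t, ] <- phi * x[t - 1, ] + x[t, ]
  x
}

#' Generate a synthetic two-group resting-state cohort
#'
#' Each subject's volume is temporally autocorrelated Gaussian noise (AR(1),
#' phi = 0.3, a simple model with a realistically reddened spectrum). Inside
#' the planted sphere, group-B subjects additionally share (within subject) a
#' latent AR(1) time series mixed into every in-sphere voxel with the weight
#' calibrated to produce the requested in-sphere ReHo effect size. Motion
#' traces are smooth random walks. Tissue masks (gray matter, white matter,
#' CSF) are concentric synthetic regions on the same grid.
#'
#' @param spec a [cohort_spec()].
#' @return list with `group_a`, `group_b` (each a list of subjects holding a
#'   `vol` [ts_volume()] and a `motion` matrix), masks `gm_mask`, `wm_mask`,
#'   `csf_mask`, the `affine`, the linear indices `planted_voxels` of the
#'   sphere, and the `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  dims <- spec$grid_shape
  affine <- centered_affine(dims, spec$voxel_mm)
  half_extent <- spec$voxel_mm * (dims - 1) / 2
  lo <- spec$planted_center_mm - spec$planted_radius_mm
  hi <- spec$planted_center_mm + spec$planted_radius_mm
  if (any(lo < -half_extent) || any(hi > half_extent)) {
    bad <- which(lo < -half_extent | hi > half_extent)[1]
    stop(sprintf(
      "planted sphere extends outside the grid along axis %d (centre %g mm, radius %g mm, grid half-extent %g mm)",
      bad, spec$planted_center_mm[bad], spec$planted_radius_mm,
      half_extent[bad]))
  }

  r_gm <- 0.9 * min(half_extent)
  gm <- ball_mask(dims, affine, c(0, 0, 0), r_gm)
  wm <- ball_mask(dims, affine, c(0.5 * r_gm, 0, 0), 0.22 * r_gm)
  csf <- ball_mask(dims, affine, c(0, 0.65 * r_gm, 0), 0.18 * r_gm)
  gm <- gm & !wm & !csf
  sphere <- ball_mask(dims, affine, spec$planted_center_mm,
                      spec$planted_radius_mm)
  planted <- which(sphere)

  set.seed(spec$seed)
  phi <- 0.3
  weight <- reho_effect_weight(spec$planted_effect_d)
  nvox <- prod(dims)
  nt <- spec$n_volumes
  make_subject <- function(with_effect) {
    noise <- ar1_series(nvox, nt, phi)           # time x voxel
    if (with_effect && weight > 0) {
      latent <- ar1_series(1, nt, phi)[, 1]
      noise[, planted] <- noise[, planted] + weight * latent
    }
    data <- array(t(noise), dim = c(dims, nt))
    motion <- cbind(
      apply(matrix(stats::rnorm(3 * nt, sd = 0.02), ncol = 3), 2, cumsum),
      apply(matrix(stats::rnorm(3 * nt, sd = 4e-4), ncol = 3), 2, cumsum))
    colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    list(vol = ts_volume(100 + data, affine, spec$tr_seconds),
         motion = motion)
  }
  group_a <- lapply(seq_len(spec$n_per_group), function(i) make_subject(FALSE))
  group_b <- lapply(seq_len(spec$n_per_group), function(i) make_subject(TRUE))
  list(group_a = group_a, group_b = group_b,
       gm_mask = gm, wm_mask = wm, csf_mask = csf, affine = affine,
       planted_voxels = planted, spec = spec)
}

#' Specification of a synthetic donor expression bundle
#'
#' Emulates a multi-donor postmortem microarray resource: per-donor probe by
#' sample intensities, probe-to-gene annotations, above-background flags, an
#' RNA-seq reference for probe selection, and per-sample MNI coordinates with
#' hemisphere/structure labels. A subset of "tracking" genes has a spatial
#' expression profile that follows a supplied target map.
#'
#' @param n_donors number of donors (default 6).
#' @param n_samples_per_donor left-hemisphere cortical samples per donor
#'   (extra right-hemisphere and subcortical decoy samples are added on top).
#' @param n_genes number of genes.
#' @param n_probes total number of probes (>= `n_genes`; default 2 per gene).
#' @param n_tracking_genes number of genes tracking the target map.
#' @param tracking_r nominal correlation between a tracking gene's expression
#'   and the target map value at the sample locations (|r| <= 1).
#' @param n_structures number of cortical structure labels.
#' @param seed integer seed.
#' @return an object of class `expression_bundle_spec`.
#' @export
expression_bundle_spec <- function(n_donors = 6, n_samples_per_donor = 67,
                                   n_genes = 200, n_probes = 2 * n_genes,
                                   n_tracking_genes = 0, tracking_r = 0.6,
                                   n_structures = 10, seed = 1) {
  if (n_probes < n_genes) stop("`n_probes` must be at least `n_genes`")
  if (n_tracking_genes < 0 || n_tracking_genes > n_genes)
    stop("`n_tracking_genes` must lie in [0, n_genes]")
  if (abs(tracking_r) > 1) stop("|tracking_r| must not exceed 1")
  if (n_donors < 2) stop("need at least 2 donors")
  structure(list(n_donors = as.integer(n_donors),
                 n_samples_per_donor = as.integer(n_samples_per_donor),
                 n_genes = as.integer(n_genes),
                 n_probes = as.integer(n_probes),
                 n_tracking_genes = as.integer(n_tracking_genes),
                 tracking_r = tracking_r,
                 n_structures = as.integer(n_structures),
                 seed = as.integer(seed)),
            class = "expression_bundle_spec")
}

#' Generate a synthetic donor expression bundle
#'
#' Sample coordinates are drawn uniformly from in-mask voxel centres in the
#' left hemisphere (x < 0 mm); cortical structure labels are compact
#' k-means parcels of the left mask, shared across donors. Tracking genes' expression follows the
#' target map value sampled in a 3 mm sphere at each coordinate, mixed with
#' Gaussian noise to the nominal correlation. Probes per gene comprise one
#' designated best probe plus planted competitors: noisier decoys, probes
#' anti-correlated with the gene profile (to fall below the RNA-seq r
#' threshold), and dim probes that fail above-background intensity filtering.
#' Every 97th gene carries only a below-threshold probe, so probe selection
#' must drop it. Above-background flags threshold intensity at the 0.2
#' quantile per donor. The RNA-seq reference covers the first two donors at
#' structure-level resolution.
#'
#' @param spec an [expression_bundle_spec()].
#' @param target_map an [activity_map()] (e.g. an uncorrected t-map) whose
#'   grid covers the sample coordinates.
#' @param mask logical/0-1 3D array of candidate tissue voxels (defaults to
#'   the target map's mask).
#' @return an object of class `expression_bundle`: `probes` (probe_id, gene),
#'   `intensity` (probes x samples), `flags` (same shape), `rnaseq` (genes x
#'   donor-structure units), `samples` (annotation data frame), and `truth`
#'   (planted ground truth: tracking genes, best probes, dim/below-threshold
#'   probes, dropped genes, kept sample ids, target profile).
#' @export
generate_expression_bundle <- function(spec, target_map, mask = NULL) {
  stopifnot(inherits(spec, "expression_bundle_spec"),
            inherits(target_map, "activity_map"))
  if (is.null(mask)) mask <- target_map$mask
  if (is.null(mask)) stop("no mask available for sample placement")
  dims <- dim(target_map$data)
  mask <- array(as.logical(mask), dim = dims)
  xyz <- grid_coordinates_mm(dims, target_map$affine)
  left_idx <- which(mask & array(xyz[, 1] < 0, dim = dims))
  right_idx <- which(mask & array(xyz[, 1] > 0, dim = dims))
  if (!length(left_idx)) stop("mask has no left-hemisphere voxels")

  set.seed(spec$seed)
  nd <- spec$n_donors
  nsd <- spec$n_samples_per_donor
  ng <- spec$n_genes
  # structure labels: compact k-means parcels of the left mask, shared
  # across donors (compact parcels preserve the between-structure variance
  # of smooth maps, which slab-shaped structures would average away)
  km <- stats::kmeans(xyz[left_idx, , drop = FALSE],
                      centers = min(spec$n_structures, length(left_idx)),
                      nstart = 5, iter.max = 100)
  parcel_of <- function(vox) {
    d2 <- outer(rowSums(xyz[vox, , drop = FALSE]^2),
                rowSums(km$centers^2), "+") -
      2 * xyz[vox, , drop = FALSE] %*% t(km$centers)
    max.col(-d2)
  }

  n_right <- round(0.1 * nsd)
  n_sub <- round(0.1 * nsd)
  samples <- do.call(rbind, lapply(seq_len(nd), function(d) {
    vox <- sample(left_idx, nsd, replace = TRUE)
    left <- data.frame(donor = paste0("D", d), hemisphere = "left",
                       cortical = TRUE, voxel = vox)
    right <- if (d <= 2 && n_right > 0 && length(right_idx)) {
      data.frame(donor = paste0("D", d), hemisphere = "right",
                 cortical = TRUE, voxel = sample(right_idx, n_right,
                                                 replace = TRUE))
    }
    sub <- if (n_sub > 0) {
      data.frame(donor = paste0("D", d), hemisphere = "left",
                 cortical = FALSE, voxel = sample(left_idx, n_sub,
                                                  replace = TRUE))
    }
    rbind(left, right, sub)
  }))
  samples$sample_id <- sprintf("S%04d", seq_len(nrow(samples)))
  coords <- xyz[samples$voxel, , drop = FALSE]
  samples$mni_x <- coords[, 1]; samples$mni_y <- coords[, 2]
  samples$mni_z <- coords[, 3]
  samples$structure <- ifelse(samples$cortical,
                              sprintf("CTX_%02d", parcel_of(samples$voxel)),
                              "SUBCTX")
  ns <- nrow(samples)

  # sample-level target profile: 3 mm sphere mean of the map, standardized
  # over the left cortical samples that the pipeline will retain
  tvals <- sample_tmap_spheres(target_map, coords, radius_mm = 3, mask = mask)
  kept <- samples$hemisphere == "left" & samples$cortical
  s <- (tvals - mean(tvals[kept])) / stats::sd(tvals[kept])

  genes <- sprintf("G%05d", seq_len(ng))
  dropped <- genes[seq_len(ng) %% 97 == 0]
  eligible <- setdiff(genes, dropped)
  tracking <- if (spec$n_tracking_genes > 0)
    sort(sample(eligible, spec$n_tracking_genes)) else character()

  # bounded log-intensity baselines keep the planted intensity-filter
  # margins deterministic for every gene
  baseline <- stats::runif(ng, 6.5, 9.5)
  r <- spec$tracking_r
  signal <- matrix(stats::rnorm(ng * ns), nrow = ng)      # gene x sample
  is_track <- genes %in% tracking
  if (any(is_track))
    signal[is_track, ] <- r * matrix(s, nrow = sum(is_track), ncol = ns,
                                     byrow = TRUE) +
      sqrt(1 - r^2) * signal[is_track, , drop = FALSE]
  expr_truth <- baseline + signal                          # gene x sample

  # probe allocation: one best probe per gene, extras cycle decoy types
  n_extra <- spec$n_probes - ng
  extra_gene <- if (n_extra > 0) ((seq_len(n_extra) - 1) %% ng) + 1 else integer()
  probe_gene <- c(seq_len(ng), extra_gene)
  probe_type <- c(ifelse(genes %in% dropped, "below", "best")[seq_len(ng)],
                  c("decoy", "below", "dim")[((seq_len(n_extra) - 1) %% 3) + 1])
  # planted-dropped genes must carry only below-threshold probes
  probe_type[genes[probe_gene] %in% dropped] <- "below"
  probes <- data.frame(probe_id = sprintf("P%05d", seq_along(probe_gene)),
                       gene = genes[probe_gene], type = probe_type,
                       stringsAsFactors = FALSE)

  np <- nrow(probes)
  noise <- matrix(stats::rnorm(np * ns), nrow = np)
  intensity <- matrix(0, nrow = np, ncol = ns,
                      dimnames = list(probes$probe_id, samples$sample_id))
  for (i in seq_len(np)) {
    g <- probe_gene[i]
    intensity[i, ] <- switch(probes$type[i],
      best  = expr_truth[g, ] + 0.15 * noise[i, ],
      decoy = baseline[g] + 0.3 * signal[g, ] + 1.0 * noise[i, ],
      below = baseline[g] - 0.6 * signal[g, ] + 0.5 * noise[i, ],
      dim   = 3 + 0.15 * noise[i, ])
  }
  flags <- matrix(0L, nrow = np, ncol = ns, dimnames = dimnames(intensity))
  for (d in unique(samples$donor)) {
    cols <- samples$donor == d
    thr <- stats::quantile(intensity[, cols], 0.2)
    flags[, cols] <- (intensity[, cols] > thr) * 1L
  }

  # RNA-seq reference: structure-level means for the first two donors
  rna_donors <- unique(samples$donor)[1:min(2, nd)]
  units <- unique(samples[kept & samples$donor %in% rna_donors,
                          c("donor", "structure")])
  units <- units[order(units$donor, units$structure), ]
  rnaseq <- matrix(NA_real_, nrow = ng, ncol = nrow(units),
                   dimnames = list(genes,
                                   paste(units$donor, units$structure,
                                         sep = ":")))
  for (u in seq_len(nrow(units))) {
    cols <- kept & samples$donor == units$donor[u] &
      samples$structure == units$structure[u]
    rnaseq[, u] <- rowMeans(expr_truth[, cols, drop = FALSE]) +
      stats::rnorm(ng, sd = 0.05)
  }

  truth <- list(tracking_genes = tracking, dropped_genes = dropped,
                best_probes = probes$probe_id[probes$type == "best"],
                dim_probes = probes$probe_id[probes$type == "dim"],
                below_probes = probes$probe_id[probes$type == "below"],
                kept_samples = samples$sample_id[kept],
                target_profile = s)
  structure(list(probes = probes[, c("probe_id", "gene")],
                 intensity = intensity, flags = flags, rnaseq = rnaseq,
                 samples = samples[, c("sample_id", "donor", "mni_x", "mni_y",
                                       "mni_z", "hemisphere", "cortical",
                                       "structure")],
                 truth = truth, spec = spec),
            class = "expression_bundle")
}

#' Draw a synthetic risk-gene list
#'
#' Emulates the gene list from a genome-wide association study: a fixed
#' number of symbols, optionally forcing a subset of the bundle's tracking
#' genes onto the list (the genes the association stage should recover).
#'
#' @param bundle an `expression_bundle`.
#' @param n_risk list length (default 123).
#' @param n_tracking_on_list how many tracking genes to include.
#' @param seed integer seed.
#' @return character vector of unique gene symbols.
#' @export
generate_risk_gene_list <- function(bundle, n_risk = 123,
                                    n_tracking_on_list = 0, seed = 1) {
  stopifnot(inherits(bundle, "expression_bundle"))
  tracking <- bundle$truth$tracking_genes
  if (n_tracking_on_list > length(tracking))
    stop("not enough tracking genes in the bundle")
  set.seed(seed)
  on_list <- if (n_tracking_on_list > 0)
    sort(sample(tracking, n_tracking_on_list)) else character()
  pool <- setdiff(unique(bundle$probes$gene),
                  c(tracking, bundle$truth$dropped_genes))
  sort(c(on_list, sample(pool, n_risk - length(on_list))))
}

#' Generate a synthetic clinical score table
#'
#' Two groups with demographic columns and seven clinical scales (HAMA-like
#' anxiety, BDI-like depression, disease duration, VAS pain, HIT-6 impact,
#' MoCA cognition, BFI neuroticism). One designated score (HAMA) differs
#' between groups by `score_shift` pooled standard deviations; all other
#' scores are null. BMI carries a sprinkle of missing values so that
#' pairwise-deletion handling is exercised.
#'
#' @param n_a,n_b group sizes (>= 2): group A ("HC"), group B ("EM").
#' @param score_shift group-B shift of the designated score, in pooled SDs.
#' @param seed integer seed.
#' @return data frame with one row per subject.
#' @export
generate_clinical_table <- function(n_a = 30, n_b = 27, score_shift = 0,
                                    seed = 1) {
  if (n_a < 2 || n_b < 2) stop("need at least 2 subjects per group")
  set.seed(seed)
  n <- n_a + n_b
  group <- rep(c("HC", "EM"), c(n_a, n_b))
  tbl <- data.frame(
    subject = sprintf("sub%03d", seq_len(n)),
    group = group,
    age = round(stats::rnorm(n, 34, 8), 1),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.88, 0.12)),
    education = round(stats::rnorm(n, 14, 3), 1),
    bmi = round(stats::rnorm(n, 22, 3), 2),
    fd = round(stats::rlnorm(n, log(0.12), 0.4), 3),
    duration = round(stats::rlnorm(n, log(8), 0.6), 1),
    hit6 = round(stats::rnorm(n, 60, 6), 1),
    vas = round(stats::rnorm(n, 6, 1.8), 1),
    hama = round(stats::rnorm(n, 8, 4) +
                   ifelse(group == "EM", score_shift * 4, 0), 1),
    bdi = round(stats::rnorm(n, 6, 4), 1),
    moca = round(stats::rnorm(n, 26, 2), 1),
    bfi_neuroticism = round(stats::rnorm(n, 31, 7), 1),
    stringsAsFactors = FALSE)
  tbl$bmi[sample.int(n, max(1, round(0.15 * n)))] <- NA
  tbl
}

#' Write synthetic inputs to disk in standard formats
#'
#' `write_cohort()` writes each subject as NIfTI plus a 6-column motion TSV
#' and the tissue masks; `write_expression_bundle()` writes the bundle as TSV
#' files (`probes.tsv`, `expression.tsv`, `noise_flags.tsv`, `rnaseq.tsv`,
#' `samples.tsv`); `write_clinical_table()` writes a CSV.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return the output directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  masks <- list(gm = cohort$gm_mask, wm = cohort$wm_mask,
                csf = cohort$csf_mask)
  for (m in names(masks))
    write_volume(activity_map(masks[[m]] * 1, cohort$affine, metric = m),
                 file.path(dir, paste0(m, "_mask.nii.gz")))
  for (g in c("group_a", "group_b")) {
    for (i in seq_along(cohort[[g]])) {
      stem <- file.path(dir, sprintf("%s_sub%02d", g, i))
      write_volume(cohort[[g]][[i]]$vol, paste0(stem, "_bold.nii.gz"))
      utils::write.table(cohort[[g]][[i]]$motion,
                         paste0(stem, "_motion.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @param bundle an `expression_bundle`.
#' @export
write_expression_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          row.names = FALSE, quote = FALSE)
  wt(bundle$probes, "probes.tsv")
  wt(data.frame(probe_id = rownames(bundle$intensity), bundle$intensity,
                check.names = FALSE), "expression.tsv")
  wt(data.frame(probe_id = rownames(bundle$flags), bundle$flags,
                check.names = FALSE), "noise_flags.tsv")
  wt(data.frame(gene = rownames(bundle$rnaseq), bundle$rnaseq,
                check.names = FALSE), "rnaseq.tsv")
  wt(bundle$samples, "samples.tsv")
  invisible(dir)
}

#' @rdname write_cohort
#' @param clinical a clinical table from [generate_clinical_table()].
#' @param path output CSV path.
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE)
  invisible(path)
}
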