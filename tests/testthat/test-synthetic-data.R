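test_that("cohort generation is deterministic and validates its spec", {
  spec <- cohort_spec(n_per_group = 2, grid_shape = c(8, 8, 8),
                      n_volumes = 20, planted_center_mm = c(0, 0, 0),
                      planted_radius_mm = 6, planted_effect_d = 0.8,
                      seed = 7)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1$group_b[[2]]$vol$data, co2$group_b[[2]]$vol$data)
  expect_identical(co1$group_a[[1]]$motion, co2$group_a[[1]]$motion)

  other <- generate_cohort(cohort_spec(n_per_group = 2,
                                       grid_shape = c(8, 8, 8),
                                       n_volumes = 20,
                                       planted_center_mm = c(0, 0, 0),
                                       planted_radius_mm = 6,
                                       planted_effect_d = 0.8, seed = 8))
  expect_false(identical(co1$group_a[[1]]$vol$data,
                         other$group_a[[1]]$vol$data))

  expect_error(cohort_spec(n_per_group = 1), "n_per_group")
  expect_error(cohort_spec(planted_radius_mm = 0), "radius")
  # sphere poking out of the grid names the offending axis/coordinate
  bad <- cohort_spec(grid_shape = c(8, 8, 8),
                     planted_center_mm = c(-20, 0, 0),
                     planted_radius_mm = 6)
  expect_error(generate_cohort(bad), "outside the grid")
})

test_that("cohort masks are disjoint tissue compartments on the grid", {
  co <- generate_cohort(cohort_spec(n_per_group = 2, n_volumes = 20,
                                    seed = 3))
  expect_false(any(co$gm_mask & co$wm_mask))
  expect_false(any(co$gm_mask & co$csf_mask))
  expect_true(all(co$planted_voxels %in% which(co$gm_mask)))
  expect_gt(sum(co$gm_mask), 500)
})

test_that("a null cohort produces nominal voxel-wise false positives", {
  spec <- cohort_spec(n_per_group = 8, grid_shape = c(10, 10, 10),
                      n_volumes = 40, planted_center_mm = c(0, 0, 0),
                      planted_effect_d = 0, seed = 41)
  co <- generate_cohort(spec)
  prep <- function(s) reho_map(bandpass(discard_initial_volumes(s$vol, 5)),
                               co$gm_mask)
  res <- voxelwise_ttest(lapply(co$group_a, prep), lapply(co$group_b, prep),
                         co$gm_mask)
  rate <- mean(res$p$data[co$gm_mask] < 0.05)
  # ~5% rejections at alpha 0.05 (binomial slack for ~700 correlated voxels)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.12)
})

test_that("expression bundle generation is deterministic and structured", {
  co <- generate_cohort(cohort_spec(n_per_group = 2, n_volumes = 20,
                                    seed = 5))
  tmap <- activity_map(array(rnorm(prod(dim(co$gm_mask))),
                             dim = dim(co$gm_mask)),
                       co$affine, metric = "t", mask = co$gm_mask)
  spec <- expression_bundle_spec(n_donors = 3, n_samples_per_donor = 30,
                                 n_genes = 60, n_tracking_genes = 5,
                                 tracking_r = 0.7, seed = 11)
  b1 <- generate_expression_bundle(spec, tmap)
  b2 <- generate_expression_bundle(spec, tmap)
  expect_identical(b1$intensity, b2$intensity)
  expect_identical(b1$truth, b2$truth)

  # every gene has at least one probe; flags aligned with intensities
  expect_true(all(sprintf("G%05d", 1:60) %in% b1$probes$gene))
  expect_identical(dim(b1$flags), dim(b1$intensity))
  expect_equal(length(b1$truth$tracking_genes), 5)
  # left-cortex samples are in the left hemisphere half (x < 0)
  kept <- b1$samples$sample_id %in% b1$truth$kept_samples
  expect_true(all(b1$samples$mni_x[kept] < 0))
  expect_true(all(b1$samples$hemisphere[b1$samples$mni_x > 0] == "right"))

  expect_error(expression_bundle_spec(n_genes = 10, n_tracking_genes = 11),
               "n_tracking_genes")
  expect_error(expression_bundle_spec(n_probes = 5, n_genes = 10), "n_probes")
})

test_that("tracking genes correlate with the sphere-sampled map at the nominal strength", {
  co <- generate_cohort(cohort_spec(n_per_group = 2, n_volumes = 20,
                                    seed = 6))
  set.seed(61)
  tmap <- activity_map(array(rnorm(prod(dim(co$gm_mask))),
                             dim = dim(co$gm_mask)),
                       co$affine, metric = "t", mask = co$gm_mask)
  spec <- expression_bundle_spec(n_donors = 6, n_samples_per_donor = 67,
                                 n_genes = 50, n_tracking_genes = 10,
                                 tracking_r = 0.6, seed = 12)
  b <- generate_expression_bundle(spec, tmap)
  kept <- b$samples$sample_id %in% b$truth$kept_samples
  coords <- as.matrix(b$samples[kept, c("mni_x", "mni_y", "mni_z")])
  tv <- sample_tmap_spheres(tmap, coords, radius_mm = 3, mask = co$gm_mask)
  best <- b$probes$probe_id[match(b$truth$tracking_genes, b$probes$gene)]
  obs <- vapply(best, function(p) cor(b$intensity[p, kept], tv), numeric(1))
  expect_equal(mean(abs(obs)), 0.6, tolerance = 0.1)

  # perfect-signal limit
  spec1 <- expression_bundle_spec(n_donors = 3, n_samples_per_donor = 40,
                                  n_genes = 20, n_tracking_genes = 3,
                                  tracking_r = 1, seed = 13)
  b1 <- generate_expression_bundle(spec1, tmap)
  kept1 <- b1$samples$sample_id %in% b1$truth$kept_samples
  tv1 <- sample_tmap_spheres(tmap,
                             as.matrix(b1$samples[kept1, c("mni_x", "mni_y",
                                                           "mni_z")]),
                             radius_mm = 3, mask = co$gm_mask)
  best1 <- b1$probes$probe_id[match(b1$truth$tracking_genes, b1$probes$gene)]
  obs1 <- vapply(best1, function(p) cor(b1$intensity[p, kept1], tv1),
                 numeric(1))
  expect_true(all(abs(obs1) > 0.97))
})

test_that("clinical tables are deterministic with a controllable group shift", {
  t1 <- generate_clinical_table(n_a = 10, n_b = 10, score_shift = 0, seed = 2)
  t2 <- generate_clinical_table(n_a = 10, n_b = 10, score_shift = 0, seed = 2)
  expect_identical(t1, t2)
  expect_equal(sum(t1$group == "HC"), 10)
  expect_true(any(is.na(t1$bmi)))
  expect_error(generate_clinical_table(n_a = 1, n_b = 5), "at least 2")
})

test_that("a 3-SD designated shift is detected at p < 0.001 in >= 95% of seeds", {
  hits <- vapply(1:200, function(s) {
    tb <- generate_clinical_table(n_a = 30, n_b = 27, score_shift = 3,
                                  seed = s)
    compare_groups(tb$hama, tb$group)$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("null clinical scores give approximately uniform p-values", {
  ps <- vapply(1:60, function(s) {
    tb <- generate_clinical_table(n_a = 15, n_b = 15, score_shift = 0,
                                  seed = 1000 + s)
    compare_groups(tb$bdi, tb$group)$p
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0)   # some small p-values occur eventually
  expect_lt(mean(ps < 0.05), 0.2) # but not an excess
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("synthetic inputs round-trip through their on-disk formats", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(n_per_group = 2, grid_shape = c(6, 6, 6),
                                    n_volumes = 10,
                                    planted_center_mm = c(0, 0, 0),
                                    planted_radius_mm = 4, seed = 9))
  write_cohort(co, file.path(dir, "cohort"))
  v <- read_volume(file.path(dir, "cohort", "group_a_sub01_bold.nii.gz"))
  expect_s3_class(v, "ts_volume")
  expect_equal(v$data, co$group_a[[1]]$vol$data, tolerance = 1e-6)
  expect_equal(v$affine, co$affine, tolerance = 1e-5, ignore_attr = TRUE)
  motion <- as.matrix(read.delim(file.path(dir, "cohort",
                                           "group_a_sub01_motion.tsv")))
  expect_equal(unname(motion), unname(co$group_a[[1]]$motion),
               tolerance = 1e-12)

  tmap <- activity_map(array(0, dim = c(6, 6, 6)), co$affine,
                       mask = co$gm_mask)
  b <- generate_expression_bundle(
    expression_bundle_spec(n_donors = 2, n_samples_per_donor = 10,
                           n_genes = 12, seed = 1), tmap)
  write_expression_bundle(b, file.path(dir, "bundle"))
  expect_true(all(file.exists(file.path(dir, "bundle",
                                        c("probes.tsv", "expression.tsv",
                                          "noise_flags.tsv", "rnaseq.tsv",
                                          "samples.tsv")))))
  expr <- read.delim(file.path(dir, "bundle", "expression.tsv"),
                     check.names = FALSE)
  expect_equal(as.matrix(expr[, -1]), b$intensity, tolerance = 1e-12,
               ignore_attr = TRUE)

  tb <- generate_clinical_table(5, 5, seed = 3)
  write_clinical_table(tb, file.path(dir, "clin.csv"))
  tb2 <- read.csv(file.path(dir, "clin.csv"))
  expect_equal(tb2$hama, tb$hama)
})
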