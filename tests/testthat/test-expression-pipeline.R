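# hand-built miniature bundle exercising each pipeline rule
mini_bundle <- function() {
  samples <- data.frame(
    sample_id = sprintf("S%02d", 1:12),
    donor = rep(c("D1", "D2"), each = 6),
    mni_x = rep(c(-9, -9, -6, -6, 9, -9), 2),
    mni_y = 0, mni_z = rep(c(-6, -3, 0, 3, 0, 0), 2),
    hemisphere = rep(c("left", "left", "left", "left", "right", "left"), 2),
    cortical = rep(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE), 2),
    structure = rep(c("A", "A", "B", "B", "B", "SUBCTX"), 2),
    stringsAsFactors = FALSE)
  set.seed(99)
  truthA <- rnorm(12); truthB <- rnorm(12)
  intensity <- rbind(
    pA1 = 8 + truthA + 0.05 * rnorm(12),   # good probe, gene A
    pA2 = 8 + 0.2 * truthA + rnorm(12),    # weaker probe, gene A
    pB1 = 8 + truthB + 0.05 * rnorm(12),   # good probe, gene B
    pB2 = 8 - truthB + 0.05 * rnorm(12),   # anti-correlated probe, gene B
    pC1 = 8 - truthA + 0.05 * rnorm(12))   # gene C: only anti-correlated
  colnames(intensity) <- samples$sample_id
  flags <- matrix(1L, nrow = 5, ncol = 12, dimnames = dimnames(intensity))
  rna_units <- c("D1:A", "D1:B", "D2:A", "D2:B")
  unit_mean <- function(truth, donor, struct) {
    sel <- samples$donor == donor & samples$structure == struct &
      samples$hemisphere == "left" & samples$cortical
    mean(8 + truth[sel])
  }
  rnaseq <- rbind(
    A = c(unit_mean(truthA, "D1", "A"), unit_mean(truthA, "D1", "B"),
          unit_mean(truthA, "D2", "A"), unit_mean(truthA, "D2", "B")),
    B = c(unit_mean(truthB, "D1", "A"), unit_mean(truthB, "D1", "B"),
          unit_mean(truthB, "D2", "A"), unit_mean(truthB, "D2", "B")),
    C = c(unit_mean(truthA, "D1", "A"), unit_mean(truthA, "D1", "B"),
          unit_mean(truthA, "D2", "A"), unit_mean(truthA, "D2", "B")))
  colnames(rnaseq) <- rna_units
  structure(list(
    probes = data.frame(probe_id = rownames(intensity),
                        gene = c("A", "A", "B", "B", "C"),
                        stringsAsFactors = FALSE),
    intensity = intensity, flags = flags, rnaseq = rnaseq,
    samples = samples), class = "expression_bundle")
}

test_that("intensity filtering keeps probes above background in >= 50% of samples", {
  b <- mini_bundle()
  b$flags["pA2", ] <- 0L                       # 0%: removed
  b$flags["pB2", 1:6] <- 0L                    # exactly 50%: retained
  b$flags["pC1", 1:7] <- 0L                    # 41.7%: removed
  out <- filter_probes_intensity(b)
  expect_setequal(attr(out, "retained"), c("pA1", "pB1", "pB2"))
})

test_that("RNA-seq-guided selection keeps the best qualifying probe per gene", {
  b <- mini_bundle()
  sel <- select_probes_by_rnaseq(b, min_r = 0.2)
  expect_equal(sel$probe_id[sel$gene == "A"], "pA1")
  expect_equal(sel$probe_id[sel$gene == "B"], "pB1")
  expect_false("C" %in% sel$gene)  # only an anti-correlated probe: dropped
  # brute-force correlation check for gene A over matched donor-structure units
  key <- paste(b$samples$donor, b$samples$structure, sep = ":")
  usable <- key %in% colnames(b$rnaseq)
  agg1 <- tapply(b$intensity["pA1", usable], key[usable], mean)
  agg2 <- tapply(b$intensity["pA2", usable], key[usable], mean)
  ref <- b$rnaseq["A", names(agg1)]
  r1 <- cor(agg1, ref)
  expect_gt(r1, cor(agg2, ref))
  expect_equal(sel$r[sel$gene == "A"], unname(r1), tolerance = 1e-12)

  # a zero-variance probe counts as sub-threshold
  b2 <- mini_bundle()
  b2$intensity["pA1", ] <- 5
  sel2 <- select_probes_by_rnaseq(b2, min_r = 0.2)
  expect_equal(sel2$probe_id[sel2$gene == "A"], "pA2")

  # genes absent from the RNA-seq platform are excluded up front
  b3 <- mini_bundle()
  b3$rnaseq <- b3$rnaseq[c("B", "C"), , drop = FALSE]
  expect_false("A" %in% select_probes_by_rnaseq(b3)$gene)
})

test_that("sample restriction keeps left cortical in-mask samples only", {
  b <- mini_bundle()
  dims <- c(8, 8, 8)
  affine <- centered_affine(dims, 3)
  mask <- array(TRUE, dim = dims)
  kept <- restrict_samples(b$samples, mask, affine)
  expect_setequal(kept, sprintf("S%02d", c(1:4, 7:10)))

  # out-of-mask coordinate is dropped
  mask2 <- array(FALSE, dim = dims)
  ijk <- round(mm_to_voxel(affine, c(-9, 0, -6)))
  mask2[ijk[1], ijk[2], ijk[3]] <- TRUE
  kept2 <- restrict_samples(b$samples, mask2, affine)
  expect_setequal(kept2, c("S01", "S07"))

  # far-outside coordinates are counted
  b$samples$mni_x[1] <- -500
  kept3 <- restrict_samples(b$samples, mask, affine)
  expect_equal(attr(kept3, "n_outside"), 1)
  expect_false("S01" %in% kept3)
})

test_that("scaled robust sigmoid normalization matches its formula", {
  x <- c(1, 2, 3, 4, 100)
  out <- srs_normalize(matrix(x, nrow = 1))[1, ]
  s <- 1 / (1 + exp(-(x - median(x)) / (IQR(x) / 1.35)))
  expect_equal(out, (s - min(s)) / (max(s) - min(s)), tolerance = 1e-12)
  # outlier gap is compressed relative to plain min-max scaling
  minmax <- (x - min(x)) / (max(x) - min(x))
  expect_lt(out[5] - out[4], minmax[5] - minmax[4])

  # the median element sits at the sigmoid midpoint before rescaling
  sig <- 1 / (1 + exp(-(x - median(x)) / (IQR(x) / 1.35)))
  expect_equal(sig[3], 0.5)

  # output bounded and rank-preserving on random vectors
  set.seed(14)
  for (i in 1:20) {
    v <- rnorm(sample(5:30, 1))
    o <- srs_normalize(matrix(v, nrow = 1))[1, ]
    expect_true(all(o >= 0 & o <= 1))
    expect_identical(order(o), order(v))
  }

  # zero IQR: constant 0.5, degenerate counted
  z <- srs_normalize(matrix(rep(2, 6), nrow = 1))
  expect_equal(z[1, ], rep(0.5, 6))
  expect_equal(attr(z, "n_degenerate"), 1)
})

test_that("differential stability equals the brute-force pairwise Spearman mean", {
  genes <- paste0("g", 1:4)
  set.seed(15)
  structs <- c("s1", "s2", "s3", "s4")
  mats <- lapply(1:3, function(d) {
    m <- matrix(rnorm(8 * 4), nrow = 8,
                dimnames = list(NULL, genes))
    m
  })
  labs <- lapply(1:3, function(d) rep(structs, each = 2))
  names(mats) <- names(labs) <- paste0("D", 1:3)
  ds <- differential_stability(mats, labs)

  brute <- sapply(genes, function(g) {
    sm <- lapply(names(mats), function(d)
      tapply(mats[[d]][, g], labs[[d]], mean))
    prs <- combn(3, 2)
    mean(apply(prs, 2, function(pr)
      cor(sm[[pr[1]]], sm[[pr[2]]], method = "spearman")))
  })
  expect_equal(ds, brute, tolerance = 1e-12)

  # identical structure profiles give DS = 1
  shared <- matrix(rnorm(8 * 4), nrow = 8, dimnames = list(NULL, genes))
  ds1 <- differential_stability(list(D1 = shared, D2 = shared, D3 = shared),
                                labs)
  expect_equal(unname(ds1), rep(1, 4))

  # fewer than 3 shared structures in every pair is an error
  labs2 <- lapply(1:3, function(d) rep(c("s1", "s2"), each = 4))
  names(labs2) <- names(mats)
  expect_error(differential_stability(mats, labs2), "3 structures")
})

test_that("top-DS selection keeps ties and matches sort-and-slice", {
  ds <- setNames(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1), paste0("g", 1:10))
  expect_setequal(select_top_ds(ds, 0.5), paste0("g", 1:5))

  tied <- setNames(rep(1, 6), paste0("g", 1:6))
  expect_setequal(select_top_ds(tied, 0.5), paste0("g", 1:6))

  set.seed(16)
  for (i in 1:20) {
    v <- setNames(rnorm(sample(4:40, 1)), NULL)
    names(v) <- paste0("g", seq_along(v))
    keep <- select_top_ds(v, 0.5)
    k <- ceiling(0.5 * length(v))
    expected <- names(sort(v, decreasing = TRUE))[seq_len(k)]
    expect_setequal(keep, expected)
  }
})

test_that("the full pipeline recovers the planted construction exactly", {
  co <- generate_cohort(cohort_spec(n_per_group = 2, n_volumes = 20,
                                    seed = 17))
  set.seed(18)
  tmap <- activity_map(array(rnorm(prod(dim(co$gm_mask))),
                             dim = dim(co$gm_mask)), co$affine,
                       mask = co$gm_mask)
  spec <- expression_bundle_spec(n_donors = 4, n_samples_per_donor = 50,
                                 n_genes = 150, n_probes = 320,
                                 n_tracking_genes = 8, tracking_r = 0.6,
                                 seed = 19)
  b <- generate_expression_bundle(spec, tmap)
  mat <- process_expression_bundle(b, co$gm_mask, co$affine)

  # retained samples are exactly the planted left-cortex samples
  expect_setequal(mat$samples$sample_id, b$truth$kept_samples)
  # selected probes are exactly the designated best probes of surviving genes
  expect_true(all(mat$probe_map$probe_id %in% b$truth$best_probes))
  sel_all <- select_probes_by_rnaseq(filter_probes_intensity(b))
  expect_setequal(sel_all$probe_id,
                  setdiff(b$truth$best_probes,
                          b$probes$probe_id[b$probes$gene %in%
                                              b$truth$dropped_genes]))
  expect_false(any(b$truth$dropped_genes %in% colnames(mat$values)))
  # normalized values complete and bounded
  expect_false(any(is.na(mat$values)))
  expect_true(all(mat$values >= 0 & mat$values <= 1))
  # DS filter halves the surviving gene set (up to ties)
  expect_equal(ncol(mat$values), ceiling(nrow(sel_all) / 2))
})

test_that("SRS normalization preserves within-vector rank order in the pipeline", {
  set.seed(20)
  m <- matrix(rnorm(60), nrow = 6)
  out <- srs_normalize(m, margin = 2)
  for (j in seq_len(ncol(m)))
    expect_identical(order(out[, j]), order(m[, j]))
})
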