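#!/usr/bin/env Rscript
# Transcriptome-neuroimaging association: sample the uncorrected ReHo t-map
# in 3-mm spheres at each tissue sample's MNI coordinate, correlate every
# gene's cross-sample expression with the sampled t-values, apply the
# Bonferroni threshold 0.05 / n_genes, and intersect the significant genes
# with the risk-gene list to define the final target genes.
# Outputs: results/association/assoc.tsv, final_genes.txt
library(imgtx)

dir.create("results/association", recursive = TRUE, showWarnings = FALSE)
gm <- read_volume("results/sim/cohort/gm_mask.nii.gz")
tmap <- read_volume("results/group/reho_tmap.nii.gz")
risk <- read_risk_genes("results/expression/risk_genes.txt")

tab <- read.delim("results/expression/matrix.tsv", check.names = FALSE)
ann_cols <- c("sample_id", "donor", "mni_x", "mni_y", "mni_z", "structure")
mat <- structure(list(values = as.matrix(tab[, setdiff(names(tab), ann_cols)]),
                      samples = tab[, ann_cols]),
                 class = "gene_expression_matrix")

assoc <- run_spatial_association(mat, tmap, risk, alpha = 0.05,
                                 radius_mm = 3, mask = gm$data > 0.5)
cat(sprintf("Bonferroni threshold: 0.05 / %d = %.3e\n",
            ncol(mat$values), assoc$threshold))
cat(sprintf("%d of %d genes significantly correlated with the t-map\n",
            sum(assoc$result$significant), nrow(assoc$result)))
cat(sprintf("Final target genes (significant AND on the risk list): %s\n",
            paste(sprintf("%s (r = %.2f, %s)", assoc$final$gene,
                          assoc$final$r, assoc$final$direction),
                  collapse = "; ")))
write.table(assoc$result, "results/association/assoc.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
writeLines(assoc$final$gene, "results/association/final_genes.txt")
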