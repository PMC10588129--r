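#!/usr/bin/env Rscript
# Step 4 — robustness to protocol and reference-profile variation.
#
# Deconvolves every matched bulk sample (3 protocols x 8 tumors) with
# NNLS against the full reference, the downsampled reference ladder
# (2000/1000/500/200 cells), and the hash-assigned subset reference.
# Reports variance of the estimates across bulk protocols and across
# reference profiles (plus stepwise), the accuracy-vs-robustness
# summary, and the factor ANOVA on epithelial proportion estimates.

library(deconvbench)

STUDY_SEED <- 20260315
dir.create("results", showWarnings = FALSE)

ref <- generate_reference(cohort_config(), seed = STUDY_SEED)
blocks <- gene_blocks(ref$gene_ids)
tumors <- sort(unique(ref$sample_id))

bulks <- list()
for (tm in tumors) {
  bs <- generate_bulk_set(ref, tm, seed = STUDY_SEED, blocks = blocks)
  for (b in bs) bulks[[paste(tm, b$protocol, sep = ".")]] <- b
}

# reference ladder + hash-subset reference
adhesion <- setNames(rep(0.9, length(tumors)), tumors)
adhesion["tumor02"] <- 0.35
tabs <- generate_assignment_tables(ref, hash_adhesion = adhesion,
                                   doublet_rate = 0.05,
                                   seed = STUDY_SEED)
hash_lab <- structure(list(
  label = unlist(lapply(tabs, function(p)
    call_assignments(p$hash, 0.90)$label), use.names = FALSE),
  barcodes = unlist(lapply(tabs, function(p) p$hash$barcodes),
                    use.names = FALSE),
  threshold = 0.90, modality = "hash"), class = "demux_labels")

refs <- c(list(full = ref),
          setNames(lapply(size_ladder(), function(sz)
            downsample_reference(ref, sz, seed = STUDY_SEED)),
            paste0("size", size_ladder())),
          list(hash_subset = subset_by_labels(ref, hash_lab)))
sigs <- lapply(names(refs), function(tag)
  build_signature(refs[[tag]], reference_tag = tag))
names(sigs) <- names(refs)

results <- list()
for (tag in names(sigs)) {
  for (bn in names(bulks)) {
    results[[paste(tag, bn, sep = "|")]] <-
      deconvolve(sigs[[tag]], bulks[[bn]])
  }
}
est <- results_table(results)

vp <- robustness_variance(est[est$reference_tag == "full", ], "protocol")
vr <- robustness_variance(est, "reference_tag")
st <- stepwise_variance(est[est$reference_tag != "hash_subset", ],
                        order = c("full", paste0("size", size_ladder())))
write.table(vp$table, "results/variance_protocol.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(vr$table, "results/variance_reference.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(st, "results/stepwise_variance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("mean variance across bulk protocols (full reference):\n")
print(vp$by_method, row.names = FALSE)
cat("\nmean variance across reference profiles:\n")
print(vr$by_method, row.names = FALSE)

# accuracy axis: pseudo-bulk RMSE from step 3 if available, else recompute
acc_path <- "results/pseudobulk_rmse.tsv"
if (file.exists(acc_path)) {
  acc <- read.table(acc_path, sep = "\t", header = TRUE)
  summ <- accuracy_robustness_summary(acc, vp$by_method)
  write.table(summ, "results/accuracy_robustness.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat("\naccuracy vs robustness (per method):\n")
  print(summ, row.names = FALSE)
} else {
  cat("\n(run 03_pseudobulk_accuracy.R first for the accuracy axis)\n")
}

# factor ANOVA on epithelial estimates; method has one level here
# (NNLS only), so the tested factors are enrichment, reference size,
# and dissociation status
meta <- do.call(rbind, lapply(results, function(r) {
  b <- bulks[[paste(r$sample_id, r$protocol, sep = ".")]]
  data.frame(method = r$method, enrichment = b$effects$enrichment,
             reference_size = r$reference_tag,
             dissociated = b$effects$dissociated,
             estimate = unname(r$fractions["epithelial"]))
}))
an <- suppressWarnings(anova_factors(meta))
write.table(an, "results/anova_epithelial.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nANOVA on epithelial proportion estimates (Type I, sequential):\n")
print(an, row.names = FALSE)
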