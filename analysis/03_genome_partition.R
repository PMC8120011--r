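#!/usr/bin/env Rscript
# Classify scaffolds as autosome / Z / W from sex-stratified read depth
# and male missingness, then re-infer each sample's sex from one Z and
# one W marker scaffold and compare with the recorded sexes.

library(strixpop)

dt <- read_depth_table("results/data/depth.tsv")
md <- read_sample_metadata("results/data/metadata.tsv")
sexes <- setNames(md$sex, md$sample_id)

cls <- classify_autosome_z(dt, sexes)
w <- identify_w(dt, sexes)
cls$class[cls$scaffold %in% w] <- "W"
print(cls)
write.table(cls, "results/scaffold_classes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("W scaffolds (>= 100 kb, male missingness > 0.99): %s",
                paste(w, collapse = ", ")))

sx <- infer_sex(dt, z_marker = cls$scaffold[cls$class == "Z"][1],
                w_marker = w[1])
sx$recorded <- sexes[sx$sample_id]
write.table(sx, "results/sex_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("sex calls matching recorded sex: %d / %d",
                sum(sx$sex == sx$recorded), nrow(sx)))
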