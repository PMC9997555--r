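#!/usr/bin/env Rscript
# Line QC on the simulated experiment: the dish-mate contamination rule
# (shared identical mutation removes the even-numbered line) followed by
# the 30x mean-depth floor. With the planted artifacts this reproduces
# the study's accounting: 80 - 3 - 4 = 73 control and 90 - 1 - 3 = 86
# treated lines kept.
#
# Reads results/data/, writes results/qc/.

suppressPackageStartupMessages(library(mamut))

md <- read_metadata("results/data/metadata.tsv")
mut <- read_vcf_dir("results/data/vcf")
qc <- qc_lines(mut, md, min_depth = 30)

dir.create("results/qc", recursive = TRUE, showWarnings = FALSE)
write.table(qc$report, "results/qc/removals.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(qc$kept, "results/qc/metadata_kept.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(qc$mutations, "results/qc/mutations_kept.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

kept <- table(qc$kept$group)
rem <- merge(qc$report, md[, c("line_id", "group")], by = "line_id")
cat("QC summary:\n")
for (g in names(kept)) {
  r <- rem[rem$group == g, ]
  cat(sprintf("  %s: %d sequenced, %d contaminated, %d low-depth -> %d kept\n",
              g, sum(md$group == g), sum(r$rule == "contamination"),
              sum(r$rule == "depth"), kept[[g]]))
}
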