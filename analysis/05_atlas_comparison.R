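#!/usr/bin/env Rscript
# Pairwise Dice similarity between the parcellations of the three modal
# atlases, per hemisphere: cerebellar vs thalamic, cerebellar vs
# microstructure, thalamic vs microstructure.

source("analysis/00_common.R")

modal_path <- file.path(SCRATCH, "modal_atlases.rds")
if (!file.exists(modal_path))
  stop("run analysis/04_group_atlases.R first")
modal <- readRDS(modal_path)

pairs <- list(c("cerebellar", "thalamic"),
              c("cerebellar", "micro"),
              c("thalamic", "micro"))

for (side in c("left", "right")) {
  for (p in pairs) {
    m <- dsc_matrix(modal[[paste(p[1], side, sep = "_")]],
                    modal[[paste(p[2], side, sep = "_")]])
    df <- data.frame(parcel = rownames(m), as.data.frame(unclass(m),
                                                         check.names = FALSE))
    write_tsv(df, sprintf("dsc_%s_vs_%s_%s.tsv", p[1], p[2], side))
    top <- which(m == max(m), arr.ind = TRUE)[1, ]
    message(sprintf("%s %s vs %s: max DSC %.2f (%s ~ %s)", side, p[1], p[2],
                    max(m), rownames(m)[top[1]], colnames(m)[top[2]]))
  }
}
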