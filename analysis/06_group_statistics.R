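#!/usr/bin/env Rscript
# Cohort statistics over the connectivity features and per-parcel
# diffusion metrics: paired left/right Wilcoxon tests, Friedman tests of
# metric differences across parcels, and female/male Mann-Whitney
# comparisons. On this synthetic cohort no hemisphere or sex effect is
# planted, so these tests characterize the pipeline's null behaviour.

source("analysis/00_common.R")

coh <- get_cohort()
spec <- coh$spec
sex <- vapply(coh$subjects, `[[`, "", "sex")

features <- function(side) {
  summaries <- lapply(coh$subjects, function(sub) {
    f <- build_membership_field(sub[[side]]$tdi_cerebellar, sub[[side]]$dn_mask)
    summarize_parcellation(f, winner_takes_all(f))
  })
  subject_feature_table(summaries, sex = sex)
}
left <- features("left")
right <- features("right")

## paired left/right comparisons per target
rows <- lapply(spec$conn_targets, function(t) {
  ws <- wilcoxon_paired(left[[paste0("streamlines_", t)]],
                        right[[paste0("streamlines_", t)]])
  wv <- wilcoxon_paired(left[[paste0("volume_pct_", t)]],
                        right[[paste0("volume_pct_", t)]])
  data.frame(target = t,
             p_streamlines = ws$p.value, p_volume = wv$p.value)
})
lr <- do.call(rbind, rows)
write_tsv(lr, "stats_left_right_wilcoxon.tsv")
message("left/right Wilcoxon: ", sum(lr$p_streamlines < 0.05 | lr$p_volume < 0.05),
        " of ", nrow(lr), " targets nominally significant at alpha = 0.05")

## per-parcel metric means and Friedman tests across parcels
for (side in c("left", "right")) {
  for (metric in c("FA", "MD", "MK")) {
    per_sub <- t(vapply(seq_along(coh$subjects), function(i) {
      sub <- coh$subjects[[i]]
      atlas <- winner_takes_all(
        build_membership_field(sub[[side]]$tdi_cerebellar, sub[[side]]$dn_mask))
      parcel_metric_means(atlas, sub[[side]]$metrics[[metric]])
    }, numeric(6)))
    keep <- colSums(is.na(per_sub)) == 0
    fr <- friedman_parcels(per_sub[, keep])
    df <- data.frame(target = colnames(per_sub),
                     mean = colMeans(per_sub, na.rm = TRUE),
                     sd = apply(per_sub, 2, sd, na.rm = TRUE))
    df$friedman_chisq <- fr$statistic
    df$friedman_p <- fr$p.value
    write_tsv(df, sprintf("stats_metric_%s_%s.tsv", metric, side))
    message(sprintf("%s %s: Friedman chi-sq %.1f, p = %.3g", side, metric,
                    fr$statistic, fr$p.value))
  }
}

## exploratory female/male comparisons (no effect planted)
mw <- lapply(spec$conn_targets, function(t) {
  a <- left[[paste0("streamlines_", t)]][sex == "F"]
  b <- left[[paste0("streamlines_", t)]][sex == "M"]
  res <- mann_whitney_groups(a, b)
  data.frame(target = t, U = res$statistic, p = res$p.value)
})
mw <- do.call(rbind, mw)
write_tsv(mw, "stats_sex_mannwhitney.tsv")
message("female/male Mann-Whitney: ", sum(mw$p < 0.05), " of ", nrow(mw),
        " targets nominally significant")
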