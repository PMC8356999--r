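#!/usr/bin/env Rscript
# Inter-subject modal atlases for the three parcellation routes
# (cerebellar connectivity, thalamic connectivity, microstructure), with
# per-label probability maps and agreement against the phantom truth.

source("analysis/00_common.R")

coh <- get_cohort()
spec <- coh$spec

atlas_of <- function(sub, side, route) {
  switch(route,
    cerebellar = winner_takes_all(
      build_membership_field(sub[[side]]$tdi_cerebellar, sub[[side]]$dn_mask)),
    thalamic = winner_takes_all(
      build_membership_field(sub[[side]]$tdi_thalamic, sub[[side]]$dn_mask)),
    micro = microstructure_parcellation(
      sub[[side]]$metrics, sub[[side]]$dn_mask,
      seed = COHORT_SEED + match(sub$subject_id,
                                 vapply(coh$subjects, `[[`, "", "subject_id")))$atlas)
}

truth_of <- function(side, route) {
  ph <- coh$phantom[[side]]
  switch(route, cerebellar = ph$truth_conn, thalamic = ph$truth_conn_thal,
         micro = ph$truth_micro)
}

rows <- list()
modal <- list()
for (route in c("cerebellar", "thalamic", "micro")) {
  for (side in c("left", "right")) {
    atlases <- lapply(coh$subjects, atlas_of, side = side, route = route)
    ma <- modal_atlas(atlases)
    modal[[paste(route, side, sep = "_")]] <- ma
    write_volume(ma, file.path(SCRATCH, sprintf("modal_%s_%s.nii.gz", route, side)))
    pm <- label_probability_maps(atlases)
    for (nm in names(pm))
      write_volume(pm[[nm]], file.path(
        SCRATCH, sprintf("prob_%s_%s_%s.nii.gz", route, side, nm)))

    truth <- truth_of(side, route)
    sel <- coh$phantom[[side]]$dn_mask$labels == 1L
    acc <- mean(ma$labels[sel] == truth$labels[sel])
    mean_top_prob <- mean(vapply(seq_len(sum(sel)), function(i) {
      max(vapply(pm, function(v) v$values[sel][i], numeric(1)))
    }, numeric(1)))
    rows[[length(rows) + 1L]] <- data.frame(
      route = route, side = side, modal_accuracy = acc,
      mean_winning_probability = mean_top_prob,
      unassigned_pct = 100 * mean(ma$labels[sel] == 0L))
    message(sprintf("%-10s %-5s modal accuracy %.4f", route, side, acc))
  }
}
saveRDS(modal, file.path(SCRATCH, "modal_atlases.rds"))
write_tsv(do.call(rbind, rows), "group_atlas_accuracy.tsv")
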