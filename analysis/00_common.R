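# Shared setup for the analysis scripts: study-scale phantom spec and a
# cached cohort so each numbered script can run standalone. Tables go to
# results/ (text); volumes and caches go to scratch/ (disposable).

library(dntopo)

RESULTS <- "results"
SCRATCH <- "scratch"
dir.create(RESULTS, showWarnings = FALSE)
dir.create(SCRATCH, showWarnings = FALSE)

COHORT_SEED <- 20260102L

get_cohort <- function() {
  cache <- file.path(SCRATCH, "cohort.rds")
  if (file.exists(cache)) return(readRDS(cache))
  spec <- phantom_spec(seed = COHORT_SEED)
  message("Simulating ", spec$n_subjects, "-subject cohort (both hemispheres) ...")
  coh <- simulate_cohort(spec)
  coh$spec <- spec
  saveRDS(coh, cache)
  coh
}

write_tsv <- function(df, name) {
  path <- file.path(RESULTS, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
  invisible(path)
}
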