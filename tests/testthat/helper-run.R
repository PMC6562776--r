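# One shared default-pipeline run (balanced corpus, fixed seed) reused by
# the end-to-end tests; built lazily, once per test session.
default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "vocalmap_default_run")
      cache <<- run_pipeline(pipeline_config(seed = 1L, out_dir = dir))
    }
    cache
  }
})

merged_truth <- function(labels) {
  ifelse(labels %in% c("grunt", "hum"), "grunt_hum",
         ifelse(labels %in% c("kiss", "wheeze"), "kiss_wheeze", labels))
}

graded_pairs <- c("grunt hum", "kiss wheeze", "grunt wheezing_grunt")

error_pair_fraction <- function(truth, pred) {
  err <- truth != pred
  if (!any(err)) return(1)  # no misclassifications to fall outside the pairs
  pairs <- paste(pmin(truth[err], pred[err]), pmax(truth[err], pred[err]))
  mean(pairs %in% graded_pairs)
}
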