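#!/usr/bin/env Rscript
# Thin command-line wrapper over the package's orchestrator.
#   Rscript scripts/run_pipeline.R [--config cfg.yaml] [--seed <int>] [--out dir]
# Exit codes: 0 ok, 1 user error, 2 internal error.

suppressPackageStartupMessages(library(rbpprio))

main <- function() {
  args <- commandArgs(trailingOnly = TRUE)
  opts <- list(config = NULL, seed = 1L, out = "pipeline_out")
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opts)) {
      message("unknown argument: ", args[i])
      quit(status = 1L)
    }
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  cfg <- if (!is.null(opts$config)) {
    read_run_config(opts$config)
  } else {
    run_config(seed = as.integer(opts$seed))
  }
  cfg$out <- opts$out
  report <- run_pipeline(cfg)
  print(report)
  invisible(report)
}

status <- tryCatch({
  main()
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  2L
})
quit(status = status)
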