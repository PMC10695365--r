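#!/usr/bin/env Rscript
# Thin command-line wrapper over the grouptrax package. Subcommands:
#   run       full pipeline from a YAML config
#   simulate  write simulated group trajectories as CSV
#   repair    repair a long-format trajectory CSV
#   metrics   social indices from a repaired trajectory CSV
#   stats     battery PCA from a battery CSV
#   report    render report.md from a results.json
# Every statistic is computed by exported package functions; this script only
# parses arguments and moves files.

suppressPackageStartupMessages({
  library(optparse)
  library(grouptrax)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L)
  stop("usage: pipeline.R <run|simulate|repair|metrics|stats|report> [options]")
cmd <- args[[1]]
rest <- args[-1]

optlist <- list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML run configuration"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "run_out",
              help = "output directory or file"),
  make_option("--input", type = "character", default = NULL,
              help = "input CSV (repair/metrics/stats/report)"),
  make_option("--frame-rate", type = "double", default = 5, dest = "frameRate"),
  make_option("--width", type = "double", default = 91),
  make_option("--height", type = "double", default = 54),
  make_option("--duration", type = "double", default = 9 * 3600),
  make_option("--days", type = "integer", default = 7L))
o <- parse_args(OptionParser(option_list = optlist), args = rest)

cfgFrom <- function() {
  cfg <- if (is.null(o$config)) defaultRunConfig(seed = o$seed)
  else readRunConfig(o$config)
  validateRunConfig(cfg)
}

switch(cmd,
  run = {
    runPipeline(cfgFrom(), o$out)
    cat("pipeline written to", o$out, "\n")
  },
  simulate = {
    cfg <- cfgFrom()
    dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
    g <- cfg$groups[[1]]
    tr <- lapply(setNames(nm = g$animals), function(id)
      agentTraits(attraction = setNames(rep(0.1, 3),
                                        setdiff(g$animals, id))))
    days <- simulateGroup(tr, arenaConfig(
      width = o$width, height = o$height, frameRate = o$frameRate,
      sessionDuration = o$duration, nDays = o$days, seed = o$seed),
      g$familiar)
    for (ts in days)
      writeLongCSV(ts, file.path(o$out, sprintf(
        "day%02d.csv", S4Vectors::metadata(ts)$day)))
    cat(length(days), "day files written to", o$out, "\n")
  },
  repair = {
    stopifnot(!is.null(o$input))
    ts <- readLongCSV(o$input, arena = c(o$width, o$height),
                      frame_rate = o$frameRate)
    rp <- repairTracks(ts)
    writeLongCSV(rp$tracks, o$out)
    repairReportJSON(rp$report, sub("\\.csv$", "_report.json", o$out))
    cat("repaired trajectory written to", o$out, "\n")
  },
  metrics = {
    stopifnot(!is.null(o$input))
    ts <- readLongCSV(o$input, arena = c(o$width, o$height),
                      frame_rate = o$frameRate)
    ps <- proximitySeries(ts)
    ev <- detectEvents(ps, ts)
    write.csv(ev, o$out, row.names = FALSE)
    cat(nrow(ev), "events written to", o$out, "\n")
  },
  stats = {
    stopifnot(!is.null(o$input))
    tab <- read.csv(o$input, check.names = FALSE)
    tab <- tab[, setdiff(names(tab), "subject")]
    p <- pcaBattery(tab)
    out <- cbind(item = rownames(p@loadings),
                 as.data.frame(p@loadings[, seq_len(p@nKeep)]))
    write.csv(out, o$out, row.names = FALSE)
    cat("loadings written to", o$out, "\n")
  },
  report = {
    stopifnot(!is.null(o$input))
    res <- jsonlite::read_json(o$input, simplifyVector = TRUE)
    writeLines(renderReport(res), o$out)
    cat("report written to", o$out, "\n")
  },
  stop("unknown subcommand: ", cmd))
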