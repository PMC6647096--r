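#!/usr/bin/env Rscript
#  Thin command-line wrapper over the epiresist pipeline functions.
#
#  Usage:
#    Rscript scripts/pipeline.R simulate --out-dir DIR [--seed N] [--n-patients N] [--n-sites N]
#    Rscript scripts/pipeline.R all      --in-dir DIR --out-dir DIR [--seed N] [--config FILE]
#    Rscript scripts/pipeline.R <stage>  --in-dir DIR --out-dir DIR [--seed N] [--config FILE]
#        where <stage> is one of: methylation variants expression associate survive
#    Rscript scripts/pipeline.R report   --in-dir DIR --out-dir DIR [--seed N]
#
#  --config is an optional YAML file of pipeline_config() threshold
#  overrides (min_reads, min_sample_frac, sd_threshold, min_depth,
#  min_qual, min_vaf, max_pop_freq, z4_threshold, alpha, b_permutations).
#  Exits 0 on success; on failure prints the failing stage and exits 1.

suppressMessages(library(epiresist))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  cat("error: no subcommand given\n")
  quit(status = 1)
}
cmd <- args[1]
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_arg("--seed", "1"))
out_dir <- get_arg("--out-dir", "pipeline_out")
in_dir <- get_arg("--in-dir")

stage_map <- c(methylation = "methylation", variants = "variants",
               expression = "expression", associate = "association",
               survive = "survival")

load_overrides <- function() {
  cfg_path <- get_arg("--config")
  if (is.null(cfg_path)) return(list())
  yaml::read_yaml(cfg_path)
}

input_paths <- function(dir) {
  list(counts = file.path(dir, "signature_counts.tsv"),
       variants = file.path(dir, "variants.tsv"),
       expression = file.path(dir, "expression_ct.csv"),
       clinical = file.path(dir, "clinical.csv"),
       line1 = file.path(dir, "line1.csv"))
}

run <- function() {
  if (cmd == "simulate") {
    n_patients <- as.integer(get_arg("--n-patients", "122"))
    n_sites <- as.integer(get_arg("--n-sites", "2000"))
    co <- simulate_cohort(cohort_sim_config(n_patients = n_patients,
                                            n_sites = n_sites, seed = seed))
    write_cohort(co, out_dir)
    cat("simulated cohort written to", out_dir, "\n")
    return(invisible())
  }
  if (is.null(in_dir)) stop("--in-dir is required for `", cmd, "`")
  stages <- if (cmd == "all" || cmd == "report") {
    c("methylation", "variants", "expression", "association", "survival")
  } else if (cmd %in% names(stage_map)) {
    # downstream stages depend on expression/clinical joins; run the
    # requested stage plus its minimal upstream requirements
    unique(c(if (stage_map[[cmd]] %in% c("association", "survival"))
      "expression", stage_map[[cmd]]))
  } else {
    stop("unknown subcommand `", cmd, "`")
  }
  ov <- load_overrides()
  cfg <- do.call(pipeline_config,
                 c(list(input = input_paths(in_dir), stages = stages,
                        seed = seed), ov))
  res <- run_pipeline(cfg, out_dir = out_dir)
  if (cmd == "report") {
    clinical <- read_clinical(file.path(in_dir, "clinical.csv"))
    rep <- make_report(res, clinical)
    readr::write_csv(rep, file.path(out_dir, "report.csv"))
    cat("report written to", file.path(out_dir, "report.csv"), "\n")
  }
  cat("stages completed:", paste(stages, collapse = ", "), "\n")
}

tryCatch(run(), error = function(e) {
  cat("error:", conditionMessage(e), "\n")
  quit(status = 1)
})
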