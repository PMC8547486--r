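#!/usr/bin/env Rscript
# Thin command-line wrapper around the hipmorph package:
#   hipmorph run          --config cfg.yaml --seed 1 --out run_dir
#   hipmorph simulate     --n 500 --seed 1 --out dir
#   hipmorph measure      --landmarks landmarks.csv --out dir
#   hipmorph grade        --measures measures.csv --participants p.csv --out dir
#   hipmorph associate    --grades grades.csv --out dir
#   hipmorph table1       --grades grades.csv --out dir
#   hipmorph repeatability --measures measures.csv --measures2 m2.csv --out dir

suppressPackageStartupMessages(library(hipmorph))

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) stop("usage: hipmorph <command> [--flag value ...]")
cmd <- args[1]
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}
out <- get_arg("--out", "hipmorph_out")
seed <- as.integer(get_arg("--seed", "1"))
dir.create(out, showWarnings = FALSE, recursive = TRUE)

switch(cmd,
  run = {
    cfg_path <- get_arg("--config")
    cfg <- if (is.null(cfg_path)) default_pipeline_config(
      n_participants = as.integer(get_arg("--n", "500")), seed = seed)
    else yaml::read_yaml(cfg_path)
    cfg$seed <- seed
    run_pipeline(cfg, out_dir = out)
    cat("pipeline run written to", out, "\n")
  },
  simulate = {
    cht <- generate_cohort(as.integer(get_arg("--n", "500")), seed = seed,
                           with_landmarks = TRUE)
    write_landmarks(cht$landmarks, file.path(out, "landmarks.csv"))
    write.csv(cht$participants, file.path(out, "participants.csv"),
              row.names = FALSE)
    yaml::write_yaml(list(n = nrow(cht$participants), seed = seed),
                     file.path(out, "simulate_config.yaml"))
    cat("simulated", nrow(cht$participants), "participants into", out, "\n")
  },
  measure = {
    rl <- read_landmarks(get_arg("--landmarks"))
    m <- measure_cohort(rl$landmarks)
    write.csv(m, file.path(out, "measures.csv"), row.names = FALSE)
    if (nrow(rl$rejected))
      write.csv(rl$rejected, file.path(out, "rejected.csv"), row.names = FALSE)
    cat("measured", nrow(m), "records (", nrow(rl$rejected), "rejected )\n")
  },
  grade = {
    m <- read.csv(get_arg("--measures"), stringsAsFactors = FALSE)
    p <- read.csv(get_arg("--participants"), stringsAsFactors = FALSE)
    g <- grade_cohort(m, p)
    write.csv(g, file.path(out, "grades.csv"), row.names = FALSE)
    cat("graded", nrow(g), "records\n")
  },
  associate = {
    g <- read.csv(get_arg("--grades"), stringsAsFactors = FALSE)
    a <- run_association_suite(g)
    write.csv(a, file.path(out, "associations.csv"), row.names = FALSE)
    s <- run_sensitivity_restricted_reference(g)
    write.csv(s, file.path(out, "sensitivity_restricted.csv"),
              row.names = FALSE)
    pa <- run_pain_attenuation(g)
    write.csv(pa, file.path(out, "pain_attenuation.csv"), row.names = FALSE)
    cat("wrote", nrow(a), "association cells\n")
  },
  table1 = {
    g <- read.csv(get_arg("--grades"), stringsAsFactors = FALSE)
    write.csv(prevalence_table(g), file.path(out, "table1.csv"),
              row.names = FALSE)
    cat("wrote descriptive table\n")
  },
  repeatability = {
    a <- read.csv(get_arg("--measures"), stringsAsFactors = FALSE)
    b <- read.csv(get_arg("--measures2"), stringsAsFactors = FALSE)
    r <- repeatability_report(a, b)
    write.csv(r, file.path(out, "repeatability.csv"), row.names = FALSE)
    print(r)
  },
  stop("unknown command: ", cmd)
)
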