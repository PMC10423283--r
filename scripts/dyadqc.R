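#!/usr/bin/env Rscript

# Thin command-line front end over the dyadqc package.
#
#   Rscript scripts/dyadqc.R <command> [--key value ...]
#
# Commands:
#   simulate      --out DIR [--seed N] [--n-images N --n-days N
#                 --raters-per-day N --images-per-session N]
#   select-subset --annotations CSV --out CSV [--quota N]
#   validate-ap   --annotations CSV --controls CSV --out-retained CSV
#                 --out-audit CSV [--pass-threshold N] [--n-controls N]
#   kappa         --annotations CSV --out CSV
#   filter-re     --votes CSV --out CSV [--z-threshold X]
#   run-all       --out DIR [--seed N] [--quota N]
#
# Results go to the named files; progress and timing go to standard error.

suppressPackageStartupMessages(library(dyadqc))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) == 0L) stop("no command given; see the header of this script")
cmd <- argv[1L]
argv <- argv[-1L]

opt <- function(flag, default = NULL) {
  i <- match(flag, argv)
  if (is.na(i) || i == length(argv)) {
    if (is.null(default)) stop("missing required argument: ", flag)
    return(default)
  }
  argv[i + 1L]
}
num <- function(flag, default) as.numeric(opt(flag, as.character(default)))
int <- function(flag, default) as.integer(opt(flag, as.character(default)))
say <- function(...) message("[dyadqc] ", ...)

t0 <- Sys.time()
switch(cmd,
  "simulate" = {
    out <- opt("--out")
    cfg <- sim_config(
      n_images = int("--n-images", 1120L),
      n_days = int("--n-days", 20L),
      raters_per_day = int("--raters-per-day", 28L),
      images_per_session = int("--images-per-session", 56L),
      p_true = num("--p-true", 0.8),
      p_adjacent = num("--p-adjacent", 0.10),
      p_opposite = num("--p-opposite", 0.05),
      inattentive_rate = num("--inattentive-rate", 0.10),
      p_control_correct = num("--p-control-correct", 0.95),
      seed = int("--seed", 1L)
    )
    sim <- simulate_annotations(cfg)
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_csv_table(sim$annotations, file.path(out, "annotations.csv"))
    write_csv_table(sim$controls, file.path(out, "controls.csv"))
    write_csv_table(sim$truth, file.path(out, "truth.csv"))
    say("wrote annotations/controls/truth to ", out)
  },
  "select-subset" = {
    tab <- read_annotations(opt("--annotations"), original = TRUE)
    sel <- select_balanced_subset(tab, quota = int("--quota", 140L))
    write_csv_table(sel, opt("--out"))
    say(nrow(sel), " images selected")
  },
  "validate-ap" = {
    rec <- read_annotations(opt("--annotations"))
    ctl <- read_controls(opt("--controls"))
    ap <- apply_ap(rec, ctl,
                   pass_threshold = int("--pass-threshold", 5L),
                   n_controls = int("--n-controls", 6L))
    write_csv_table(ap$retained, opt("--out-retained"))
    write_csv_table(ap$audit, opt("--out-audit"))
    say(sum(ap$audit$valid), "/", nrow(ap$audit), " sessions valid")
  },
  "kappa" = {
    rec <- read_annotations(opt("--annotations"))
    kt <- kappa_table(tally_votes(rec))
    write_csv_table(kt, opt("--out"))
    say(sprintf("mean kappa %.4f over %d images", mean_kappa(kt), nrow(kt)))
  },
  "filter-re" = {
    votes <- data.table::fread(opt("--votes"), data.table = FALSE,
                               colClasses = list(character = "image_id"))
    st <- run_re_stage(votes, z_threshold = num("--z-threshold", 0))
    write_csv_table(st$results, opt("--out"))
    say(sprintf("mean kappa %.4f -> %.4f",
                mean(st$results$kappa_pre), mean(st$results$kappa_post)))
  },
  "run-all" = {
    seed <- int("--seed", 1L)
    cfg <- pipeline_config(quota = int("--quota", 140L),
                           sim = sim_config(seed = seed), seed = seed)
    run_pipeline(cfg, opt("--out"))
  },
  stop("unknown command: ", cmd)
)
say(sprintf("%s finished in %.1f s", cmd,
            as.numeric(difftime(Sys.time(), t0, units = "secs"))))
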