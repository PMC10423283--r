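# End-to-end orchestration: simulate (or read) -> balanced subset ->
# AP session validation -> per-image kappa -> RE filter -> report, with a
# manifest recording configuration, seed and per-stage row counts. All
# tabular I/O is plain UTF-8 CSV with a mandatory header.

#' Read / write the pipeline's CSV dialects
#'
#' Thin wrappers over [data.table::fread()] / [data.table::fwrite()] that
#' validate the expected header. `read_annotations` covers both the
#' dyad-vote records (`image_id,annotator_id,day,dyad_id`) and, with
#' `original = TRUE`, the 26-word original tables
#' (`image_id,annotator_id,emotion_word`).
#'
#' @param path CSV file path.
#' @param original read an original 26-word table instead of dyad records.
#' @return data.frame.
#' @export
read_annotations <- function(path, original = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- data.table::fread(path, colClasses = list(character = "image_id"))
  req <- if (original) c("image_id", "annotator_id", "emotion_word")
         else c("image_id", "annotator_id", "day", "dyad_id")
  if (!all(req %in% names(df))) {
    stop(path, ": expected header ", paste(req, collapse = ","))
  }
  data.table::setDF(df)
  df
}

#' @rdname read_annotations
#' @export
read_controls <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- data.table::fread(path, colClasses = list(character = "image_id"))
  if (!all(c("image_id", "expected_dyad") %in% names(df))) {
    stop(path, ": expected header image_id,expected_dyad")
  }
  data.table::setDF(df)
  df
}

#' @rdname read_annotations
#' @param x data.frame to write.
#' @export
write_csv_table <- function(x, path) {
  drop <- vapply(x, is.list, logical(1))
  data.table::fwrite(x[, !drop, drop = FALSE], path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the stage parameters with the campaign constants: subset quota
#' (140 per dyad), control-selection threshold (4 coinciding pilot votes),
#' session pass threshold (5 of 6 controls) and Z cut-off (0).
#'
#' @param quota images per dyad for the balanced subset.
#' @param min_coincidence pilot votes required to fix a control image.
#' @param pass_threshold correct controls required for a valid session.
#' @param n_controls controls per session.
#' @param z_threshold Z-score cut-off of the RE filter.
#' @param sim a [sim_config()] for the simulated campaign.
#' @param original_sim parameters for [simulate_original_annotations()]
#'   (list with `n_images`, `raters_per_image`, `p_dominant`).
#' @param seed master seed (propagated to both simulators).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(quota = 140L, min_coincidence = 4L,
                            pass_threshold = 5L, n_controls = 6L,
                            z_threshold = 0,
                            sim = sim_config(seed = seed),
                            original_sim = list(n_images = 8L * (quota + 20L),
                                                raters_per_image = 10L,
                                                p_dominant = 0.7),
                            seed = 1L) {
  structure(list(
    quota = as.integer(quota),
    min_coincidence = as.integer(min_coincidence),
    pass_threshold = as.integer(pass_threshold),
    n_controls = as.integer(n_controls),
    z_threshold = z_threshold,
    sim = sim, original_sim = original_sim,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full pipeline on a simulated campaign
#'
#' Executes all stages in order and writes every stage output plus a JSON
#' manifest to `out_dir`: original annotations and the balanced subset,
#' the simulated dyad annotations with controls and ground truth, the AP
#' audit and retained records, the per-image kappa table, the RE results
#' and summary, and recovery metrics against the simulated truth. The
#' manifest records the configuration, seed, row counts per stage and the
#' vote-conservation checks (retained votes = 56 per valid session;
#' post-RE votes = sum of kept counts).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param quiet suppress progress messages on standard error.
#' @return (invisibly) a list with all in-memory stage outputs and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[dyadqc] ", ...)
  t0 <- Sys.time()

  say("stage 1/5: original annotations + balanced subset selection")
  orig <- simulate_original_annotations(
    n_images = config$original_sim$n_images,
    raters_per_image = config$original_sim$raters_per_image,
    p_dominant = config$original_sim$p_dominant,
    seed = config$seed
  )
  subset <- select_balanced_subset(orig, quota = config$quota)
  write_csv_table(orig, file.path(out_dir, "original_annotations.csv"))
  write_csv_table(subset, file.path(out_dir, "subset.csv"))

  say("stage 2/5: simulated dyad annotation campaign")
  sim <- simulate_annotations(config$sim)
  write_csv_table(sim$annotations, file.path(out_dir, "annotations.csv"))
  write_csv_table(sim$controls, file.path(out_dir, "controls.csv"))
  write_csv_table(sim$truth, file.path(out_dir, "truth.csv"))

  say("stage 3/5: attentiveness-promotion session validation")
  ap <- apply_ap(sim$annotations, sim$controls,
                 pass_threshold = config$pass_threshold,
                 n_controls = config$n_controls)
  write_csv_table(ap$retained, file.path(out_dir, "ap_retained.csv"))
  write_csv_table(ap$audit, file.path(out_dir, "ap_audit.csv"))
  n_valid <- sum(ap$audit$valid)
  expected_votes <- n_valid * config$sim$images_per_session
  if (nrow(ap$retained) != expected_votes) {
    stop("vote conservation violated after AP: ", nrow(ap$retained),
         " retained votes, expected ", expected_votes)
  }

  say("stage 4/5: per-image agreement")
  votes <- tally_votes(ap$retained)
  kap <- kappa_table(votes)
  write_csv_table(kap, file.path(out_dir, "per_image_kappa.csv"))

  say("stage 5/5: reliability-enhancement filter")
  re <- run_re_stage(votes, z_threshold = config$z_threshold)
  post_votes <- sum(unlist(re$results[paste0("counts_post_", 1:8)]))
  write_csv_table(re$results, file.path(out_dir, "re_results.csv"))
  write_csv_table(re$summary, file.path(out_dir, "re_summary.csv"))
  write_csv_table(summarize_agreement(kap, by = "band"),
                  file.path(out_dir, "summary_band_ap.csv"))
  recov <- recovery_report(re$results, sim$truth)

  manifest <- list(
    package = "dyadqc",
    version = as.character(utils::packageVersion("dyadqc")),
    seed = config$seed,
    config = config[c("quota", "min_coincidence", "pass_threshold",
                      "n_controls", "z_threshold")],
    sim = unclass(config$sim),
    rows = list(
      original_annotations = nrow(orig),
      subset = nrow(subset),
      annotations = nrow(sim$annotations),
      sessions = nrow(ap$audit),
      valid_sessions = n_valid,
      ap_retained = nrow(ap$retained),
      images_scored = nrow(kap)
    ),
    vote_conservation = list(
      retained_after_ap = nrow(ap$retained),
      expected_after_ap = expected_votes,
      total_after_re = post_votes
    ),
    recovery = recov,
    mean_kappa_ap = mean_kappa(kap),
    mean_kappa_re = mean(re$results$kappa_post),
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say(sprintf("done: mean kappa %.3f (AP) -> %.3f (RE), %d/%d sessions valid",
              manifest$mean_kappa_ap, manifest$mean_kappa_re,
              n_valid, nrow(ap$audit)))
  invisible(list(original = orig, subset = subset, sim = sim, ap = ap,
                 votes = votes, kappa = kap, re = re, recovery = recov,
                 manifest = manifest))
}
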