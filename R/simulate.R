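# Synthetic annotation campaigns. The generator emulates the structure the
# analysis assumes: images are partitioned into daily batches, every rater
# attending a day annotates that day's full batch once plus one repeated
# image, six images of each batch are known-answer controls, and votes come
# from a wheel-distance mixture around each image's true dyad. A fraction
# of rater-sessions is inattentive and votes uniformly at random on every
# presentation (controls and both copies of the repeated image included).

#' Configuration for a simulated annotation campaign
#'
#' Defaults mirror the study scale the pipeline was designed around:
#' 1,120 images annotated over 20 days, 28 raters per day, 56 images per
#' session (6 of them controls) plus one repeated presentation. Attentive
#' raters vote the image's true dyad with probability `p_true`, a
#' wheel-adjacent dyad with `p_adjacent` (split equally between the two
#' neighbours), the wheel-opposite dyad with `p_opposite` (the projection
#' effect), and the remaining four dyads uniformly with the residual mass.
#'
#' @param n_images total images; must equal `n_days * images_per_session`.
#' @param n_days number of annotation days (one batch of images per day).
#' @param raters_per_day raters attending each day.
#' @param images_per_session distinct images shown per session.
#' @param controls_per_session control images per daily batch.
#' @param p_true probability an attentive rater votes the true dyad.
#' @param p_adjacent probability mass on the two wheel-distance-1 dyads.
#' @param p_opposite probability mass on the wheel-opposite dyad.
#' @param inattentive_rate fraction of rater-sessions voting uniformly.
#' @param p_control_correct probability an attentive rater answers a
#'   control with its expected dyad.
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_images = 1120L, n_days = 20L, raters_per_day = 28L,
                       images_per_session = 56L, controls_per_session = 6L,
                       p_true = 0.8, p_adjacent = 0.10, p_opposite = 0.05,
                       inattentive_rate = 0.10, p_control_correct = 0.95,
                       seed = 1L) {
  cfg <- list(
    n_images = as.integer(n_images), n_days = as.integer(n_days),
    raters_per_day = as.integer(raters_per_day),
    images_per_session = as.integer(images_per_session),
    controls_per_session = as.integer(controls_per_session),
    p_true = p_true, p_adjacent = p_adjacent, p_opposite = p_opposite,
    inattentive_rate = inattentive_rate,
    p_control_correct = p_control_correct,
    seed = as.integer(seed)
  )
  probs <- c(p_true, p_adjacent, p_opposite, inattentive_rate, p_control_correct)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p_true + p_adjacent + p_opposite > 1 + 1e-12) {
    stop("p_true + p_adjacent + p_opposite must not exceed 1")
  }
  if (cfg$n_images != cfg$n_days * cfg$images_per_session) {
    stop("n_images must equal n_days * images_per_session (one batch per day)")
  }
  if (cfg$images_per_session < cfg$controls_per_session + 1L) {
    stop("images_per_session must exceed controls_per_session ",
         "(the repeated image is drawn from the non-control images)")
  }
  if (cfg$n_days < 1L || cfg$raters_per_day < 1L) {
    stop("need at least one day and one rater per day")
  }
  structure(cfg, class = "sim_config")
}

# wheel-geometry lookups indexed by true dyad id
.wheel_lookups <- function(catalog = dyad_catalog()) {
  nb <- t(vapply(1:8, function(d) which(wheel_distance(d, 1:8, catalog) == 1L),
                 integer(2)))
  far <- t(vapply(1:8, function(d) which(wheel_distance(d, 1:8, catalog) %in% c(2L, 3L)),
                  integer(4)))
  opp <- opposite_dyad(1:8, catalog)
  oth <- t(vapply(1:8, function(d) setdiff(1:8, d), integer(7)))
  list(nb = nb, far = far, opp = opp, oth = oth)
}

#' Simulate an annotation campaign
#'
#' Generates ground truth, daily batches with embedded control images, and
#' one session per rater-day built per the session contract: every batch
#' image presented once, one non-control image presented a second time, in
#' randomised order. Attentive raters vote each distinct image once from
#' the wheel-distance mixture (so their repeated presentation is
#' consistent by construction) and answer controls correctly with
#' probability `p_control_correct`; inattentive rater-sessions draw every
#' presentation independently and uniformly over the 8 dyads.
#'
#' @param config a [sim_config()].
#' @param catalog a [dyad_catalog()].
#' @return list with
#'   \describe{
#'     \item{annotations}{records `image_id`, `annotator_id`, `day`,
#'       `dyad_id` in presentation order within each session.}
#'     \item{controls}{`image_id`, `expected_dyad` (the true dyad).}
#'     \item{truth}{`image_id`, `true_dyad` for every simulated image.}
#'     \item{sessions}{`annotator_id`, `day`, `attentive` -- the latent
#'       attentiveness of each rater-session, for diagnostics.}
#'   }
#' @export
simulate_annotations <- function(config, catalog = dyad_catalog()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ni <- config$n_images; nd <- config$n_days; rp <- config$raters_per_day
  ips <- config$images_per_session; ncpd <- config$controls_per_session

  image_id <- sprintf("img%06d", seq_len(ni))
  true_dyad <- sample(rep_len(1:8, ni))
  day_of_image <- rep(seq_len(nd), each = ips)
  is_control <- logical(ni)
  for (d in seq_len(nd)) {
    idx <- which(day_of_image == d)
    is_control[sample(idx, ncpd)] <- TRUE
  }
  truth <- data.frame(image_id = image_id, true_dyad = true_dyad)
  controls <- data.frame(image_id = image_id[is_control],
                         expected_dyad = true_dyad[is_control])

  sess <- data.table::data.table(
    day = rep(seq_len(nd), each = rp),
    rater = rep(seq_len(rp), times = nd)
  )
  sess[, annotator_id := sprintf("d%03d_r%03d", day, rater)]
  sess[, attentive := stats::runif(.N) >= config$inattentive_rate]
  sess[, sid := .I]

  img_dt <- data.table::data.table(
    image_id = image_id, true_dyad = true_dyad,
    day = day_of_image, is_control = is_control
  )
  pres <- sess[img_dt, on = "day", allow.cartesian = TRUE]

  lk <- .wheel_lookups(catalog)
  nrows <- nrow(pres)
  u <- stats::runif(nrows)
  r2 <- stats::runif(nrows)
  vote <- integer(nrows)
  td <- pres$true_dyad
  att <- pres$attentive
  ic <- pres$is_control

  # attentive, regular image: wheel-distance mixture
  i <- which(att & !ic)
  if (length(i) > 0L) {
    edges <- cumsum(c(config$p_true, config$p_adjacent, config$p_opposite))
    lev <- findInterval(u[i], edges) # 0 true, 1 adjacent, 2 opposite, 3 far
    tdi <- td[i]
    v <- integer(length(i))
    v[lev == 0L] <- tdi[lev == 0L]
    a1 <- lev == 1L
    v[a1] <- lk$nb[cbind(tdi[a1], 1L + (r2[i][a1] >= 0.5))]
    o1 <- lev == 2L
    v[o1] <- lk$opp[tdi[o1]]
    f1 <- lev == 3L
    v[f1] <- lk$far[cbind(tdi[f1], ceiling(r2[i][f1] * 4))]
    vote[i] <- v
  }
  # attentive, control image
  j <- which(att & ic)
  if (length(j) > 0L) {
    tdj <- td[j]
    correct <- u[j] < config$p_control_correct
    v <- integer(length(j))
    v[correct] <- tdj[correct]
    v[!correct] <- lk$oth[cbind(tdj[!correct], ceiling(r2[j][!correct] * 7))]
    vote[j] <- v
  }
  # inattentive: uniform everywhere
  k <- which(!att)
  if (length(k) > 0L) vote[k] <- sample.int(8L, length(k), replace = TRUE)
  pres[, dyad_id := vote]

  # repeated presentation: one non-control image per session
  noncon <- img_dt[is_control == FALSE]
  dup_pick <- noncon[, .(image_id = image_id[sample.int(.N, rp, replace = TRUE)]),
                     by = day]
  dup_pick[, sid := sess$sid] # same (day, rater) order as sess by construction
  dup <- pres[dup_pick, on = c("sid", "image_id")]
  # attentive raters repeat their vote; inattentive redraw uniformly
  redraw <- which(!dup$attentive)
  if (length(redraw) > 0L) {
    dup$dyad_id[redraw] <- sample.int(8L, length(redraw), replace = TRUE)
  }
  all_pres <- rbind(pres, dup, fill = TRUE)
  all_pres[, ord := stats::runif(.N)]
  data.table::setorder(all_pres, sid, ord)

  annotations <- all_pres[, .(image_id, annotator_id, day, dyad_id)]
  data.table::setDF(annotations)
  sessions <- sess[, .(annotator_id, day, attentive)]
  data.table::setDF(sessions)
  list(annotations = annotations, controls = controls,
       truth = truth, sessions = sessions)
}

#' Simulate an original 26-word annotation table
#'
#' Emulates EMOTIC-style first-pass labels for exercising the balanced
#' subset selection: each image has a dominant dyad (balanced over the 8),
#' each rater votes a word from the dominant dyad with probability
#' `p_dominant` and otherwise a word from a uniformly drawn other dyad;
#' within a dyad the word is drawn uniformly from its vocabulary.
#'
#' @param n_images number of images (dominant dyads balanced over 8).
#' @param raters_per_image original votes per image.
#' @param p_dominant probability a vote falls in the dominant dyad.
#' @param seed integer seed.
#' @param catalog a [dyad_catalog()].
#' @return data.frame `image_id`, `annotator_id`, `emotion_word`.
#' @export
simulate_original_annotations <- function(n_images = 1280L,
                                          raters_per_image = 10L,
                                          p_dominant = 0.7,
                                          seed = 1L,
                                          catalog = dyad_catalog()) {
  stopifnot(n_images >= 1L, raters_per_image >= 1L,
            p_dominant >= 0, p_dominant <= 1)
  set.seed(seed)
  image_id <- sprintf("orig%06d", seq_len(n_images))
  dominant <- sample(rep_len(1:8, n_images))
  nrec <- n_images * raters_per_image
  img_idx <- rep(seq_len(n_images), each = raters_per_image)
  hit <- stats::runif(nrec) < p_dominant
  oth <- t(vapply(1:8, function(d) setdiff(1:8, d), integer(7)))
  dyad <- integer(nrec)
  dyad[hit] <- dominant[img_idx[hit]]
  nmiss <- sum(!hit)
  dyad[!hit] <- oth[cbind(dominant[img_idx[!hit]],
                          sample.int(7L, nmiss, replace = TRUE))]
  words_by_dyad <- split(names(catalog$emotic_map), catalog$emotic_map)
  word <- vapply(dyad, function(d) {
    w <- words_by_dyad[[as.character(d)]]
    w[sample.int(length(w), 1L)]
  }, character(1))
  # restore canonical capitalisation for output readability
  canon <- names(jsonlite::fromJSON(system.file("extdata", "dyad_catalog.json",
                                                package = "dyadqc"))$emotic_map)
  word <- canon[match(word, tolower(canon))]
  data.frame(
    image_id = image_id[img_idx],
    annotator_id = sprintf("r%02d", rep(seq_len(raters_per_image), n_images)),
    emotion_word = word
  )
}

#' Recovery metrics of the RE filter against simulated ground truth
#'
#' @param re_results the `results` data.frame of [run_re_stage()].
#' @param truth ground-truth table (`image_id`, `true_dyad`).
#' @return list with `n_images`, `frac_true_kept` (fraction of images
#'   whose surviving dyads include the true dyad), `frac_true_unique`
#'   (true dyad is the only survivor), `mean_kappa_pre`, `mean_kappa_post`.
#' @export
recovery_report <- function(re_results, truth) {
  if (nrow(re_results) == 0L) stop("empty filter results")
  if (!all(c("image_id", "true_dyad") %in% names(truth))) {
    stop("truth table needs columns: image_id, true_dyad")
  }
  idx <- match(re_results$image_id, truth$image_id)
  if (anyNA(idx)) {
    stop("image(s) missing from ground truth: ",
         paste(utils::head(re_results$image_id[is.na(idx)], 5L), collapse = ", "))
  }
  true_dyad <- truth$true_dyad[idx]
  kept <- re_results$kept
  in_kept <- mapply(function(k, t) t %in% k, kept, true_dyad)
  unique_kept <- mapply(function(k, t) length(k) == 1L && k == t, kept, true_dyad)
  list(
    n_images = nrow(re_results),
    frac_true_kept = mean(in_kept),
    frac_true_unique = mean(unique_kept),
    mean_kappa_pre = mean(re_results$kappa_pre),
    mean_kappa_post = mean(re_results$kappa_post)
  )
}
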