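# Per-image Fleiss-style kappa over the 8 dyads. Observed agreement for an
# image with counts c_1..c_8 and n = sum(c) raters is the fraction of
# agreeing rater pairs,
#     P_obs = (sum_j c_j^2 - n) / (n (n - 1)),
# and chance agreement is uniform over the K = 8 categories,
#     kappa = (P_obs - 1/8) / (1 - 1/8),
# so kappa ranges over [-1/7, 1]. The uniform-chance convention (rather
# than marginal-based chance) is the one under which a single image's
# kappa is well defined; it treats all eight dyads as equally likely a
# priori.

.K_DYADS <- 8L
.P_CHANCE <- 1 / 8

.kappa_closed_form <- function(counts_mat) {
  n <- rowSums(counts_mat)
  p_obs <- (rowSums(counts_mat^2) - n) / (n * (n - 1))
  kappa <- (p_obs - .P_CHANCE) / (1 - .P_CHANCE)
  list(n = n, p_obs = p_obs, kappa = kappa)
}

#' Per-image agreement coefficient
#'
#' Computes observed pairwise agreement and the chance-corrected kappa for
#' one image's vote-count vector over the eight dyads, with uniform chance
#' agreement 1/8.
#'
#' @param counts nonnegative integer vector of length 8 (votes per dyad).
#' @return list with `n` (raters), `p_obs`, `kappa`, `band`
#'   (Landis-Koch category, see [kappa_band()]) and `n_labels` (number of
#'   dyads with at least one vote).
#' @export
#' @examples
#' per_image_kappa(c(1, 1, 1, 0, 23, 0, 3, 1)) # kappa 0.53 at 2 d.p.
per_image_kappa <- function(counts) {
  stopifnot(length(counts) == .K_DYADS, all(counts >= 0),
            all(counts == round(counts)))
  n <- sum(counts)
  if (n < 2) {
    stop("agreement is undefined for fewer than 2 raters (n = ", n, ")")
  }
  cf <- .kappa_closed_form(matrix(counts, nrow = 1L))
  list(
    n = as.integer(n),
    p_obs = cf$p_obs,
    kappa = cf$kappa,
    band = as.character(kappa_band(cf$kappa)),
    n_labels = as.integer(sum(counts > 0))
  )
}

#' Landis-Koch qualitative band for a kappa value
#'
#' Bands follow the Landis-Koch convention: Poor (kappa < 0),
#' Slight (0 to 0.2), Fair (above 0.2 to 0.4), Moderate (above 0.4 to 0.6),
#' Substantial (above 0.6, below 0.8), Almost Perfect (0.8 and above).
#'
#' @param kappa numeric vector in \[-1/7, 1\].
#' @return factor with levels Poor, Slight, Fair, Moderate, Substantial,
#'   Almost Perfect.
#' @export
kappa_band <- function(kappa) {
  stopifnot(all(kappa >= -1 / 7 - 1e-9), all(kappa <= 1 + 1e-9))
  labs <- c("Poor", "Slight", "Fair", "Moderate", "Substantial", "Almost Perfect")
  idx <- ifelse(kappa < 0, 1L,
         ifelse(kappa <= 0.2, 2L,
         ifelse(kappa <= 0.4, 3L,
         ifelse(kappa <= 0.6, 4L,
         ifelse(kappa < 0.8, 5L, 6L)))))
  factor(labs[idx], levels = labs)
}

#' Tally an annotation table into per-image vote vectors
#'
#' @param records annotation table (`image_id`, `annotator_id`, `day`,
#'   `dyad_id`), typically the AP-retained records.
#' @return data.frame with `image_id`, `n` and `counts_1` .. `counts_8`.
#' @export
tally_votes <- function(records) {
  .check_annotation_records(records)
  dt <- data.table::as.data.table(records)
  if (nrow(dt) == 0L) {
    out <- data.frame(image_id = character(0), n = integer(0))
    out[paste0("counts_", 1:8)] <- lapply(1:8, function(i) integer(0))
    return(out)
  }
  tal <- dt[, as.list(stats::setNames(tabulate(dyad_id, nbins = 8L),
                                      paste0("counts_", 1:8))),
            by = image_id]
  tal[, n := as.integer(rowSums(.SD)), .SDcols = paste0("counts_", 1:8)]
  data.table::setcolorder(tal, c("image_id", "n", paste0("counts_", 1:8)))
  data.table::setorder(tal, image_id)
  data.table::setDF(tal)
  tal
}

.counts_matrix <- function(votes) {
  cols <- paste0("counts_", 1:8)
  if (!all(cols %in% names(votes))) {
    stop("vote table needs columns counts_1 .. counts_8")
  }
  m <- as.matrix(votes[, cols])
  dimnames(m) <- NULL
  m
}

#' Kappa table for a set of images
#'
#' Vectorised [per_image_kappa()] over a vote table as produced by
#' [tally_votes()].
#'
#' @param votes data.frame with `image_id` and `counts_1` .. `counts_8`.
#' @return data.frame `image_id`, `n`, `counts_1..8`, `p_obs`, `kappa`,
#'   `band`, `n_labels`, one row per image.
#' @export
kappa_table <- function(votes) {
  m <- .counts_matrix(votes)
  n <- rowSums(m)
  if (any(n < 2)) {
    stop("agreement is undefined for fewer than 2 raters; offending image(s): ",
         paste(utils::head(votes$image_id[n < 2], 5L), collapse = ", "))
  }
  cf <- .kappa_closed_form(m)
  out <- data.frame(image_id = votes$image_id, n = as.integer(n))
  out[paste0("counts_", 1:8)] <- as.data.frame(m)
  out$p_obs <- cf$p_obs
  out$kappa <- cf$kappa
  out$band <- as.character(kappa_band(cf$kappa))
  out$n_labels <- as.integer(rowSums(m > 0))
  out
}

#' Mean of per-image kappas
#'
#' The aggregate agreement figure is the unweighted arithmetic mean of the
#' per-image kappas (rater counts vary by image, so a pooled multi-rater
#' kappa is not defined here).
#'
#' @param results a [kappa_table()] data.frame, or a numeric vector of
#'   kappas.
#' @return scalar mean kappa.
#' @export
mean_kappa <- function(results) {
  k <- if (is.data.frame(results)) results$kappa else results
  if (length(k) == 0L) stop("cannot average an empty set of kappas")
  mean(k)
}

#' Summaries of a kappa table
#'
#' Groups images and reports, per group, the number of images, the mean
#' number of raters and the mean kappa.
#'
#' @param results a [kappa_table()] data.frame.
#' @param by grouping key: `"band"` (Landis-Koch category), `"n_labels"`
#'   (number of voted dyads), `"n_raters"`, or `"modal_dyad"` (most-voted
#'   dyad, ties to the lowest id).
#' @return data.frame with the grouping column, `n_images`,
#'   `mean_n_raters` and `mean_kappa`.
#' @export
summarize_agreement <- function(results,
                                by = c("band", "n_labels", "n_raters", "modal_dyad")) {
  by <- match.arg(by)
  if (nrow(results) == 0L) stop("empty kappa table")
  m <- .counts_matrix(results)
  key <- switch(by,
    band = factor(results$band,
                  levels = levels(kappa_band(0))),
    n_labels = results$n_labels,
    n_raters = results$n,
    modal_dyad = apply(m, 1L, which.max)
  )
  dt <- data.table::data.table(
    grp = key, n = results$n, kappa = results$kappa
  )
  out <- dt[, .(n_images = .N, mean_n_raters = mean(n), mean_kappa = mean(kappa)),
            by = grp]
  data.table::setorder(out, grp)
  data.table::setnames(out, "grp", by)
  data.table::setDF(out)
  out
}
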