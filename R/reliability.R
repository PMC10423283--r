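# Reliability enhancement (RE): per-image Z-score filter of the vote
# vector. Each of the 8 counts X is standardised against the mean mu and
# standard deviation sigma of the full 8-vector (zeros included,
# population sigma), Z = (X - mu) / sigma, and only dyads with Z >= 0 are
# kept -- equivalently, counts at or above the per-image mean. Votes on
# discarded dyads are removed (their raters dropped), and kappa is
# recomputed on the surviving counts with K = 8 and uniform chance 1/8
# unchanged.

#' Z-scores of a per-image vote vector
#'
#' @param counts nonnegative integer vector of length 8.
#' @return list with `mu` (mean of the 8 counts), `sigma` (population
#'   standard deviation, i.e. divisor 8) and `z` (length-8 vector; all
#'   zero when `sigma` is zero).
#' @export
#' @examples
#' z_scores(c(1, 1, 1, 0, 23, 0, 3, 1))
z_scores <- function(counts) {
  stopifnot(length(counts) == .K_DYADS, all(counts >= 0))
  mu <- mean(counts)
  sigma <- sqrt(mean((counts - mu)^2))
  z <- if (sigma > 0) (counts - mu) / sigma else rep(0, .K_DYADS)
  list(mu = mu, sigma = sigma, z = z)
}

# kept set for a counts matrix at a Z threshold; for the default threshold
# 0 this reduces to counts >= row mean (sigma rescales but never flips the
# sign of Z)
.re_kept_matrix <- function(m, z_threshold = 0) {
  mu <- rowMeans(m)
  if (z_threshold == 0) {
    m >= mu
  } else {
    sigma <- sqrt(rowMeans((m - mu)^2))
    z <- (m - mu) / ifelse(sigma > 0, sigma, 1)
    z[sigma == 0, ] <- 0
    z >= z_threshold
  }
}

#' Apply the Z-score reliability filter to one image
#'
#' Keeps the dyads whose vote count standardises to `Z >= z_threshold`
#' (default 0: counts at or above the per-image mean), zeroes the rest,
#' and recomputes kappa on the surviving votes.
#'
#' @param counts nonnegative integer vector of length 8 with at least 2
#'   votes in total.
#' @param z_threshold Z cut-off; the campaign's rule is 0.
#' @return list with `kept_dyads` (integer vector of surviving dyad ids),
#'   `filtered_counts` (length-8, discarded dyads zeroed), `kappa_pre` and
#'   `kappa_post` ([per_image_kappa()] results before and after).
#' @export
#' @examples
#' apply_re(c(1, 1, 1, 0, 23, 0, 3, 1)) # keeps Joy/Affection only
apply_re <- function(counts, z_threshold = 0) {
  kappa_pre <- per_image_kappa(counts)
  kept <- which(.re_kept_matrix(matrix(counts, nrow = 1L), z_threshold)[1L, ])
  filtered <- counts
  filtered[-kept] <- 0
  if (sum(filtered) < 2) {
    stop("post-filter agreement undefined: fewer than 2 surviving votes")
  }
  list(
    kept_dyads = as.integer(kept),
    filtered_counts = filtered,
    kappa_pre = kappa_pre,
    kappa_post = per_image_kappa(filtered)
  )
}

#' Run the RE stage over a vote table
#'
#' Applies the Z-score filter image by image and reports per-image results
#' together with a before/after summary of Landis-Koch band counts, label
#' counts and mean kappa.
#'
#' @param votes vote table (`image_id`, `counts_1..8`) as from
#'   [tally_votes()]; typically the AP-retained tallies.
#' @param z_threshold Z cut-off (default 0).
#' @return list with
#'   \describe{
#'     \item{results}{data.frame `image_id`, `kept_dyads`
#'       (";"-joined ids), `kept` (list column of integer vectors),
#'       `counts_post_1..8`, `kappa_pre`, `kappa_post`, `band_pre`,
#'       `band_post`, `n_labels_pre`, `n_labels_post`.}
#'     \item{summary}{data.frame of band counts before/after plus rows for
#'       mean kappa and mean label count.}
#'   }
#' @export
run_re_stage <- function(votes, z_threshold = 0) {
  if (nrow(votes) == 0L) {
    empty <- data.frame(image_id = character(0), kept_dyads = character(0))
    return(list(results = empty, summary = data.frame()))
  }
  m <- .counts_matrix(votes)
  pre <- kappa_table(votes)
  keep <- .re_kept_matrix(m, z_threshold)
  post_m <- m * keep
  cf <- .kappa_closed_form(post_m)
  kept_list <- lapply(seq_len(nrow(keep)), function(i) which(keep[i, ]))

  res <- data.frame(
    image_id = votes$image_id,
    kept_dyads = vapply(kept_list, paste, character(1), collapse = ";")
  )
  res$kept <- kept_list
  res[paste0("counts_post_", 1:8)] <- as.data.frame(post_m)
  res$kappa_pre <- pre$kappa
  res$kappa_post <- cf$kappa
  res$band_pre <- pre$band
  res$band_post <- as.character(kappa_band(cf$kappa))
  res$n_labels_pre <- pre$n_labels
  res$n_labels_post <- as.integer(rowSums(post_m > 0))

  bands <- levels(kappa_band(0))
  summary <- data.frame(
    statistic = c(paste0("images_", gsub(" ", "_", bands)),
                  "mean_kappa", "mean_n_labels"),
    before = c(as.vector(table(factor(res$band_pre, levels = bands))),
               mean(res$kappa_pre), mean(res$n_labels_pre)),
    after = c(as.vector(table(factor(res$band_post, levels = bands))),
              mean(res$kappa_post), mean(res$n_labels_post))
  )
  list(results = res, summary = summary)
}
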