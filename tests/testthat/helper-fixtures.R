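# Shared fixtures: an exhaustive pair-counting oracle for the agreement
# statistic and a builder for well-formed annotation sessions.

# Independent oracle: expand the vote vector into individual rater labels
# and count agreeing rater pairs exhaustively.
pair_count_kappa <- function(counts) {
  labels <- rep(1:8, counts)
  n <- length(labels)
  agree <- (sum(outer(labels, labels, "==")) - n) / 2
  p_obs <- agree / (n * (n - 1) / 2)
  list(p_obs = p_obs, kappa = (p_obs - 1 / 8) / (1 - 1 / 8))
}

# One session: six controls c1..c6, a few regular images r1.., and one
# duplicated image presented twice.
make_session <- function(annotator = "a1", day = 1L,
                         control_votes = rep(1L, 6L),
                         control_expected = rep(1L, 6L),
                         regular_votes = c(2L, 3L),
                         dup_votes = c(5L, 5L)) {
  stopifnot(length(control_votes) == 6L, length(dup_votes) == 2L)
  records <- data.frame(
    image_id = c(paste0("c", 1:6),
                 paste0("r", seq_along(regular_votes)),
                 "dup", "dup"),
    annotator_id = annotator,
    day = day,
    dyad_id = as.integer(c(control_votes, regular_votes, dup_votes))
  )
  controls <- data.frame(image_id = paste0("c", 1:6),
                         expected_dyad = as.integer(control_expected))
  list(records = records, controls = controls)
}

random_vote_matrix <- function(n_vectors, n_min = 15L, n_max = 35L) {
  t(vapply(seq_len(n_vectors), function(i) {
    n <- sample(n_min:n_max, 1L)
    p <- stats::rgamma(8, shape = stats::runif(1, 0.2, 2))
    as.integer(stats::rmultinom(1, n, p / sum(p)))
  }, integer(8)))
}
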