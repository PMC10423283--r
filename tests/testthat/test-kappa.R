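test_that("per-image kappa matches the exhaustive pair-counting oracle on worked vectors", {
  # the two worked per-image vote vectors (dyad-aligned)
  left <- c(1, 1, 1, 0, 23, 0, 3, 1)
  right <- c(1, 13, 7, 0, 0, 0, 5, 2)
  for (counts in list(left, right)) {
    got <- per_image_kappa(counts)
    ref <- pair_count_kappa(counts)
    expect_equal(got$p_obs, ref$p_obs, tolerance = 1e-12)
    expect_equal(got$kappa, ref$kappa, tolerance = 1e-12)
  }
  expect_equal(round(per_image_kappa(left)$kappa, 2), 0.53)
  expect_equal(per_image_kappa(right)$kappa, 0.1897203, tolerance = 1e-6)
  expect_identical(per_image_kappa(left)$n_labels, 6L)
})

test_that("kappa attains its extremes: unanimity gives 1, uniform spread gives -1/7", {
  expect_equal(per_image_kappa(c(0, 0, 28, 0, 0, 0, 0, 0))$kappa, 1)
  expect_equal(per_image_kappa(rep(1, 8))$kappa, -1 / 7)
  # kappa = 1 iff a single dyad carries all votes
  expect_lt(per_image_kappa(c(27, 1, 0, 0, 0, 0, 0, 0))$kappa, 1)
  expect_error(per_image_kappa(c(1, 0, 0, 0, 0, 0, 0, 0)), "fewer than 2 raters")
})

test_that("kappa is invariant under permutation of the dyad indices", {
  set.seed(3)
  for (i in 1:25) {
    counts <- as.integer(rmultinom(1, sample(15:35, 1), rgamma(8, 0.8)))
    k0 <- per_image_kappa(counts)$kappa
    expect_equal(per_image_kappa(counts[sample(8)])$kappa, k0, tolerance = 1e-12)
  }
})

test_that("Landis-Koch banding places boundary kappas in their observed categories", {
  expect_identical(as.character(kappa_band(0.2)), "Slight")
  expect_identical(as.character(kappa_band(0.4)), "Fair")
  expect_identical(as.character(kappa_band(0.6)), "Moderate")
  expect_identical(as.character(kappa_band(0.7971)), "Substantial")
  expect_identical(as.character(kappa_band(0.8021)), "Almost Perfect")
  expect_identical(as.character(kappa_band(-0.0013)), "Poor")
  expect_identical(as.character(kappa_band(c(0, 0.0006, 0.2004, 0.4014, 0.6027, 0.8))),
                   c("Slight", "Slight", "Fair", "Moderate", "Substantial",
                     "Almost Perfect"))
})

test_that("mean kappa is the unweighted average and is bounded by the extremes", {
  expect_equal(mean_kappa(c(0, 1)), 0.5)
  expect_equal(mean_kappa(0.37), 0.37)
  set.seed(8)
  m <- random_vote_matrix(10)
  votes <- data.frame(image_id = sprintf("i%02d", 1:10))
  votes[paste0("counts_", 1:8)] <- as.data.frame(m)
  kt <- kappa_table(votes)
  expect_equal(mean_kappa(kt), sum(kt$kappa) / nrow(kt), tolerance = 1e-12)
  expect_gte(mean_kappa(kt), min(kt$kappa))
  expect_lte(mean_kappa(kt), max(kt$kappa))
  expect_error(mean_kappa(numeric(0)), "empty")
})

test_that("tally_votes reproduces hand counts and kappa_table matches per_image_kappa", {
  rec <- data.frame(
    image_id = c("a", "a", "a", "b", "b"),
    annotator_id = c("r1", "r2", "r3", "r1", "r2"),
    day = 1L,
    dyad_id = c(5L, 5L, 7L, 2L, 2L)
  )
  tal <- tally_votes(rec)
  expect_identical(tal$n, c(3L, 2L))
  expect_identical(tal$counts_5[tal$image_id == "a"], 2L)
  expect_identical(tal$counts_2[tal$image_id == "b"], 2L)
  kt <- kappa_table(tal)
  expect_equal(kt$kappa[kt$image_id == "b"], 1)
  expect_equal(kt$kappa[kt$image_id == "a"],
               per_image_kappa(c(0, 0, 0, 0, 2, 0, 1, 0))$kappa)
})

test_that("summaries group images by band, label count and modal dyad as constructed", {
  vecs <- list(
    c(1, 1, 1, 1, 1, 1, 1, 0), # kappa -1/7          -> Poor
    c(3, 3, 1, 1, 0, 0, 0, 0), # kappa ~0.102        -> Slight
    c(4, 3, 1, 0, 0, 0, 0, 0), # kappa ~0.224        -> Fair
    c(6, 2, 0, 0, 0, 0, 0, 0), # kappa ~0.51         -> Moderate
    c(7, 1, 0, 0, 0, 0, 0, 0), # kappa ~0.714        -> Substantial
    c(0, 0, 0, 8, 0, 0, 0, 0)  # kappa 1             -> Almost Perfect
  )
  votes <- data.frame(image_id = sprintf("i%d", 1:6))
  votes[paste0("counts_", 1:8)] <- as.data.frame(do.call(rbind, vecs))
  kt <- kappa_table(votes)
  by_band <- summarize_agreement(kt, by = "band")
  expect_identical(nrow(by_band), 6L)
  expect_true(all(by_band$n_images == 1L))
  expect_identical(as.character(by_band$band),
                   c("Poor", "Slight", "Fair", "Moderate", "Substantial",
                     "Almost Perfect"))
  by_labels <- summarize_agreement(kt, by = "n_labels")
  expect_identical(by_labels$n_images[by_labels$n_labels == 2],
                   2L) # the 6/2- and 7/1-split images
  by_modal <- summarize_agreement(kt, by = "modal_dyad")
  expect_identical(by_modal$n_images[by_modal$modal_dyad == 1], 5L)
  expect_identical(by_modal$n_images[by_modal$modal_dyad == 4], 1L)
  expect_error(summarize_agreement(kt, by = "annotator"), "arg")
})
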