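test_that("config validation rejects infeasible campaigns", {
  expect_error(sim_config(n_images = 100, n_days = 2, images_per_session = 56),
               "n_days \\* images_per_session")
  expect_error(sim_config(p_true = 0.9, p_adjacent = 0.1, p_opposite = 0.1),
               "exceed 1")
  expect_error(sim_config(n_images = 12, n_days = 2, images_per_session = 6,
                          controls_per_session = 6),
               "exceed controls_per_session")
  expect_error(sim_config(p_true = 1.2), "\\[0, 1\\]")
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_images = 80, n_days = 2, raters_per_day = 8,
                    images_per_session = 40, seed = 5)
  a <- simulate_annotations(cfg)
  b <- simulate_annotations(cfg)
  expect_identical(a, b)
  c <- simulate_annotations(sim_config(n_images = 80, n_days = 2,
                                       raters_per_day = 8,
                                       images_per_session = 40, seed = 6))
  expect_false(identical(a$annotations, c$annotations))
})

test_that("sessions satisfy the structural contract", {
  cfg <- sim_config(n_images = 120, n_days = 3, raters_per_day = 6,
                    images_per_session = 40, seed = 2)
  sim <- simulate_annotations(cfg)
  dt <- sim$annotations
  for (key in split(dt, list(dt$annotator_id, dt$day), drop = TRUE)) {
    expect_identical(nrow(key), 41L) # 40 distinct images + 1 repeat
    tab <- table(key$image_id)
    expect_identical(sum(tab == 2L), 1L)
    expect_identical(sum(key$image_id %in% sim$controls$image_id), 6L)
  }
  # every image belongs to exactly one day and collects votes from every
  # rater of that day
  per_img_days <- tapply(dt$day, dt$image_id, function(d) length(unique(d)))
  expect_true(all(per_img_days == 1L))
  expect_identical(nrow(sim$truth), 120L)
  expect_true(all(sim$controls$image_id %in% sim$truth$image_id))
})

test_that("the degenerate attentive limit yields all-valid sessions and unanimous images", {
  cfg <- sim_config(n_images = 80, n_days = 2, raters_per_day = 10,
                    images_per_session = 40, p_true = 1, p_adjacent = 0,
                    p_opposite = 0, inattentive_rate = 0,
                    p_control_correct = 1, seed = 3)
  sim <- simulate_annotations(cfg)
  ap <- apply_ap(sim$annotations, sim$controls)
  expect_true(all(ap$audit$valid))
  kt <- kappa_table(tally_votes(ap$retained))
  expect_true(all(kt$kappa == 1))
  expect_equal(mean_kappa(kt), 1)
  # and every vote equals the true dyad
  merged <- merge(ap$retained, sim$truth, by = "image_id")
  expect_true(all(merged$dyad_id == merged$true_dyad))

  re <- run_re_stage(tally_votes(ap$retained))
  rec <- recovery_report(re$results, sim$truth)
  expect_equal(rec$frac_true_kept, 1)
  expect_equal(rec$frac_true_unique, 1)
})

test_that("fully inattentive raters almost never survive the AP rules", {
  cfg <- sim_config(n_images = 64, n_days = 8, raters_per_day = 250,
                    images_per_session = 8, inattentive_rate = 1, seed = 4)
  sim <- simulate_annotations(cfg)
  ap <- apply_ap(sim$annotations, sim$controls)
  # pass probability is ~2e-5; over 2,000 sessions even a loose bound holds
  expect_lt(mean(ap$audit$valid), 0.005)
})

test_that("mean post-AP kappa is nondecreasing in the attentive vote probability", {
  kappas <- vapply(c(0.3, 0.9), function(p) {
    cfg <- sim_config(n_images = 160, n_days = 4, raters_per_day = 15,
                      images_per_session = 40, p_true = p,
                      p_adjacent = min(0.1, (1 - p) * 2 / 3),
                      p_opposite = min(0.05, (1 - p) / 3),
                      inattentive_rate = 0.1, seed = 17)
    sim <- simulate_annotations(cfg)
    ap <- apply_ap(sim$annotations, sim$controls)
    mean_kappa(kappa_table(tally_votes(ap$retained)))
  }, numeric(1))
  expect_lt(kappas[1], kappas[2])
})

test_that("RE reduces the prevalence of wheel-opposite vote contamination", {
  cfg <- sim_config(n_images = 160, n_days = 4, raters_per_day = 20,
                    images_per_session = 40, p_true = 0.65, p_adjacent = 0.15,
                    p_opposite = 0.15, inattentive_rate = 0, seed = 19)
  sim <- simulate_annotations(cfg)
  ap <- apply_ap(sim$annotations, sim$controls)
  votes <- tally_votes(ap$retained)
  m <- as.matrix(votes[paste0("counts_", 1:8)])
  truth <- sim$truth$true_dyad[match(votes$image_id, sim$truth$image_id)]
  opp <- opposite_dyad(truth)
  pre_opp <- mean(m[cbind(seq_len(nrow(m)), opp)] > 0)
  st <- run_re_stage(votes)
  post <- as.matrix(st$results[paste0("counts_post_", 1:8)])
  post_opp <- mean(post[cbind(seq_len(nrow(post)), opp)] > 0)
  expect_gt(pre_opp, 0.5) # contamination is widespread before filtering
  expect_lt(post_opp, pre_opp) # and strictly reduced by RE
})

test_that("recovery_report validates its inputs", {
  cfg <- sim_config(n_images = 40, n_days = 1, raters_per_day = 8,
                    images_per_session = 40, seed = 23)
  sim <- simulate_annotations(cfg)
  ap <- apply_ap(sim$annotations, sim$controls)
  st <- run_re_stage(tally_votes(ap$retained))
  expect_error(recovery_report(st$results[0, ], sim$truth), "empty")
  bad_truth <- sim$truth[-1, ]
  expect_error(recovery_report(st$results, bad_truth), "missing from ground truth")
})
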