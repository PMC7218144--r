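manifest_of <- function(n_prc, n_nrc) {
  tibble::tibble(channel_id = sprintf("ch%03d", seq_len(n_prc + n_nrc)),
                 label = rep(c("PRC", "NRC"), c(n_prc, n_nrc)))
}

test_that("class balancing keeps all positives and subsamples negatives", {
  m <- manifest_of(30, 90)
  bal <- balance_classes(m, seed = 4)
  expect_identical(sum(bal$label == "PRC"), 30L)
  expect_identical(sum(bal$label == "NRC"), 30L)
  expect_setequal(bal$channel_id[bal$label == "PRC"],
                  m$channel_id[m$label == "PRC"])
  expect_identical(balance_classes(m, seed = 4), bal)
  expect_false(identical(balance_classes(m, seed = 5), bal))

  even <- manifest_of(10, 10)
  expect_identical(sort(balance_classes(even, 1)$channel_id),
                   sort(even$channel_id))
  expect_error(balance_classes(manifest_of(0, 10)),
               class = "ecogmapr_validation_error")
  expect_warning(bal2 <- balance_classes(manifest_of(8, 5), 1),
                 regexp = "keeping all NRC")
  expect_identical(nrow(bal2), 13L)
})

test_that("grouped shuffle-split never leaks a channel across the split", {
  m <- manifest_of(15, 45)
  plan <- grouped_shuffle_split(m, n_repeats = 30, test_fraction = 0.2, seed = 9)
  expect_identical(nrow(plan), 30L)
  for (r in seq_len(30)) {
    expect_length(intersect(plan$train[[r]], plan$test[[r]]), 0)
    expect_setequal(c(plan$train[[r]], plan$test[[r]]), m$channel_id)
  }
  # stratification: test sets keep the class ratio
  labs <- setNames(m$label, m$channel_id)
  n_prc_test <- vapply(plan$test, function(ids) sum(labs[ids] == "PRC"),
                       integer(1))
  expect_true(all(n_prc_test == 3L))
})

test_that("stratification floor holds one channel per class and errors bind", {
  m <- manifest_of(2, 4)
  plan <- grouped_shuffle_split(m, n_repeats = 5, test_fraction = 0.1, seed = 2)
  labs <- setNames(m$label, m$channel_id)
  for (r in 1:5) {
    expect_gte(sum(labs[plan$test[[r]]] == "PRC"), 1)
    expect_gte(sum(labs[plan$test[[r]]] == "NRC"), 1)
  }
  expect_error(grouped_shuffle_split(manifest_of(2, 4), test_fraction = 0.9),
               class = "ecogmapr_validation_error")
  expect_error(grouped_shuffle_split(manifest_of(1, 5)),
               class = "ecogmapr_validation_error")
})

test_that("majority voting applies the strict >50% rule with abstention on ties", {
  expect_identical(majority_vote(rep(c("positive", "negative"), c(200, 154))),
                   "PRC")
  expect_identical(majority_vote(rep("negative", 355)), "NRC")
  expect_identical(majority_vote(rep(c("positive", "negative"), c(177, 177))),
                   "abstain")
  expect_identical(majority_vote(rep(c("positive", "negative"), c(178, 176))),
                   "PRC")
  expect_identical(majority_vote("positive"), "PRC")
  expect_error(majority_vote(character()), class = "ecogmapr_validation_error")
  expect_error(majority_vote(c("yes", "no")), class = "ecogmapr_validation_error")
})

test_that("metrics reproduce hand-computed ratios exactly", {
  preds <- tibble::tibble(
    channel_id = sprintf("c%02d", 1:24),
    voted_label = rep(c("PRC", "NRC", "NRC", "PRC"), c(11, 1, 9, 3)),
    truth = rep(c("PRC", "NRC"), c(12, 12)))
  rep <- compute_metrics(preds)
  expect_equal(rep$summary$sensitivity_mean, 100 * 11 / 12, tolerance = 1e-10)
  expect_equal(rep$summary$specificity_mean, 100 * 9 / 12, tolerance = 1e-10)
  expect_equal(rep$summary$accuracy_mean, 100 * 20 / 24, tolerance = 1e-10)
  # printed two-decimal form matches the familiar 91.67 / 75.00 / 83.33
  expect_identical(sprintf("%.2f", rep$summary$sensitivity_mean), "91.67")
  expect_identical(sprintf("%.2f", rep$summary$specificity_mean), "75.00")
  expect_identical(sprintf("%.2f", rep$summary$accuracy_mean), "83.33")
})

test_that("metric identities and degenerate predictors behave", {
  perfect <- tibble::tibble(channel_id = sprintf("c%d", 1:10),
                            voted_label = rep(c("PRC", "NRC"), each = 5),
                            truth = rep(c("PRC", "NRC"), each = 5))
  s <- compute_metrics(perfect)$summary
  expect_equal(c(s$sensitivity_mean, s$specificity_mean, s$accuracy_mean),
               c(100, 100, 100))

  all_prc <- dplyr::mutate(perfect, voted_label = "PRC")
  s2 <- compute_metrics(all_prc)$summary
  expect_equal(c(s2$sensitivity_mean, s2$specificity_mean, s2$accuracy_mean),
               c(100, 0, 50))

  # accuracy = (sens*P + spec*N) / (P+N) on any balanced table
  withr::local_seed(30)
  rand <- dplyr::mutate(perfect,
                        voted_label = sample(c("PRC", "NRC"), 10, TRUE))
  pr <- compute_metrics(rand)$per_repeat
  expect_equal(pr$accuracy, (pr$sensitivity * 5 + pr$specificity * 5) / 10,
               tolerance = 1e-10)
})

test_that("truth can be joined from a manifest and mismatches error", {
  preds <- tibble::tibble(channel_id = c("a", "b"),
                          voted_label = c("PRC", "NRC"))
  truth <- tibble::tibble(channel_id = c("a", "b"), label = c("PRC", "PRC"))
  rep <- compute_metrics(preds, truth)
  expect_equal(rep$summary$sensitivity_mean, 50)
  expect_error(compute_metrics(preds, truth[1, ]),
               class = "ecogmapr_validation_error")
  expect_error(compute_metrics(preds), class = "ecogmapr_validation_error")
})

test_that("abstaining channels are excluded from the denominators and counted", {
  preds <- tibble::tibble(
    channel_id = sprintf("c%d", 1:6),
    voted_label = c("PRC", "abstain", "NRC", "NRC", "abstain", "PRC"),
    truth = c("PRC", "PRC", "PRC", "NRC", "NRC", "NRC"))
  rep <- compute_metrics(preds)
  expect_identical(rep$n_abstained, 2L)
  expect_equal(rep$summary$sensitivity_mean, 50)
  expect_equal(rep$summary$specificity_mean, 50)
})
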