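toy_truth <- function(virus_ids, genera) {
  data.frame(virus_id = virus_ids, host_id = NA_character_, genus = genera,
             family = paste0("f_", genera), order = "order_1",
             class = "class_1", phylum = "phylum_1", domain = "Bacteria",
             stringsAsFactors = FALSE)
}

fake_predictions <- function(virus_ids, genera, predicted = TRUE) {
  rows <- mapply(function(v, g, made) {
    taxa <- if (made) c(g, paste0("f_", g), "order_1", "class_1", "phylum_1",
                        "Bacteria") else rep(NA_character_, 6)
    data.frame(virus_id = v,
               rank = c("genus", "family", "order", "class", "phylum",
                        "domain"),
               taxon = taxa, score = 0.1, host_id = "h1", predicted = made,
               stringsAsFactors = FALSE)
  }, virus_ids, genera, predicted, SIMPLIFY = FALSE)
  do.call(rbind, rows)
}

test_that("accuracy_by_level counts hits, denominators and recall correctly", {
  truth <- toy_truth(paste0("v", 1:5), c("gA", "gA", "gB", "gB", "gC"))
  # 4 predicted (v5 gated out), 3 of them right at genus
  preds <- fake_predictions(paste0("v", 1:5),
                            c("gA", "gA", "gB", "gX", "gC"),
                            predicted = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  acc <- accuracy_by_level(preds, truth)
  g <- acc[acc$rank == "genus", ]
  expect_equal(g$accuracy, 0.75)
  expect_equal(g$recall, 0.8)
  expect_identical(g$n_predicted, 4L)

  # perfect predictions: accuracy and recall 1 everywhere
  perfect <- fake_predictions(paste0("v", 1:5),
                              c("gA", "gA", "gB", "gB", "gC"))
  expect_true(all(accuracy_by_level(perfect, truth)$accuracy == 1))

  # unknown truth excluded from that rank's denominator
  truth2 <- truth; truth2$genus[1] <- "unknown"
  acc2 <- accuracy_by_level(preds, truth2)
  expect_identical(acc2$n_predicted[acc2$rank == "genus"], 3L)

  expect_error(accuracy_by_level(preds, toy_truth("vX", "gA")), "overlap")
})

test_that("accuracy is invariant to virus row order", {
  truth <- toy_truth(paste0("v", 1:5), c("gA", "gA", "gB", "gB", "gC"))
  preds <- fake_predictions(paste0("v", 1:5),
                            c("gA", "gA", "gB", "gX", "gC"))
  shuffled <- preds[rev(seq_len(nrow(preds))), ]
  expect_equal(accuracy_by_level(preds, truth),
               accuracy_by_level(shuffled, truth))
})

test_that("roc_auc equals the all-pairs oracle and handles edge cases", {
  expect_equal(roc_auc(rep(0.1, 5), rep(0.9, 5)), 1)
  same <- c(0.2, 0.5, 0.7)
  expect_equal(roc_auc(same, same), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4), c(0.2, 0.3)),
               oracle_auc(c(0.1, 0.4), c(0.2, 0.3)))
  set.seed(13)
  for (i in 1:20) {
    a <- round(runif(sample(2:50, 1)), 2) # rounding induces ties
    b <- round(runif(sample(2:50, 1)), 2)
    expect_equal(roc_auc(a, b), oracle_auc(a, b))
  }
  expect_error(roc_auc(numeric(0), 1), "non-empty")
})

test_that("pair_ttest behaves like a Welch t-test should", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(pair_ttest(x, x), 1)
  set.seed(14)
  expect_lt(pair_ttest(rnorm(100, 0), rnorm(100, 5)), 1e-10)
  # type-I control at the 5% level under an equal-mean null
  rej <- onfhost:::with_seed(99, {
    mean(replicate(500, pair_ttest(rnorm(20), rnorm(20)) < 0.05))
  })
  expect_lt(abs(rej - 0.05), 0.03)
  expect_error(pair_ttest(1, c(1, 2)), "at least 2")
})

test_that("random_baseline is the closed-form expectation", {
  tax <- toy_taxonomy(c("gA", "gA", "gB", "gB"))
  truth <- toy_truth(c("v1", "v2"), c("gA", "gA"))
  rb <- random_baseline(tax, truth)
  expect_equal(rb$baseline[rb$rank == "genus"], 0.5)
  # single-domain host set: domain baseline exactly 1
  expect_equal(rb$baseline[rb$rank == "domain"], 1)

  # skewed fixture: 90/10 hosts, truths split 50/50 -> 0.5*0.9 + 0.5*0.1
  tax2 <- toy_taxonomy(c(rep("gA", 9), "gB"))
  truth2 <- toy_truth(c("v1", "v2"), c("gA", "gB"))
  rb2 <- random_baseline(tax2, truth2)
  expect_equal(rb2$baseline[rb2$rank == "genus"], 0.5)

  expect_error(random_baseline(tax[0, ], truth), "empty")
})

test_that("robustness sweep at null settings matches the unperturbed run", {
  set.seed(112)
  bench <- simulate_benchmark(simulation_config(
    n_hosts = 8, host_length = 20000, virus_length = 6000, seed = 112))
  m <- compute_matrix(bench$viruses, bench$hosts, "d2star", 4, 1)
  base <- accuracy_by_level(predict_nearest(m, bench$taxonomy), bench$truth)

  # full-length grid point reproduces the baseline accuracies
  sw <- robustness_sweep(bench$viruses, bench$hosts, bench$taxonomy,
                         bench$truth, lengths = NA, replicates = 2,
                         measure = "d2star", k = 4, order = 1, seed = 3)
  for (rk in unique(sw$rank))
    expect_true(all(sw$accuracy[sw$rank == rk] ==
                      base$accuracy[base$rank == rk]))

  # error-rate 0 on full-length fragments likewise
  sw0 <- robustness_sweep(bench$viruses, bench$hosts, bench$taxonomy,
                          bench$truth, error_rates = 0, replicates = 1,
                          measure = "d2star", k = 4, order = 1,
                          error_fragment = 60000, seed = 3)
  expect_true(all(sw0$accuracy[sw0$rank == "genus"] ==
                    base$accuracy[base$rank == "genus"]))

  smry <- summarize_sweep(sw)
  expect_true(all(c("mean_accuracy", "lo", "hi") %in% names(smry)))
  expect_true(all(smry$lo <= smry$mean_accuracy &
                    smry$mean_accuracy <= smry$hi))
  expect_error(robustness_sweep(bench$viruses, bench$hosts, bench$taxonomy,
                                bench$truth), "at least one")
})
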