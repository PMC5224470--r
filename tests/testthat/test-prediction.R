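make_matrix <- function(scores, viruses = NULL, hosts = NULL) {
  m <- matrix(scores, nrow = if (is.null(viruses)) 1 else length(viruses),
              byrow = TRUE)
  rownames(m) <- viruses %||% "v1"
  colnames(m) <- hosts %||% paste0("h", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("compute_matrix equals pairwise single calls and subsets cleanly", {
  set.seed(501)
  vir <- lapply(1:2, function(i) seq_record(rand_dna(400), paste0("v", i)))
  hos <- lapply(1:3, function(i) seq_record(rand_dna(400), paste0("h", i)))
  m <- compute_matrix(vir, hos, "d2star", k = 4, order = 1)
  expect_identical(dim(m), c(2L, 3L))
  for (i in 1:2) for (j in 1:3)
    expect_equal(m[i, j],
                 dissimilarity(vir[[i]], hos[[j]], "d2star", 4, 1))

  # identical virus and host sequence -> exact zero
  same <- seq_record(rand_dna(400, seed = 6), "g")
  vm <- compute_matrix(list(same), list(same), "d2star", 4, 1)
  expect_equal(vm[1, 1], 0)

  # habitat filtering is plain column subsetting
  sub <- compute_matrix(vir, hos[c(1, 3)], "d2star", 4, 1)
  expect_equal(unname(sub), unname(m[, c(1, 3)]), ignore_attr = TRUE)

  # degenerate genomes are reported by id, not dropped
  bad <- seq_record("AAAAAAAAAAAA", "bad_host")
  expect_error(compute_matrix(vir, c(hos, list(bad)), "d2star", 4, 0),
               "bad_host")
})

test_that("predict_nearest takes the argmin lineage and applies thresholds", {
  tax <- toy_taxonomy(c("g1", "g2", "g3"))
  m <- make_matrix(c(0.3, 0.1, 0.2))
  p <- predict_nearest(m, tax)
  expect_identical(p$taxon[p$rank == "genus"], "g2")
  expect_identical(unique(p$host_id), "h2")
  expect_equal(unique(p$score), 0.1)

  p2 <- predict_nearest(m, tax, threshold = 0.05)
  expect_true(all(is.na(p2$taxon)))
  expect_true(all(!p2$predicted))

  # threshold equal to the best score still predicts (gate is score > t)
  p3 <- predict_nearest(m, tax, threshold = 0.1)
  expect_identical(p3$taxon[p3$rank == "genus"], "g2")

  expect_error(predict_nearest(make_matrix(0.1, hosts = "hx"), tax),
               "missing from taxonomy")
})

test_that("nearest-host ties break uniformly and deterministically by seed", {
  tax <- toy_taxonomy(c("g1", "g2", "g3"))
  m <- make_matrix(c(0.1, 0.1, 0.5))
  picks <- vapply(1:1000, function(s)
    predict_nearest(m, tax, seed = s)$host_id[1], "")
  expect_identical(sort(unique(picks)), c("h1", "h2"))
  expect_true(abs(mean(picks == "h1") - 0.5) < 0.05)
  expect_identical(predict_nearest(m, tax, seed = 42)$host_id,
                   predict_nearest(m, tax, seed = 42)$host_id)
})

test_that("consensus voting is modal per rank with seeded tie-breaks", {
  tax <- toy_taxonomy(c("A", "A", "B", "A", "C"))
  m <- make_matrix(c(0.1, 0.2, 0.3, 0.4, 0.5))
  p <- predict_consensus(m, tax, n = 5)
  expect_identical(p$taxon[p$rank == "genus"], "A")

  # 2-2 frequency tie between A and B over the top 4
  tax2 <- toy_taxonomy(c("A", "A", "B", "B", "C"))
  picks <- vapply(1:1000, function(s)
    predict_consensus(m, tax2, n = 4, seed = s)$taxon[1], "")
  expect_true(abs(mean(picks == "A") - 0.5) < 0.05)

  # unknown labels never win a vote
  tax3 <- toy_taxonomy(c("unknown", "unknown", "B", "unknown", "C"))
  p3 <- predict_consensus(m, tax3, n = 4)
  expect_identical(p3$taxon[p3$rank == "genus"], "B")

  expect_error(predict_consensus(m, tax, n = 9), "n must be")
})

test_that("consensus with n = 1 is exactly nearest-host", {
  set.seed(77)
  for (i in 1:10) {
    m <- matrix(runif(30), 5, 6,
                dimnames = list(paste0("v", 1:5), paste0("h", 1:6)))
    tax <- toy_taxonomy(sample(c("gA", "gB", "gC"), 6, replace = TRUE))
    pn <- predict_nearest(m, tax, seed = i)
    pc <- predict_consensus(m, tax, n = 1, seed = i)
    expect_identical(pn$taxon, pc$taxon)
    expect_identical(pn$score, pc$score)
  }
})

test_that("raising the threshold never loses predictions", {
  set.seed(88)
  m <- matrix(runif(40), 4, 10,
              dimnames = list(paste0("v", 1:4), paste0("h", 1:10)))
  tax <- toy_taxonomy(sample(c("gA", "gB"), 10, replace = TRUE))
  made <- vapply(c(0.05, 0.2, 0.5, 1), function(t)
    sum(predict_nearest(m, tax, threshold = t)$predicted) / 6, 0)
  expect_true(all(diff(made) >= 0))
})

test_that("predictions are invariant to host column order", {
  set.seed(99)
  m <- matrix(runif(24), 3, 8,
              dimnames = list(paste0("v", 1:3), paste0("h", 1:8)))
  tax <- toy_taxonomy(sample(c("gA", "gB", "gC"), 8, replace = TRUE))
  p1 <- predict_nearest(m, tax, seed = 5)
  perm <- sample(8)
  p2 <- predict_nearest(m[, perm], tax, seed = 5)
  expect_identical(p1$taxon, p2$taxon) # no ties in runif scores
})

test_that("rank-sum test flags a planted low-scoring taxon", {
  genera <- c(rep("gA", 20), rep("gB", 100), rep("gC", 100))
  tax <- toy_taxonomy(genera)
  scores <- setNames(c(rep(0.1, 20), rep(0.9, 200)), tax$host_id)
  res <- ranksum_taxa(scores, tax, "genus")
  expect_identical(res$taxon, "gA")
  expect_lt(res$corrected_p, 1e-10)

  # a 1-host taxon cannot survive Bonferroni among many taxa, even shifted low
  tax1 <- toy_taxonomy(c("rare", paste0("g", rep(1:30, each = 2))))
  set.seed(61)
  s1 <- setNames(c(0.01, runif(60, 0.4, 0.9)), tax1$host_id)
  expect_identical(nrow(ranksum_taxa(s1, tax1, "genus")), 0L)

  expect_error(ranksum_taxa(scores, toy_taxonomy(rep("g", 220)), "genus"),
               "distinct taxa")
  expect_error(ranksum_taxa(unname(scores), tax, "genus"), "named")
})

test_that("matrix TSV round-trips at full precision", {
  m <- matrix(c(pi * 1e-3, exp(-7), 1 / 3, 2 / 7), 2, 2,
              dimnames = list(c("v1", "v2"), c("h1", "h2")))
  attr(m, "config") <- NULL
  f <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, f)
  expect_equal(read_matrix_tsv(f), m, tolerance = 1e-15)
  unlink(f)
})
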