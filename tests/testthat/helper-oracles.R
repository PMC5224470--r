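# Independent brute-force oracles used to validate the package's k-mer
# counting, background models and all eleven measures. Everything here works
# on plain character sequences with naive substring scans and per-word
# loops; nothing calls back into the package's counting/measure code.

rand_dna <- function(n, n_prob = 0, seed = NULL) {
  draw <- function() {
    letters <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    if (n_prob > 0) {
      hit <- runif(n) < n_prob
      letters[hit] <- "N"
    }
    paste(letters, collapse = "")
  }
  if (is.null(seed)) draw() else onfhost:::with_seed(seed, draw())
}

all_words <- function(k) {
  if (k == 0) return("")
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                      stringsAsFactors = FALSE)
  # lexicographic with the FIRST letter most significant
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1, paste, collapse = "")
}

# Naive window scan over one or more contigs; windows containing N dropped.
oracle_count <- function(contigs, k) {
  words <- all_words(k)
  counts <- setNames(numeric(length(words)), words)
  for (s in contigs) {
    L <- nchar(s)
    if (L < k) next
    for (i in seq_len(L - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (!grepl("N", w, fixed = TRUE)) counts[w] <- counts[w] + 1
    }
  }
  counts
}

oracle_freq <- function(contigs, k) {
  n <- oracle_count(contigs, k)
  n / sum(n)
}

# Order-r transition probabilities and context distribution from naive
# (r+1)-mer scans; contexts weighted by how often they precede a successor.
oracle_model <- function(contigs, r) {
  cts <- oracle_count(contigs, r + 1)
  ctxs <- all_words(r) # "" for r = 0; index positionally, not by name
  trans <- matrix(NA_real_, length(ctxs), 4,
                  dimnames = list(ctxs, c("A", "C", "G", "T")))
  totals <- numeric(length(ctxs))
  for (ci in seq_along(ctxs))
    for (b in c("A", "C", "G", "T"))
      totals[ci] <- totals[ci] + cts[paste0(ctxs[ci], b)]
  for (ci in seq_along(ctxs))
    if (totals[ci] > 0)
      for (b in c("A", "C", "G", "T"))
        trans[ci, b] <- cts[paste0(ctxs[ci], b)] / totals[ci]
  list(trans = trans, ctx_probs = setNames(totals / sum(totals), ctxs))
}

# p_w for every k-word by explicit per-word chain product.
oracle_word_probs <- function(contigs, k, r) {
  mod <- oracle_model(contigs, r)
  words <- all_words(k)
  p <- setNames(numeric(length(words)), words)
  for (w in words) {
    pw <- if (r == 0) 1 else mod$ctx_probs[substr(w, 1, r)]
    for (i in (r + 1):k) {
      row <- if (r == 0) 1 else substr(w, i - r, i - 1)
      tr <- mod$trans[row, substr(w, i, i)]
      pw <- pw * if (is.na(tr)) 0 else tr
    }
    p[w] <- pw
  }
  p
}

oracle_expected <- function(contigs, k, r) {
  n <- sum(oracle_count(contigs, k))
  n * oracle_word_probs(contigs, k, r)
}

oracle_eu <- function(x, y, k) sqrt(sum((oracle_freq(x, k) - oracle_freq(y, k))^2))
oracle_ma <- function(x, y, k) sum(abs(oracle_freq(x, k) - oracle_freq(y, k)))
oracle_ch <- function(x, y, k) max(abs(oracle_freq(x, k) - oracle_freq(y, k)))

oracle_d2 <- function(x, y, k) {
  fx <- oracle_freq(x, k); fy <- oracle_freq(y, k)
  (1 - sum(fx * fy) / sqrt(sum(fx^2)) / sqrt(sum(fy^2))) / 2
}

oracle_js <- function(x, y, r) {
  p <- oracle_freq(x, r + 1); q <- oracle_freq(y, r + 1)
  m <- (p + q) / 2
  tot <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) tot <- tot + p[i] * log2(p[i] / m[i]) / 2
    if (q[i] > 0) tot <- tot + q[i] * log2(q[i] / m[i]) / 2
  }
  tot
}

oracle_d2star <- function(x, y, k, r) {
  ex <- oracle_expected(x, k, r); ey <- oracle_expected(y, k, r)
  cx <- oracle_count(x, k) - ex; cy <- oracle_count(y, k) - ey
  cross <- 0; dx <- 0; dy <- 0
  for (w in names(ex)) {
    if (ex[w] > 0 && ey[w] > 0)
      cross <- cross + cx[w] * cy[w] / sqrt(ex[w] * ey[w])
    if (ex[w] > 0) dx <- dx + cx[w]^2 / ex[w]
    if (ey[w] > 0) dy <- dy + cy[w]^2 / ey[w]
  }
  (1 - cross / (sqrt(dx) * sqrt(dy))) / 2
}

oracle_d2s <- function(x, y, k, r) {
  cx <- oracle_count(x, k) - oracle_expected(x, k, r)
  cy <- oracle_count(y, k) - oracle_expected(y, k, r)
  cross <- 0; dx <- 0; dy <- 0
  for (w in names(cx)) {
    s <- sqrt(cx[w]^2 + cy[w]^2)
    if (s > 0) {
      cross <- cross + cx[w] * cy[w] / s
      dx <- dx + cx[w]^2 / s
      dy <- dy + cy[w]^2 / s
    }
  }
  (1 - cross / (sqrt(dx) * sqrt(dy))) / 2
}

oracle_euf <- function(x, y, k, r) {
  ex <- oracle_expected(x, k, r); ey <- oracle_expected(y, k, r)
  cx <- oracle_count(x, k); cy <- oracle_count(y, k)
  tot <- 0
  for (w in names(ex))
    if (ex[w] > 0 && ey[w] > 0)
      tot <- tot + ((cx[w] - ex[w]) / ex[w] - (cy[w] - ey[w]) / ey[w])^2
  sqrt(tot)
}

oracle_hao_vec <- function(x, k) {
  fk <- oracle_freq(x, k)
  f1 <- oracle_freq(x, k - 1)
  f2 <- oracle_freq(x, k - 2)
  a <- setNames(numeric(length(fk)), names(fk))
  for (w in names(fk)) {
    pre <- substr(w, 1, k - 1); suf <- substr(w, 2, k)
    mid <- substr(w, 2, k - 1)
    f0 <- if (f2[mid] > 0) f1[pre] * f1[suf] / f2[mid] else 0
    a[w] <- if (f0 > 0) (fk[w] - f0) / f0 else 0
  }
  a
}

oracle_hao <- function(x, y, k) {
  ax <- oracle_hao_vec(x, k); ay <- oracle_hao_vec(y, k)
  (1 - sum(ax * ay) / sqrt(sum(ax^2)) / sqrt(sum(ay^2))) / 2
}

oracle_teeling_z <- function(x, k) {
  nk <- oracle_count(x, k)
  n1 <- oracle_count(x, k - 1)
  n2 <- oracle_count(x, k - 2)
  z <- setNames(rep(NA_real_, length(nk)), names(nk))
  for (w in names(nk)) {
    pre <- substr(w, 1, k - 1); suf <- substr(w, 2, k)
    mid <- substr(w, 2, k - 1)
    if (n2[mid] > 0) {
      e <- n1[pre] * n1[suf] / n2[mid]
      if (e > 0) z[w] <- (nk[w] - e) / sqrt(e)
    }
  }
  z
}

oracle_teeling <- function(x, y, k) {
  zx <- oracle_teeling_z(x, k); zy <- oracle_teeling_z(y, k)
  ok <- !is.na(zx) & !is.na(zy)
  (1 - cor(zx[ok], zy[ok])) / 2
}

oracle_willner_vec <- function(x, k) {
  fk <- oracle_freq(x, k)
  f1 <- oracle_freq(x, 1)
  d <- setNames(numeric(length(fk)), names(fk))
  for (w in names(fk)) {
    denom <- 1
    for (i in seq_len(k)) denom <- denom * f1[substr(w, i, i)]
    d[w] <- if (denom > 0) fk[w] / denom else 0
  }
  d
}

oracle_willner <- function(x, y, k)
  mean(abs(oracle_willner_vec(x, k) - oracle_willner_vec(y, k)))

# Dispatch an oracle by measure id on two character-vector "genomes".
oracle_measure <- function(measure, x, y, k, r) {
  switch(measure,
         Eu = oracle_eu(x, y, k), Ma = oracle_ma(x, y, k),
         Ch = oracle_ch(x, y, k), d2 = oracle_d2(x, y, k),
         JS = oracle_js(x, y, r), d2star = oracle_d2star(x, y, k, r),
         d2S = oracle_d2s(x, y, k, r), Hao = oracle_hao(x, y, k),
         Teeling = oracle_teeling(x, y, k), EuF = oracle_euf(x, y, k, r),
         Willner = oracle_willner(x, y, k))
}

# All-pairs AUC oracle: P(true < random) + P(tie)/2 by enumeration.
oracle_auc <- function(true_scores, random_scores) {
  tot <- 0
  for (t in true_scores)
    for (r in random_scores)
      tot <- tot + (t < r) + 0.5 * (t == r)
  tot / (length(true_scores) * length(random_scores))
}

# Tiny deterministic taxonomy builder for prediction-layer tests.
toy_taxonomy <- function(genera, prefix = "h") {
  n <- length(genera)
  data.frame(host_id = paste0(prefix, seq_len(n)), genus = genera,
             family = paste0("f_", genera), order = "order_1",
             class = "class_1", phylum = "phylum_1", domain = "Bacteria",
             stringsAsFactors = FALSE)
}
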