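#' Available dissimilarity measures
#'
#' Eleven alignment-free distance/dissimilarity measures between two genomes'
#' k-mer profiles, in two families:
#' \describe{
#'   \item{no background correction}{`Eu` (Euclidean), `Ma` (Manhattan),
#'     `Ch` (Chebyshev), `d2` (cosine-type), `JS` (Jensen-Shannon divergence
#'     of (r+1)-mer distributions; independent of k)}
#'   \item{background corrected}{`d2star`, `d2S` (centered counts under an
#'     order-r Markov background), `Hao` (composition-vector cosine),
#'     `Teeling` (tetranucleotide-style z-score correlation), `EuF`
#'     (Euclidean distance of relative deviations from expectation),
#'     `Willner` (mean absolute difference of mononucleotide-normalized
#'     abundance ratios; defined only for k <= 4)}
#' }
#' All scores are oriented so that smaller means more similar; similarity
#' statistics s in \[-1, 1\] (cosine, correlation) are wrapped as (1 - s)/2.
#'
#' @return Character vector of measure ids.
#' @export
onf_measures <- function() {
  c("Eu", "Ma", "Ch", "d2", "JS",
    "d2star", "d2S", "Hao", "Teeling", "EuF", "Willner")
}

BACKGROUND_MEASURES <- c("d2star", "d2S", "EuF")

# Validate a (measure, k, order) configuration against each measure's domain
# constraints.
check_measure_config <- function(measure, k, order) {
  measure <- match.arg(measure, onf_measures())
  k <- as.integer(k)
  order <- as.integer(order)
  if (is.na(k) || k < 1L || k > 9L)
    stop("k must be in 1..9", call. = FALSE)
  if (is.na(order) || order < 0L)
    stop("order must be >= 0", call. = FALSE)
  if (measure == "Willner" && k > 4L)
    stop("the Willner measure is not defined for k-mer lengths > 4",
         call. = FALSE)
  if (measure %in% c("Hao", "Teeling") && k < 3L)
    stop(measure, " requires k >= 3 (its expectation uses (k-1)- and ",
         "(k-2)-words)", call. = FALSE)
  if (measure %in% BACKGROUND_MEASURES && order > k - 1L)
    stop("background order (", order, ") must be <= k - 1 for ", measure,
         call. = FALSE)
  list(measure = measure, k = k, order = order)
}

#' Precompute everything the measures need for one genome
#'
#' Builds, once per genome, the k-mer profile, the lower-order profiles used
#' by Hao and Teeling, the mononucleotide frequencies used by Willner, the
#' (r+1)-mer distribution used by JS, and the order-r background model with
#' the centered profile used by d2*, d2S and EuF. [dissimilarity()] and
#' [compute_matrix()] accept these objects wherever a [seq_record] is
#' accepted, so profiles are computed once and reused across a whole matrix.
#'
#' @param record a [seq_record].
#' @param k word length.
#' @param order background Markov order r (estimated from this genome's own
#'   sequence; each genome carries its own background).
#' @param strand_mode as in [count_kmers()].
#' @return An `onf_features` object.
#' @export
genome_features <- function(record, k, order = 2L,
                            strand_mode = c("forward", "both")) {
  stopifnot(inherits(record, "seq_record"))
  strand_mode <- match.arg(strand_mode)
  k <- as.integer(k); order <- as.integer(order)
  if (is.na(k) || k < 1L || k > 9L) stop("k must be in 1..9", call. = FALSE)
  prof <- count_kmers(record, k, strand_mode)
  feats <- list(id = record$id, k = k, order = order,
                strand_mode = strand_mode, profile = prof,
                freq = prof$counts / prof$n_positions)
  contigs <- effective_contigs(record, strand_mode)
  if (k >= 3L) {
    feats$counts_km1 <- count_words_raw(contigs, k - 1L)
    feats$counts_km2 <- count_words_raw(contigs, k - 2L)
  }
  mono <- count_words_raw(contigs, 1L)
  feats$mono_freq <- mono / sum(mono)
  r1 <- count_words_raw(contigs, order + 1L)
  if (sum(r1) > 0L) feats$freq_r1 <- r1 / sum(r1)
  if (order <= k - 1L) {
    feats$model <- estimate_markov(record, order, strand_mode)
    feats$centered <- center_profile(prof, feats$model)
  }
  structure(feats, class = "onf_features")
}

#' @export
print.onf_features <- function(x, ...) {
  cat(sprintf("<onf_features> %s: k=%d, order=%d, %s strand\n",
              x$id, x$k, x$order, x$strand_mode))
  invisible(x)
}

as_features <- function(x, k, order, strand_mode) {
  if (inherits(x, "onf_features")) {
    if (x$k != k || x$order != order || x$strand_mode != strand_mode)
      stop("features for '", x$id, "' were built with (k=", x$k, ", order=",
           x$order, ", strand=", x$strand_mode, ") but (k=", k, ", order=",
           order, ", strand=", strand_mode, ") was requested", call. = FALSE)
    return(x)
  }
  genome_features(x, k, order, strand_mode)
}

#' Dissimilarity between two genomes
#'
#' Computes one of the eleven ONF dissimilarity measures between two genomes
#' (see [onf_measures()]). Smaller scores mean greater similarity.
#'
#' @param x,y [seq_record]s or precomputed [genome_features()] objects.
#' @param measure measure id, see [onf_measures()].
#' @param k word length.
#' @param order background Markov order (used by the background-corrected
#'   measures and by JS; ignored by Eu/Ma/Ch/d2/Hao/Teeling/Willner).
#' @param strand_mode as in [count_kmers()].
#' @return A single non-negative score.
#' @export
dissimilarity <- function(x, y, measure = "d2star", k = 6L, order = 2L,
                          strand_mode = c("forward", "both")) {
  strand_mode <- match.arg(strand_mode)
  cfg <- check_measure_config(measure, k, order)
  fx <- as_features(x, cfg$k, cfg$order, strand_mode)
  fy <- as_features(y, cfg$k, cfg$order, strand_mode)
  if (fx$profile$k != fy$profile$k)
    stop("profiles have different k", call. = FALSE)
  fun <- switch(cfg$measure,
    Eu = measure_eu, Ma = measure_ma, Ch = measure_ch, d2 = measure_d2,
    JS = measure_js, d2star = measure_d2star, d2S = measure_d2s,
    Hao = measure_hao, Teeling = measure_teeling, EuF = measure_euf,
    Willner = measure_willner)
  fun(fx, fy)
}

measure_eu <- function(x, y) sqrt(sum((x$freq - y$freq)^2))

measure_ma <- function(x, y) sum(abs(x$freq - y$freq))

measure_ch <- function(x, y) max(abs(x$freq - y$freq))

measure_d2 <- function(x, y) {
  nx <- sqrt(sum(x$freq^2)); ny <- sqrt(sum(y$freq^2))
  if (nx == 0 || ny == 0)
    stop("d2 undefined for an all-zero frequency vector", call. = FALSE)
  (1 - sum(x$freq * y$freq) / (nx * ny)) / 2
}

# Jensen-Shannon divergence (log base 2, so bounded by 1) between the two
# genomes' empirical (order+1)-mer distributions. Depends on the background
# order only, not on k.
measure_js <- function(x, y) {
  p <- x$freq_r1; q <- y$freq_r1
  if (is.null(p) || is.null(q))
    stop("JS divergence needs at least one valid (order+1)-mer window in ",
         "both genomes", call. = FALSE)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

# d2*: correlation-type statistic on centered counts standardized by expected
# counts. Sums run over words with positive expectation (joint support for
# the cross term); with self-estimated backgrounds every observed word has
# positive expectation.
measure_d2star <- function(x, y) {
  cx <- x$centered; cy <- y$centered
  ex <- cx$expected; ey <- cy$expected
  sx <- ex > 0; sy <- ey > 0
  if (!any(cx$centered[sx] != 0) || !any(cy$centered[sy] != 0))
    stop("d2* degenerate: all centered counts are zero for '",
         if (!any(cx$centered[sx] != 0)) x$id else y$id, "'", call. = FALSE)
  joint <- sx & sy
  cross <- sum(cx$centered[joint] * cy$centered[joint] /
                 sqrt(ex[joint] * ey[joint]))
  denom <- sqrt(sum(cx$centered[sx]^2 / ex[sx])) *
           sqrt(sum(cy$centered[sy]^2 / ey[sy]))
  (1 - cross / denom) / 2
}

# d2S: as d2*, but each word standardized by sqrt(X~^2 + Y~^2); sums run over
# words where that scale is positive.
measure_d2s <- function(x, y) {
  a <- x$centered$centered; b <- y$centered$centered
  s <- sqrt(a^2 + b^2)
  keep <- s > 0
  if (!any(keep))
    stop("d2S degenerate: all centered counts are zero", call. = FALSE)
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  cross <- sum(a * b / s)
  denom <- sqrt(sum(a^2 / s)) * sqrt(sum(b^2 / s))
  (1 - cross / denom) / 2
}

# Hao (composition-vector / CVTree style): predicted frequency of w from its
# two (k-1)-subwords via f0_w = f(prefix) f(suffix) / f(middle); the measure
# is the cosine dissimilarity of the relative deviations a_w = (f - f0)/f0.
measure_hao <- function(x, y) {
  ax <- hao_deviation(x); ay <- hao_deviation(y)
  nx <- sqrt(sum(ax^2)); ny <- sqrt(sum(ay^2))
  if (nx == 0 || ny == 0)
    stop("Hao degenerate: zero deviation vector", call. = FALSE)
  (1 - sum(ax * ay) / (nx * ny)) / 2
}

hao_deviation <- function(f) {
  k <- f$k
  n_k <- f$profile$n_positions
  fk <- f$freq
  f1 <- f$counts_km1 / sum(f$counts_km1)
  f2 <- f$counts_km2 / sum(f$counts_km2)
  idx <- seq_len(4L^k) - 1L
  pre <- idx %/% 4L              # w_1..w_{k-1}
  suf <- idx %% 4L^(k - 1L)      # w_2..w_k
  mid <- suf %/% 4L              # w_2..w_{k-1}
  f0 <- ifelse(f2[mid + 1L] > 0,
               f1[pre + 1L] * f1[suf + 1L] / f2[mid + 1L], 0)
  ifelse(f0 > 0, (fk - f0) / f0, 0)
}

# Teeling: per-word z-score of observed counts against the maximal-order
# Markov expectation E_w = N(prefix) N(suffix) / N(middle), compared between
# genomes by Pearson correlation over the words defined in both.
measure_teeling <- function(x, y) {
  zx <- teeling_z(x); zy <- teeling_z(y)
  joint <- !is.na(zx) & !is.na(zy)
  if (sum(joint) < 2L)
    stop("Teeling degenerate: fewer than 2 jointly defined words",
         call. = FALSE)
  zx <- zx[joint]; zy <- zy[joint]
  if (sd(zx) == 0 || sd(zy) == 0)
    stop("Teeling degenerate: zero-variance z vector", call. = FALSE)
  (1 - cor(zx, zy)) / 2
}

teeling_z <- function(f) {
  k <- f$k
  nk <- as.numeric(f$profile$counts)
  n1 <- as.numeric(f$counts_km1)
  n2 <- as.numeric(f$counts_km2)
  idx <- seq_len(4L^k) - 1L
  pre <- idx %/% 4L
  suf <- idx %% 4L^(k - 1L)
  mid <- suf %/% 4L
  e <- ifelse(n2[mid + 1L] > 0, n1[pre + 1L] * n1[suf + 1L] / n2[mid + 1L], 0)
  z <- rep(NA_real_, length(nk))
  ok <- e > 0
  z[ok] <- (nk[ok] - e[ok]) / sqrt(e[ok])
  z
}

# EuF: Euclidean distance between relative deviations from the Markov
# expectation, delta_w = (N_w - E_w)/E_w, over words with positive
# expectation in both genomes (others contribute 0).
measure_euf <- function(x, y) {
  cx <- x$centered; cy <- y$centered
  joint <- cx$expected > 0 & cy$expected > 0
  dx <- cx$centered[joint] / cx$expected[joint]
  dy <- cy$centered[joint] / cy$expected[joint]
  sqrt(sum((dx - dy)^2))
}

# Willner: relative abundance ratio delta_w = f_w / prod(mononucleotide
# frequencies of w's letters), compared as the mean absolute difference over
# all 4^k words.
measure_willner <- function(x, y) {
  k <- x$k
  mean(abs(willner_delta(x) - willner_delta(y)))
}

willner_delta <- function(f) {
  k <- f$k
  idx <- seq_len(4L^k) - 1L
  denom <- rep(1, length(idx))
  for (i in seq_len(k)) {
    base_i <- (idx %/% 4L^(k - i)) %% 4L
    denom <- denom * f$mono_freq[base_i + 1L]
  }
  ifelse(denom > 0, f$freq / denom, 0)
}
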