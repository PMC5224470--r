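#' All k-mer words in lexicographic order
#'
#' Word indexing throughout the package is lexicographic over A<C<G<T (2-bit
#' encoding), matching the column order of
#' [Biostrings::oligonucleotideFrequency()].
#'
#' @param k word length.
#' @return Character vector of the 4^k words.
#' @export
kmer_words <- function(k) {
  grid <- do.call(expand.grid,
                  c(rev(replicate(k, BASES, simplify = FALSE)),
                    list(stringsAsFactors = FALSE)))
  do.call(paste0, rev(grid))
}

# Raw counts of all length-w words across a character vector of contigs.
# Windows containing N match none of the 4^w words and are dropped, which is
# exactly the package's N rule.
count_words_raw <- function(contigs, w) {
  keep <- nchar(contigs) >= w
  if (!any(keep)) return(setNames(integer(4^w), kmer_words(w)))
  m <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(contigs[keep]), width = w, step = 1L)
  counts <- if (is.null(dim(m))) m else colSums(m)
  storage.mode(counts) <- "integer"
  counts
}

#' Count k-mers in a genome
#'
#' Counts every length-k window that lies fully inside a contig and contains
#' no N. With `strand_mode = "both"` the reverse complement of every contig is
#' counted in addition (the profile of a sequence plus that of its reverse
#' complement).
#'
#' @param record a [seq_record].
#' @param k word length (1-9 supported).
#' @param strand_mode `"forward"` (default) or `"both"`.
#' @return A `kmer_profile`: list with `k`, `counts` (named integer vector of
#'   length 4^k, lexicographic), `n_positions` (total valid windows) and
#'   `source_id`.
#' @export
count_kmers <- function(record, k, strand_mode = c("forward", "both")) {
  stopifnot(inherits(record, "seq_record"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 9L)
    stop("k must be an integer in 1..9", call. = FALSE)
  contigs <- effective_contigs(record, strand_mode)
  if (max(nchar(contigs)) < k)
    stop("no contig of '", record$id, "' is at least ", k, " nt; ",
         "cannot build a k-mer profile", call. = FALSE)
  counts <- count_words_raw(contigs, k)
  n_pos <- sum(counts)
  if (n_pos == 0L)
    stop("genome '", record$id, "' has no valid (N-free) ", k,
         "-mer window", call. = FALSE)
  structure(list(k = k, counts = counts, n_positions = n_pos,
                 source_id = record$id),
            class = "kmer_profile")
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf("<kmer_profile> %s: k=%d, %d positions, %d/%d words observed\n",
              x$source_id, x$k, x$n_positions, sum(x$counts > 0),
              length(x$counts)))
  invisible(x)
}

#' Estimate an order-r Markov background model from a genome
#'
#' Transition probabilities are estimated from (r+1)-mer counts:
#' P(b | c) = n(cb) / sum_b' n(cb'). Context probabilities are the empirical
#' frequencies of contexts at transition positions (row sums of the
#' (r+1)-mer count table, normalized), so that word probabilities under the
#' model telescope to exactly 1. Contexts never observed with a successor get
#' an undefined (NA) transition row and zero context probability; no
#' pseudocounts are applied.
#'
#' @param record a [seq_record].
#' @param order Markov order r >= 0. Order 0 is an i.i.d. base model.
#' @param strand_mode as in [count_kmers()].
#' @return A `markov_model`: list with `order`, `context_probs` (length 4^r),
#'   `transition_probs` (4^r x 4 matrix), `transition_counts`, `source_id`.
#' @export
estimate_markov <- function(record, order, strand_mode = c("forward", "both")) {
  stopifnot(inherits(record, "seq_record"))
  order <- as.integer(order)
  if (is.na(order) || order < 0L)
    stop("order must be an integer >= 0", call. = FALSE)
  contigs <- effective_contigs(record, strand_mode)
  if (max(nchar(contigs)) < order + 1L)
    stop("genome '", record$id, "' too short to estimate an order-", order,
         " model (needs a ", order + 1L, " nt window)", call. = FALSE)
  counts <- count_words_raw(contigs, order + 1L)
  if (sum(counts) == 0L)
    stop("genome '", record$id, "' has no valid (N-free) window for an ",
         "order-", order, " model", call. = FALSE)
  tc <- matrix(counts, nrow = 4L^order, ncol = 4L, byrow = TRUE,
               dimnames = list(if (order > 0L) kmer_words(order) else "",
                               BASES))
  totals <- rowSums(tc)
  trans <- tc / totals # rows with 0 successors become NaN (undefined)
  ctx_probs <- totals / sum(totals)
  structure(list(order = order, context_probs = ctx_probs,
                 transition_probs = trans, transition_counts = tc,
                 source_id = record$id),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("<markov_model> %s: order %d, %d/%d contexts observed\n",
              x$source_id, x$order, sum(x$context_probs > 0),
              length(x$context_probs)))
  invisible(x)
}

# Word probabilities p_w for all 4^k words under an order-r model:
# p_w = pi(w_1..w_r) * prod_{i=r+1..k} P(w_i | w_{i-r}..w_{i-1}).
# Built by extending prefixes one base at a time; undefined transition rows
# contribute probability 0.
word_probs <- function(model, k) {
  r <- model$order
  if (r >= k)
    stop("background order (", r, ") must be <= k - 1 (k = ", k, ")",
         call. = FALSE)
  trans <- model$transition_probs
  trans[is.na(trans)] <- 0
  p <- model$context_probs # prefixes of length r (length 1 when r = 0)
  ncxt <- 4L^r
  for (m in r:(k - 1L)) {
    idx <- seq_len(4L^m) - 1L
    ctx <- idx %% ncxt
    # row i of the product = p(prefix i) * P(b | last r bases of prefix i);
    # flattening row-major appends the new base as the least significant digit
    p <- as.vector(t(p * trans[ctx + 1L, , drop = FALSE]))
  }
  names(p) <- kmer_words(k)
  p
}

#' Center a k-mer profile against a Markov background
#'
#' Computes the expected count of every word under the background model,
#' E_w = n * p_w, and the centered counts X~_w = N_w - E_w that the
#' background-corrected measures (d2*, d2S, EuF) operate on.
#'
#' @param profile a `kmer_profile`.
#' @param model a `markov_model` with `order <= k - 1`.
#' @return A `centered_profile`: list with the input `profile` and `model`
#'   plus `word_probs`, `expected` and `centered` vectors of length 4^k.
#' @export
center_profile <- function(profile, model) {
  stopifnot(inherits(profile, "kmer_profile"), inherits(model, "markov_model"))
  p <- word_probs(model, profile$k)
  expected <- profile$n_positions * p
  structure(list(profile = profile, model = model, word_probs = p,
                 expected = expected,
                 centered = as.numeric(profile$counts) - expected),
            class = "centered_profile")
}

# Order-r log-likelihood of the transitions in a genome (initial-context
# terms omitted; contributions are scored within contigs only) together with
# the number of scored transitions.
markov_loglik <- function(record, order, strand_mode = "forward") {
  contigs <- effective_contigs(record, strand_mode)
  if (max(nchar(contigs)) < order + 1L) return(NULL)
  counts <- count_words_raw(contigs, order + 1L)
  n <- sum(counts)
  if (n == 0L) return(NULL)
  tc <- matrix(counts, nrow = 4L^order, ncol = 4L, byrow = TRUE)
  totals <- rowSums(tc)
  pos <- tc > 0
  ll <- sum(tc[pos] * log(tc[pos] / totals[row(tc)[pos]]))
  list(loglik = ll, n = n)
}

#' Serialize a k-mer profile or Markov model to a JSON sidecar
#'
#' Caching format for expensive per-genome objects: a `kmer_profile` is
#' stored as `{type, id, k, n_positions, counts}` with counts as a sparse
#' word -> count map; a `markov_model` as `{type, id, order, counts}` with
#' the sparse (order+1)-mer transition counts it was estimated from.
#' [read_profile_json()] restores the object (models are re-derived from
#' the stored counts).
#'
#' @param x a `kmer_profile` or `markov_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(x, path) {
  sparse <- function(counts) {
    keep <- counts > 0
    as.list(setNames(as.integer(counts[keep]), names(counts)[keep]))
  }
  obj <- if (inherits(x, "kmer_profile")) {
    list(type = "kmer_profile", id = x$source_id, k = x$k,
         n_positions = x$n_positions, counts = sparse(x$counts))
  } else if (inherits(x, "markov_model")) {
    if (is.null(x$transition_counts))
      stop("model has no transition counts to serialize", call. = FALSE)
    tc <- as.vector(t(x$transition_counts))
    names(tc) <- kmer_words(x$order + 1L)
    list(type = "markov_model", id = x$source_id, order = x$order,
         counts = sparse(tc))
  } else stop("cannot serialize objects of class ", class(x)[1],
              call. = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a k-mer profile or Markov model from its JSON sidecar
#'
#' @param path file written by [write_profile_json()].
#' @return A `kmer_profile` or `markov_model`.
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path)
  dense <- function(sparse, w) {
    counts <- setNames(integer(4L^w), kmer_words(w))
    counts[names(sparse)] <- as.integer(unlist(sparse))
    counts
  }
  if (identical(obj$type, "kmer_profile")) {
    k <- as.integer(obj$k)
    structure(list(k = k, counts = dense(obj$counts, k),
                   n_positions = as.integer(obj$n_positions),
                   source_id = obj$id),
              class = "kmer_profile")
  } else if (identical(obj$type, "markov_model")) {
    r <- as.integer(obj$order)
    tc <- matrix(dense(obj$counts, r + 1L), nrow = 4L^r, ncol = 4L,
                 byrow = TRUE,
                 dimnames = list(if (r > 0L) kmer_words(r) else "", BASES))
    totals <- rowSums(tc)
    structure(list(order = r, context_probs = totals / sum(totals),
                   transition_probs = tc / totals, transition_counts = tc,
                   source_id = obj$id),
              class = "markov_model")
  } else stop("not a recognized sidecar file: ", path, call. = FALSE)
}

#' Select a Markov background order by BIC
#'
#' Scores orders r = 0..max_order by
#' BIC(r) = -2 logL(r) + 3 * 4^r * log(n), where logL(r) is the order-r
#' Markov log-likelihood of the within-contig transitions and n the number of
#' scored transitions, and returns the minimizer (ties go to the smaller
#' order). Used to pick the background order per sequence; on real phage
#' genomes order 2 is the typical choice.
#'
#' @param record a [seq_record].
#' @param max_order largest order to consider.
#' @param strand_mode as in [count_kmers()].
#' @return Integer order in `0..max_order`.
#' @export
select_order_bic <- function(record, max_order,
                             strand_mode = c("forward", "both")) {
  stopifnot(inherits(record, "seq_record"))
  strand_mode <- match.arg(strand_mode)
  max_order <- as.integer(max_order)
  if (is.na(max_order) || max_order < 0L)
    stop("max_order must be an integer >= 0", call. = FALSE)
  bic <- rep(NA_real_, max_order + 1L)
  for (r in 0:max_order) {
    fit <- markov_loglik(record, r, strand_mode)
    if (is.null(fit)) next
    bic[r + 1L] <- -2 * fit$loglik + 3 * 4^r * log(fit$n)
  }
  if (all(is.na(bic)))
    stop("genome '", record$id, "' too short to score any order", call. = FALSE)
  as.integer(which.min(bic) - 1L) # which.min skips NA, ties -> smaller order
}
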