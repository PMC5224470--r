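#' Read a known-truth table
#'
#' TSV with header `virus_id`, optionally `host_id`, and the six rank columns
#' (`genus` ... `domain`) giving the lineage of each virus's known host.
#' Ranks may be `unknown`; such viruses are excluded from that rank's
#' accuracy denominator.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_truth <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_truth(tab)
}

validate_truth <- function(tab) {
  need <- c("virus_id", TAX_RANKS)
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L)
    stop("truth table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$virus_id))
    stop("duplicate virus_id in truth table", call. = FALSE)
  tab
}

#' Accuracy and recall per taxonomic rank
#'
#' Accuracy at a rank is the fraction of scored predictions that match the
#' known host taxon at that rank; the denominator is the set of viruses that
#' (a) received a prediction at that rank and (b) have known (non-`unknown`)
#' truth there. Recall is the fraction of all evaluated viruses for which a
#' prediction was made at all (the cost of thresholding).
#'
#' @param predictions a `prediction_set` from [predict_nearest()] or
#'   [predict_consensus()].
#' @param truth data.frame as returned by [read_truth()].
#' @return data.frame with columns `rank`, `n_predicted`, `n_correct`,
#'   `accuracy`, `recall`.
#' @export
accuracy_by_level <- function(predictions, truth) {
  truth <- validate_truth(truth)
  viruses <- intersect(unique(predictions$virus_id), truth$virus_id)
  if (length(viruses) == 0L)
    stop("no overlap between predicted and truth virus ids", call. = FALSE)
  preds <- predictions[predictions$virus_id %in% viruses, , drop = FALSE]
  res <- lapply(TAX_RANKS, function(rk) {
    p <- preds[preds$rank == rk, , drop = FALSE]
    tr <- truth[[rk]][match(p$virus_id, truth$virus_id)]
    known <- tr != "unknown"
    made <- !is.na(p$taxon) & p$taxon != "unknown"
    scored <- known & made
    n_corr <- sum(p$taxon[scored] == tr[scored])
    data.frame(rank = rk, n_predicted = sum(scored), n_correct = n_corr,
               accuracy = if (sum(scored) > 0) n_corr / sum(scored)
                          else NA_real_,
               recall = sum(made) / length(viruses),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' ROC AUC for separating true from random virus-host pairs
#'
#' Lower dissimilarity marks the positive (true-pair) class, so
#' AUC = P(true < random) + P(true = random)/2, computed by the Mann-Whitney
#' rank statistic; this equals the trapezoidal area under the TPR-FPR curve.
#'
#' @param true_scores dissimilarities of known interacting pairs.
#' @param random_scores dissimilarities of random (non-interacting) pairs.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(true_scores, random_scores) {
  nt <- length(true_scores); nr <- length(random_scores)
  if (nt == 0L || nr == 0L)
    stop("both score lists must be non-empty", call. = FALSE)
  r <- rank(c(random_scores, true_scores)) # midranks handle ties
  u <- sum(r[seq_len(nr)]) - nr * (nr + 1) / 2 # pairs with random > true
  u / (nt * nr)
}

#' Extract true-pair and random-pair scores from a dissimilarity matrix
#'
#' For the ROC/t-test discrimination analysis: the true pairs are
#' (virus, known host) as given by the truth table; non-interacting pairs
#' are simulated by drawing, for each virus, `per_virus` hosts uniformly at
#' random with the true host excluded (most virus-host pairs do not
#' interact, so random pairs are a reasonable null).
#'
#' @param scores matrix from [compute_matrix()].
#' @param truth data.frame with `virus_id` and `host_id` columns.
#' @param per_virus random pairs drawn per virus.
#' @param seed integer seed.
#' @return List with numeric vectors `true_scores` and `random_scores`.
#' @export
pair_scores <- function(scores, truth, per_virus = 1L, seed = 1L) {
  truth <- truth[match(rownames(scores), truth$virus_id), , drop = FALSE]
  if (anyNA(truth$virus_id))
    stop("truth table lacks some viruses in the matrix", call. = FALSE)
  if (is.null(truth$host_id) || !all(truth$host_id %in% colnames(scores)))
    stop("truth table must give a host_id present in the matrix",
         call. = FALSE)
  true_idx <- match(truth$host_id, colnames(scores))
  true_scores <- scores[cbind(seq_len(nrow(scores)), true_idx)]
  random_scores <- with_seed(seed, unlist(lapply(seq_len(nrow(scores)),
    function(i) {
      others <- setdiff(seq_len(ncol(scores)), true_idx[i])
      scores[i, sample(others, min(per_virus, length(others)))]
    })))
  list(true_scores = unname(true_scores),
       random_scores = unname(random_scores))
}

#' Welch t-test between true-pair and random-pair scores
#'
#' Two-sided two-sample t-test (unequal variances) of whether the mean
#' dissimilarity of known virus-host pairs differs from that of random
#' pairs.
#'
#' @inheritParams roc_auc
#' @return The p-value.
#' @export
pair_ttest <- function(true_scores, random_scores) {
  if (length(true_scores) < 2L || length(random_scores) < 2L)
    stop("need at least 2 scores per group", call. = FALSE)
  t.test(true_scores, random_scores)$p.value
}

#' Expected accuracy of picking a host uniformly at random
#'
#' Because host databases are taxonomically unbalanced, the random-guess
#' baseline is computed empirically in closed form: at each rank it is the
#' mean, over viruses with known truth at that rank, of the fraction of hosts
#' sharing the virus's true taxon (`unknown` host labels never match).
#'
#' @param taxonomy host taxonomy data.frame.
#' @param truth truth data.frame.
#' @return data.frame with columns `rank` and `baseline`.
#' @export
random_baseline <- function(taxonomy, truth) {
  taxonomy <- validate_taxonomy(taxonomy)
  truth <- validate_truth(truth)
  if (nrow(taxonomy) == 0L || nrow(truth) == 0L)
    stop("empty taxonomy or truth table", call. = FALSE)
  res <- vapply(TAX_RANKS, function(rk) {
    tr <- truth[[rk]]
    tr <- tr[tr != "unknown"]
    if (length(tr) == 0L) return(NA_real_)
    hosts <- taxonomy[[rk]]
    mean(vapply(tr, function(t) mean(hosts == t & hosts != "unknown"), 0))
  }, 0)
  data.frame(rank = TAX_RANKS, baseline = unname(res),
             stringsAsFactors = FALSE)
}

#' Fragment-length and sequencing-error robustness sweep
#'
#' Re-runs nearest-host prediction after perturbing every virus — either
#' subsampling a contiguous fragment of each length, or subsampling a fixed
#' fragment (default 5 kb) and then applying substitution errors at each rate
#' — and scores per-rank accuracy and recall for every replicate. Host
#' profiles are computed once.
#'
#' @param viruses,hosts named lists of [seq_record]s (hosts may be
#'   precomputed [genome_features()]).
#' @param taxonomy,truth taxonomy and truth data.frames.
#' @param lengths fragment lengths in nt; `NA` means full length.
#' @param error_rates substitution rates; applied to `error_fragment`-nt
#'   subsamples.
#' @param replicates subsampling replicates per grid point.
#' @param measure,k,order measure configuration.
#' @param error_fragment fragment length used for the error grid.
#' @param threshold optional dissimilarity threshold.
#' @param seed integer seed; replicate draws derive from it.
#' @return Tidy data.frame: `grid_var` (`length` or `error_rate`), `value`,
#'   `replicate`, `rank`, `accuracy`, `recall`.
#' @export
robustness_sweep <- function(viruses, hosts, taxonomy, truth,
                             lengths = NULL, error_rates = NULL,
                             replicates = 10L, measure = "d2star", k = 6L,
                             order = 2L, error_fragment = 5000L,
                             threshold = NULL, seed = 1L) {
  hf <- lapply(hosts, as_features, k = as.integer(k),
               order = as.integer(order), strand_mode = "forward")
  run_point <- function(grid_var, value, rep_i, sub_seed) {
    perturbed <- lapply(seq_along(viruses), function(i) {
      v <- viruses[[i]]
      s <- sub_seed + i
      if (grid_var == "length") {
        if (is.na(value) || value >= max(nchar(v$contigs))) v
        else {
          f <- subsample_fragment(v, value, seed = s); f$id <- v$id; f
        }
      } else {
        f <- if (error_fragment < max(nchar(v$contigs)))
          subsample_fragment(v, error_fragment, seed = s) else v
        f <- mutate_record(f, value, seed = s + 1L)
        f$id <- v$id
        f
      }
    })
    names(perturbed) <- vapply(perturbed, `[[`, "", "id")
    m <- compute_matrix(perturbed, hf, measure, k, order)
    acc <- accuracy_by_level(predict_nearest(m, taxonomy, threshold,
                                             seed = sub_seed), truth)
    data.frame(grid_var = grid_var, value = value, replicate = rep_i,
               rank = acc$rank, accuracy = acc$accuracy, recall = acc$recall,
               stringsAsFactors = FALSE)
  }
  out <- list()
  base <- as.integer(seed)
  grid <- rbind(
    if (length(lengths) > 0L)
      data.frame(grid_var = "length", value = as.numeric(lengths)),
    if (length(error_rates) > 0L)
      data.frame(grid_var = "error_rate", value = as.numeric(error_rates)))
  if (is.null(grid) || nrow(grid) == 0L)
    stop("supply at least one of lengths or error_rates", call. = FALSE)
  for (g in seq_len(nrow(grid)))
    for (rep_i in seq_len(replicates)) {
      sub_seed <- base + 10000L * g + 100L * rep_i
      out[[length(out) + 1L]] <-
        run_point(grid$grid_var[g], grid$value[g], rep_i, sub_seed)
    }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize a robustness sweep
#'
#' Mean accuracy per grid point and rank with a normal-approximation 95%
#' interval (mean +/- 1.96 SE) across replicates.
#'
#' @param sweep data.frame from [robustness_sweep()].
#' @return data.frame with `grid_var`, `value`, `rank`, `mean_accuracy`,
#'   `lo`, `hi`, `mean_recall`.
#' @export
summarize_sweep <- function(sweep) {
  # paste-based key: NA grid values (full length) must form a group too
  key <- paste(sweep$grid_var, sweep$value, sweep$rank)
  res <- lapply(split(sweep, key), function(d) {
    m <- mean(d$accuracy)
    se <- if (nrow(d) > 1L) sd(d$accuracy) / sqrt(nrow(d)) else 0
    data.frame(grid_var = d$grid_var[1], value = d$value[1], rank = d$rank[1],
               mean_accuracy = m, lo = m - 1.96 * se, hi = m + 1.96 * se,
               mean_recall = mean(d$recall), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$grid_var, out$value, match(out$rank, TAX_RANKS)), ]
  rownames(out) <- NULL
  out
}
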