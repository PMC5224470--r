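#' Read a host taxonomy table
#'
#' Tab-separated file with header `host_id, genus, family, order, class,
#' phylum, domain`. Missing assignments are written as `unknown`; unknown
#' labels never win a consensus vote and never count as a correct prediction.
#'
#' @param path TSV file path.
#' @return A data.frame with the seven columns above.
#' @export
read_taxonomy <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_taxonomy(tab)
}

validate_taxonomy <- function(tab) {
  need <- c("host_id", TAX_RANKS)
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L)
    stop("taxonomy table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$host_id))
    stop("duplicate host_id in taxonomy table", call. = FALSE)
  tab[, need]
}

#' Compute a virus x host dissimilarity matrix
#'
#' Per-genome profiles and background models are computed once and reused
#' across rows and columns; degenerate genomes are reported together rather
#' than silently dropped.
#'
#' @param viruses,hosts named lists of [seq_record]s or of precomputed
#'   [genome_features()] objects.
#' @param measure,k,order,strand_mode measure configuration, see
#'   [dissimilarity()].
#' @return A numeric matrix (viruses as rows, hosts as columns) with the
#'   configuration attached as attribute `config`.
#' @export
compute_matrix <- function(viruses, hosts, measure = "d2star", k = 6L,
                           order = 2L, strand_mode = c("forward", "both")) {
  strand_mode <- match.arg(strand_mode)
  cfg <- check_measure_config(measure, k, order)
  if (length(viruses) == 0L || length(hosts) == 0L)
    stop("need at least one virus and one host", call. = FALSE)
  build <- function(records, what) {
    feats <- vector("list", length(records))
    bad <- character(0)
    for (i in seq_along(records)) {
      feats[[i]] <- tryCatch(
        as_features(records[[i]], cfg$k, cfg$order, strand_mode),
        error = function(e) {
          bad <<- c(bad, sprintf("%s (%s)",
                                 if (inherits(records[[i]], "seq_record"))
                                   records[[i]]$id else names(records)[i] %||% i,
                                 conditionMessage(e)))
          NULL
        })
    }
    if (length(bad) > 0L)
      stop("degenerate ", what, " genome(s): ", paste(bad, collapse = "; "),
           call. = FALSE)
    names(feats) <- vapply(feats, `[[`, "", "id")
    if (anyDuplicated(names(feats)))
      stop("duplicate ", what, " ids: ",
           paste(unique(names(feats)[duplicated(names(feats))]),
                 collapse = ", "), call. = FALSE)
    feats
  }
  vf <- build(viruses, "virus")
  hf <- build(hosts, "host")
  scores <- matrix(NA_real_, length(vf), length(hf),
                   dimnames = list(names(vf), names(hf)))
  for (i in seq_along(vf))
    for (j in seq_along(hf))
      scores[i, j] <- dissimilarity(vf[[i]], hf[[j]], cfg$measure, cfg$k,
                                    cfg$order, strand_mode)
  attr(scores, "config") <- list(measure = cfg$measure, k = cfg$k,
                                 order = cfg$order, strand_mode = strand_mode)
  scores
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_matrix_taxonomy <- function(scores, taxonomy) {
  taxonomy <- validate_taxonomy(taxonomy)
  missing <- setdiff(colnames(scores), taxonomy$host_id)
  if (length(missing) > 0L)
    stop("host(s) missing from taxonomy table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  taxonomy[match(colnames(scores), taxonomy$host_id), , drop = FALSE]
}

new_prediction_set <- function(rows, method, n = NA_integer_,
                               threshold = NA_real_, seed = NA_integer_) {
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  attr(df, "method") <- list(method = method, n = n, threshold = threshold,
                             seed = seed)
  class(df) <- c("prediction_set", class(df))
  df
}

#' Predict hosts by nearest (most similar) genome
#'
#' For each virus the host with the lowest dissimilarity is selected and its
#' lineage reported at all six ranks. If a `threshold` is given, a virus gets
#' no prediction (`NA` taxa) when its best score exceeds the threshold —
#' trading recall for accuracy. Ties on the minimum score are broken by a
#' seeded uniform draw.
#'
#' @param scores matrix from [compute_matrix()] (viruses x hosts).
#' @param taxonomy data.frame as returned by [read_taxonomy()].
#' @param threshold optional maximum dissimilarity for making a prediction.
#' @param seed integer seed for tie-breaking.
#' @return A `prediction_set` data.frame with columns `virus_id`, `rank`,
#'   `taxon`, `score`, `host_id` and `predicted`.
#' @export
predict_nearest <- function(scores, taxonomy, threshold = NULL, seed = 1L) {
  tax <- check_matrix_taxonomy(scores, taxonomy)
  rows <- with_seed(seed, lapply(rownames(scores), function(v) {
    s <- scores[v, ]
    best <- min(s)
    if (!is.null(threshold) && best > threshold)
      return(no_prediction_rows(v, best))
    cand <- which(s == best)
    pick <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
    lineage <- unlist(tax[pick, TAX_RANKS])
    data.frame(virus_id = v, rank = TAX_RANKS, taxon = unname(lineage),
               score = best, host_id = colnames(scores)[pick],
               predicted = TRUE, stringsAsFactors = FALSE)
  }))
  new_prediction_set(rows, "nearest", n = 1L,
                     threshold = threshold %||% NA_real_, seed = seed)
}

no_prediction_rows <- function(v, best) {
  data.frame(virus_id = v, rank = TAX_RANKS, taxon = NA_character_,
             score = best, host_id = NA_character_, predicted = FALSE,
             stringsAsFactors = FALSE)
}

#' Predict hosts by consensus of the top-n most similar genomes
#'
#' For each virus the `n` hosts with the lowest dissimilarities vote,
#' independently at every rank, for their taxon; the modal taxon wins
#' (`unknown` labels are excluded from the vote) and frequency ties are
#' broken by a seeded uniform draw. The optional threshold gate applies to
#' the single best score, as in [predict_nearest()]. With `n = 1` the result
#' is identical to [predict_nearest()].
#'
#' @inheritParams predict_nearest
#' @param n number of top hosts voting, `1 <= n <= ncol(scores)`.
#' @return A `prediction_set` data.frame; `host_id` lists the supporting
#'   (voting) hosts, comma-separated.
#' @export
predict_consensus <- function(scores, taxonomy, n, threshold = NULL,
                              seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L || n > ncol(scores))
    stop("n must be in 1..", ncol(scores), call. = FALSE)
  tax <- check_matrix_taxonomy(scores, taxonomy)
  rows <- with_seed(seed, lapply(rownames(scores), function(v) {
    s <- scores[v, ]
    best <- min(s)
    if (!is.null(threshold) && best > threshold)
      return(no_prediction_rows(v, best))
    # top-n by score; ties at the n-th score resolved by a seeded shuffle so
    # host column order does not matter
    ord <- order(s, sample.int(length(s)))
    top <- ord[seq_len(n)]
    supporting <- paste(colnames(scores)[top], collapse = ",")
    taxon <- vapply(TAX_RANKS, function(rk) {
      votes <- tax[[rk]][top]
      votes <- votes[votes != "unknown"]
      if (length(votes) == 0L) return(NA_character_)
      counts <- table(votes)
      winners <- names(counts)[counts == max(counts)]
      if (length(winners) > 1L)
        winners[sample.int(length(winners), 1L)] else winners
    }, "")
    data.frame(virus_id = v, rank = TAX_RANKS, taxon = unname(taxon),
               score = best, host_id = supporting, predicted = TRUE,
               stringsAsFactors = FALSE)
  }))
  new_prediction_set(rows, "consensus", n = n,
                     threshold = threshold %||% NA_real_, seed = seed)
}

#' Rank-sum test for candidate host taxa
#'
#' For one virus, tests at a given rank whether the hosts of each taxon have
#' systematically lower dissimilarity scores than all other hosts (one-sided
#' Wilcoxon rank-sum). P-values are Bonferroni-corrected by the number of
#' taxa tested; taxa significant at `alpha` are returned sorted by corrected
#' p-value. The exact test is used when the combined group size is below 30
#' and there are no ties; otherwise the normal approximation with tie
#' correction.
#'
#' @param scores_row numeric vector of one virus's dissimilarities, named by
#'   host id (one row of a [compute_matrix()] result).
#' @param taxonomy data.frame as returned by [read_taxonomy()].
#' @param rank one of genus, family, order, class, phylum, domain.
#' @param alpha significance level for the corrected p-values.
#' @return data.frame with columns `taxon`, `p`, `corrected_p` for taxa with
#'   `corrected_p < alpha`, ascending.
#' @export
ranksum_taxa <- function(scores_row, taxonomy, rank = "genus", alpha = 0.05) {
  rank <- match.arg(rank, TAX_RANKS)
  taxonomy <- validate_taxonomy(taxonomy)
  if (is.null(names(scores_row)))
    stop("scores_row must be named by host id", call. = FALSE)
  missing <- setdiff(names(scores_row), taxonomy$host_id)
  if (length(missing) > 0L)
    stop("host(s) missing from taxonomy table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  labels <- taxonomy[[rank]][match(names(scores_row), taxonomy$host_id)]
  keep <- labels != "unknown"
  scores_row <- scores_row[keep]; labels <- labels[keep]
  taxa <- unique(labels)
  if (length(taxa) < 2L)
    stop("need >= 2 distinct taxa at rank '", rank, "' for the rank-sum test",
         call. = FALSE)
  p <- vapply(taxa, function(t) {
    in_t <- labels == t
    x <- scores_row[in_t]; y <- scores_row[!in_t]
    exact <- (length(x) + length(y)) < 30L
    suppressWarnings(
      wilcox.test(x, y, alternative = "less", exact = exact)$p.value)
  }, 0)
  res <- data.frame(taxon = taxa, p = unname(p),
                    corrected_p = pmin(1, unname(p) * length(taxa)),
                    stringsAsFactors = FALSE)
  res <- res[res$corrected_p < alpha, , drop = FALSE]
  res <- res[order(res$corrected_p, res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a dissimilarity matrix as TSV
#'
#' Viruses as rows, hosts as columns, full float precision so downstream
#' thresholding round-trips exactly.
#'
#' @param scores matrix from [compute_matrix()].
#' @param path output path.
#' @export
write_matrix_tsv <- function(scores, path) {
  df <- data.frame(virus_id = rownames(scores),
                   format(scores, digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dissimilarity matrix written by [write_matrix_tsv()]
#'
#' @param path TSV path.
#' @return Numeric matrix with virus row names and host column names.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}
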