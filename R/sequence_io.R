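#' Genome sequence records
#'
#' A `seq_record` holds one genome (a complete genome or a multi-contig
#' sequencing project) as an ordered set of contigs over the alphabet
#' {A,C,G,T,N}. All downstream k-mer counting treats contigs independently, so
#' no artificial junction words are ever created. Lowercase letters are
#' upper-cased and IUPAC ambiguity codes other than N are mapped to N.
#'
#' @param contigs character vector of nucleotide sequences.
#' @param id single string identifying the genome.
#' @param names optional per-contig names (FASTA headers), kept as metadata.
#' @return An object of class `seq_record` with fields `id`, `contigs`
#'   (named character vector) and `total_length`.
#' @export
seq_record <- function(contigs, id, names = NULL) {
  if (!is.character(contigs) || length(contigs) < 1L)
    stop("contigs must be a non-empty character vector", call. = FALSE)
  if (any(nchar(contigs) == 0L))
    stop("zero-length contig in record '", id, "'", call. = FALSE)
  contigs <- normalize_nt(contigs)
  if (!is.null(names)) names(contigs) <- names
  structure(
    list(id = as.character(id), contigs = contigs,
         total_length = sum(nchar(contigs))),
    class = "seq_record")
}

# Upper-case and collapse every non-ACGT letter (IUPAC ambiguity codes, gaps,
# anything else) to N. Keeps the 4^k word space exact downstream.
normalize_nt <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s: %d contig(s), %d nt\n",
              x$id, length(x$contigs), x$total_length))
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' Reads a (possibly multi-record, possibly gzip-compressed) FASTA file into a
#' single [seq_record]. Each FASTA record becomes one contig, in file order;
#' headers are retained only as contig names.
#'
#' @param path path to a FASTA file (`.gz` accepted).
#' @param id genome identifier; defaults to the file stem.
#' @return A [seq_record].
#' @export
read_genome <- function(path, id = NULL) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e)
                    stop("not a readable FASTA file: ", path,
                         " (", conditionMessage(e), ")", call. = FALSE))
  if (length(set) == 0L)
    stop("no FASTA records in file: ", path, call. = FALSE)
  if (any(Biostrings::width(set) == 0L))
    stop("zero-length FASTA record in file: ", path, call. = FALSE)
  if (is.null(id)) {
    id <- basename(path)
    id <- sub("\\.gz$", "", id)
    id <- tools::file_path_sans_ext(id)
  }
  seq_record(as.character(set), id = id, names = names(set))
}

#' Write a genome to a FASTA file
#'
#' @param record a [seq_record].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(record, path) {
  stopifnot(inherits(record, "seq_record"))
  set <- Biostrings::DNAStringSet(record$contigs)
  if (is.null(names(record$contigs)))
    names(set) <- if (length(set) == 1L) record$id
                  else paste0(record$id, "_", seq_along(set))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a directory of FASTA files as a genome collection
#'
#' One FASTA file = one genome (virus or host sequencing project); the file
#' stem is the genome id. Ids must be unique.
#'
#' @param dir directory containing `.fa`/`.fasta`/`.fna` files (optionally
#'   `.gz`).
#' @return Named list of [seq_record]s.
#' @export
read_genome_dir <- function(dir) {
  if (!dir.exists(dir)) stop("directory not found: ", dir, call. = FALSE)
  paths <- sort(list.files(
    dir, pattern = "\\.(fa|fasta|fna)(\\.gz)?$", full.names = TRUE))
  if (length(paths) == 0L)
    stop("no FASTA files in directory: ", dir, call. = FALSE)
  records <- lapply(paths, read_genome)
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate genome ids in ", dir, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(records) <- ids
  records
}

#' Subsample a contiguous fragment from a genome
#'
#' Draws one contiguous window of `length` nt from the record, mimicking the
#' subsampling used to test how prediction accuracy depends on contig length.
#' The window never spans a contig junction: a contig is chosen with
#' probability proportional to its number of valid start positions, then the
#' start is uniform over those positions.
#'
#' @param record a [seq_record].
#' @param length fragment length in nt.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A single-contig [seq_record] with id `<id>_frag`.
#' @export
subsample_fragment <- function(record, length, seed) {
  stopifnot(inherits(record, "seq_record"))
  length <- as.integer(length)
  if (is.na(length) || length < 1L)
    stop("fragment length must be >= 1", call. = FALSE)
  widths <- nchar(record$contigs)
  n_windows <- pmax(0L, widths - length + 1L)
  if (all(n_windows == 0L))
    stop("fragment length ", length, " exceeds the longest contig of '",
         record$id, "' (", max(widths), " nt)", call. = FALSE)
  with_seed(seed, {
    contig_i <- sample.int(length(widths), 1L, prob = n_windows)
    start <- sample.int(n_windows[contig_i], 1L)
    frag <- substr(record$contigs[[contig_i]], start, start + length - 1L)
    seq_record(frag, id = paste0(record$id, "_frag"))
  })
}

#' Introduce random nucleotide substitutions
#'
#' Simulates sequencing error: each A/C/G/T position is independently
#' substituted with probability `rate`, the replacement drawn uniformly from
#' the three other bases. N positions are left unchanged and sequence length
#' is preserved.
#'
#' @param record a [seq_record].
#' @param rate substitution probability per position, in \[0, 1\].
#' @param seed integer seed.
#' @return A [seq_record] with the same contig structure.
#' @export
mutate_record <- function(record, rate, seed) {
  stopifnot(inherits(record, "seq_record"))
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate < 0 || rate > 1)
    stop("substitution rate must be in [0, 1]", call. = FALSE)
  if (rate == 0) return(record)
  with_seed(seed, {
    contigs <- vapply(record$contigs, function(s) {
      chars <- strsplit(s, "", fixed = TRUE)[[1L]]
      hit <- runif(length(chars)) < rate & chars != "N"
      n_hit <- sum(hit)
      if (n_hit > 0L) {
        # uniform over the 3 non-identical bases: offset current base by 1..3
        cur <- match(chars[hit], BASES)
        off <- sample.int(3L, n_hit, replace = TRUE)
        chars[hit] <- BASES[(cur - 1L + off) %% 4L + 1L]
      }
      paste(chars, collapse = "")
    }, "", USE.NAMES = FALSE)
    seq_record(contigs, id = record$id, names = names(record$contigs))
  })
}

# Contigs used for counting under a strand convention: "forward" counts the
# contigs as given; "both" additionally counts their reverse complements
# (doubling n_positions for N-free sequences).
effective_contigs <- function(record, strand_mode = c("forward", "both")) {
  strand_mode <- match.arg(strand_mode)
  contigs <- record$contigs
  if (strand_mode == "both") {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(contigs)))
    contigs <- c(contigs, unname(rc))
  }
  unname(contigs)
}
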