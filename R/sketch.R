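#' MinHash sketch of a genome
#'
#' Builds a bottom-`s` MinHash sketch over the canonical k-mers of a set of
#' sequences. A canonical k-mer is the lexicographic minimum of a k-mer and
#' its reverse complement, so a sequence and its reverse complement produce
#' identical sketches. K-mers overlapping non-ACGT characters are skipped and
#' counted. Hashing is deterministic for a fixed `hash_seed`.
#'
#' @param sequences a `DNAStringSet` (see [read_fasta()]), or a character
#'   vector of sequences.
#' @param k k-mer size (1..31); default 21.
#' @param s sketch size (number of smallest distinct hashes kept); default
#'   1000.
#' @param hash_seed integer seed mixed into the hash; default 42.
#' @param genome_id name attached to the sketch.
#' @return an object of class `kmer_sketch` with elements `hashes` (sorted
#'   ascending), `k`, `s`, `hash_seed`, `genome_id`, `n_skipped`.
#' @export
sketch <- function(sequences, k = 21, s = 1000, hash_seed = 42,
                   genome_id = "genome") {
  seqs <- as.character(sequences)
  if (all(nchar(seqs) < k)) {
    stop("every sequence is shorter than k = ", k)
  }
  res <- .sketch_cpp(seqs, as.integer(k), as.integer(s), as.numeric(hash_seed))
  structure(
    list(hashes = res$hashes, k = as.integer(k), s = as.integer(s),
         hash_seed = as.numeric(hash_seed), genome_id = genome_id,
         n_skipped = res$n_skipped),
    class = "kmer_sketch"
  )
}

#' @export
print.kmer_sketch <- function(x, ...) {
  cat(sprintf("MinHash sketch '%s': k=%d, s=%d, %d hashes\n",
              x$genome_id, x$k, x$s, length(x$hashes)))
  invisible(x)
}

#' Mash distance between two sketches
#'
#' Estimates the Jaccard index `j` of the two k-mer sets on the merged
#' bottom-`s` sketch (the `s` smallest hashes of the union; shared hashes in
#' that set divided by its size) and converts it to a genome distance
#' \deqn{d = -\frac{1}{k}\,\ln\frac{2j}{1+j}.}
#' Identical sketches give `d = 0`; disjoint sketches (`j = 0`) are assigned
#' the capped distance 1 so downstream tree fitting stays finite.
#'
#' @param a,b `kmer_sketch` objects with equal `k` and `hash_seed`.
#' @return a nonnegative distance (scalar).
#' @export
mash_distance <- function(a, b) {
  stopifnot(inherits(a, "kmer_sketch"), inherits(b, "kmer_sketch"))
  if (a$k != b$k) stop("sketches have different k")
  if (a$hash_seed != b$hash_seed) stop("sketches have different hash seeds")
  s <- min(a$s, b$s)
  merged <- sort(unique(c(a$hashes, b$hashes)))
  merged <- merged[seq_len(min(s, length(merged)))]
  shared <- sum(merged %in% a$hashes & merged %in% b$hashes)
  j <- shared / length(merged)
  if (j <= 0) return(1)
  d <- -log(2 * j / (1 + j)) / a$k
  min(max(d, 0), 1)
}

#' Pairwise Mash distance matrix for a set of FASTA files or sketches
#'
#' @param x a named list of `kmer_sketch` objects, or a character vector of
#'   FASTA paths (names taken from file names).
#' @param k,s,hash_seed sketch parameters used when `x` is a set of paths.
#' @return a symmetric `matrix` of distances with zero diagonal.
#' @export
mash_distance_matrix <- function(x, k = 21, s = 1000, hash_seed = 42) {
  if (is.character(x)) {
    nms <- if (!is.null(names(x))) names(x) else
      tools::file_path_sans_ext(basename(x))
    x <- lapply(seq_along(x), function(i) {
      sketch(read_fasta(x[i]), k = k, s = s, hash_seed = hash_seed,
             genome_id = nms[i])
    })
    names(x) <- nms
  }
  n <- length(x)
  labels <- vapply(x, `[[`, "", "genome_id")
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        D[i, j] <- D[j, i] <- mash_distance(x[[i]], x[[j]])
      }
    }
  }
  D
}
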