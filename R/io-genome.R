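#' Construct a whole-genome alignment match table
#'
#' The internal container for alignment matches between a query assembly and a
#' reference. Coordinates are uniformly 0-based half-open with
#' `start < end`; strand is explicit. Identity is the fraction of matching
#' bases within the aligned block.
#'
#' @param query_id,target_id character vectors of sequence names.
#' @param query_start,query_end,target_start,target_end numeric, 0-based
#'   half-open.
#' @param strand character, `"+"` or `"-"`.
#' @param identity_fraction numeric in `[0, 1]`.
#' @param mapq integer mapping quality (>= 0).
#' @return a `data.frame` of class `match_table`.
#' @export
match_table <- function(query_id = character(), query_start = numeric(),
                        query_end = numeric(), target_id = character(),
                        target_start = numeric(), target_end = numeric(),
                        strand = character(), identity_fraction = numeric(),
                        mapq = integer()) {
  df <- data.frame(
    query_id = as.character(query_id),
    query_start = as.numeric(query_start),
    query_end = as.numeric(query_end),
    target_id = as.character(target_id),
    target_start = as.numeric(target_start),
    target_end = as.numeric(target_end),
    strand = as.character(strand),
    identity_fraction = as.numeric(identity_fraction),
    mapq = as.integer(mapq),
    stringsAsFactors = FALSE
  )
  if (nrow(df) > 0) {
    stopifnot(
      all(df$query_start < df$query_end),
      all(df$target_start < df$target_end),
      all(df$strand %in% c("+", "-")),
      all(df$identity_fraction >= 0 & df$identity_fraction <= 1),
      all(df$mapq >= 0)
    )
  }
  class(df) <- c("match_table", "data.frame")
  df
}

#' Read a PAF alignment file
#'
#' Parses minimap2 PAF (>= 12 tab-separated columns). Identity is computed as
#' the number of matching bases (column 10) divided by the alignment block
#' length (column 11). PAF coordinates are already 0-based half-open and are
#' kept as-is. No filtering happens at parse time; records with mapq 0 are
#' retained.
#'
#' @param path path to a PAF file.
#' @return a [match_table()].
#' @export
read_paf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty PAF file: ", path)
    return(match_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 12L)
  if (length(bad) > 0L) {
    stop(sprintf(
      "%d malformed PAF line(s) (fewer than 12 columns); first: line %d: %s",
      length(bad), bad[1], lines[bad[1]]
    ))
  }
  col <- function(i) vapply(fields, `[[`, "", i)
  num <- function(i) {
    v <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(v)) {
      stop("non-numeric value in PAF column ", i, " at line ", which(is.na(v))[1])
    }
    v
  }
  tab <- match_table(
    query_id = col(1),
    query_start = num(3), query_end = num(4),
    target_id = col(6),
    target_start = num(8), target_end = num(9),
    strand = col(5),
    identity_fraction = num(10) / num(11),
    mapq = as.integer(num(12))
  )
  kf_log("INFO", sprintf("read_paf: %d matches from %s", nrow(tab), path),
         counts = list(n_in = nrow(tab), n_kept = nrow(tab), n_dropped = 0L))
  tab
}

#' Read a nucmer show-coords table
#'
#' Parses the tab-separated, headerless dialect produced by
#' `show-coords -qldcoHT`: positional columns S1 E1 S2 E2 LEN1 LEN2 %IDY LENR
#' LENQ COVR COVQ followed by reference and query names (extra annotation
#' columns are tolerated and ignored). Input coordinates are 1-based
#' inclusive; they are converted to the internal 0-based half-open convention.
#' A span whose end precedes its start (the reverse-strand convention) is
#' normalised to `start < end` and the strand recorded as `"-"`.
#'
#' @param path path to a show-coords output file.
#' @return a [match_table()].
#' @export
read_coords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(match_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 11L)
  if (length(bad) > 0L) {
    stop("show-coords format error: fewer than 11 columns at line ", bad[1])
  }
  n <- length(fields)
  num <- function(i) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
    if (anyNA(v)) {
      stop("non-numeric coordinate in column ", i, " at line ",
           which(is.na(v))[1])
    }
    v
  }
  s1 <- num(1); e1 <- num(2); s2 <- num(3); e2 <- num(4)
  idy <- num(7)
  nf <- vapply(fields, length, 0L)
  ref_name <- mapply(function(f, k) if (k >= 12L) f[[12L]] else "ref",
                     fields, nf)
  qry_name <- mapply(function(f, k) if (k >= 13L) f[[13L]] else "query",
                     fields, nf)
  strand <- ifelse(s2 <= e2 & s1 <= e1, "+", "-")
  rs <- pmin(s1, e1); re <- pmax(s1, e1)
  qs <- pmin(s2, e2); qe <- pmax(s2, e2)
  tab <- match_table(
    query_id = as.character(qry_name),
    query_start = qs - 1, query_end = qe,
    target_id = as.character(ref_name),
    target_start = rs - 1, target_end = re,
    strand = strand,
    identity_fraction = idy / 100,
    mapq = rep(255L, n)
  )
  kf_log("INFO", sprintf("read_coords: %d matches from %s", nrow(tab), path),
         counts = list(n_in = nrow(tab), n_kept = nrow(tab), n_dropped = 0L))
  tab
}

#' Read genome sequences from FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that additionally
#' checks for duplicate or empty records and flags records containing
#' non-ACGT characters (k-mers overlapping such positions are skipped during
#' sketching). Case is preserved; downstream consumers are case-insensitive.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] with a logical `has_ambiguous`
#'   entry in its metadata columns.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  names(seqs) <- ids
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]),
                                        collapse = ", "))
  }
  if (any(Biostrings::width(seqs) == 0L)) {
    stop("zero-length FASTA record: ", ids[Biostrings::width(seqs) == 0L][1])
  }
  freq <- Biostrings::alphabetFrequency(seqs)
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  S4Vectors::mcols(seqs)$has_ambiguous <- acgt < Biostrings::width(seqs)
  seqs
}

#' Write a match table as PAF
#'
#' Serializes a [match_table()] in minimap2 PAF layout (12 columns). The
#' matching-base count is reconstructed as `identity * target span`;
#' sequence lengths default to the largest end coordinate seen per sequence
#' when not supplied.
#'
#' @param matches a [match_table()].
#' @param path output path.
#' @param query_lengths,target_lengths optional named length vectors.
#' @return `path`, invisibly.
#' @export
write_paf <- function(matches, path, query_lengths = NULL,
                      target_lengths = NULL) {
  stopifnot(inherits(matches, "match_table"))
  qlen <- if (is.null(query_lengths)) {
    tapply(matches$query_end, matches$query_id, max)
  } else query_lengths
  tlen <- if (is.null(target_lengths)) {
    tapply(matches$target_end, matches$target_id, max)
  } else target_lengths
  alen <- matches$target_end - matches$target_start
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   matches$query_id, as.integer(qlen[matches$query_id]),
                   as.integer(matches$query_start),
                   as.integer(matches$query_end),
                   matches$strand, matches$target_id,
                   as.integer(tlen[matches$target_id]),
                   as.integer(matches$target_start),
                   as.integer(matches$target_end),
                   as.integer(round(matches$identity_fraction * alen)),
                   as.integer(alen), matches$mapq)
  writeLines(lines, path)
  invisible(path)
}
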