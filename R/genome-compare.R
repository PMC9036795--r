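#' Filter alignment matches by span length and mapping quality
#'
#' Retains matches whose reference span is at least `min_len` bases long and
#' whose mapping quality is at least `min_mapq`. Input order is preserved and
#' the read/kept/dropped counts are written to the run log. The defaults
#' mirror the analysis filter (quality > 0, span >= 1 kbp); a larger
#' `min_len` (e.g. 10 kbp) gives the display filter used for synteny plots.
#'
#' @param table a [match_table()].
#' @param min_len minimum reference span in bases.
#' @param min_mapq minimum mapping quality.
#' @return the filtered [match_table()].
#' @export
filter_matches <- function(table, min_len = 1000, min_mapq = 1) {
  stopifnot(inherits(table, "match_table"), min_len >= 0, min_mapq >= 0)
  keep <- (table$target_end - table$target_start) >= min_len &
    table$mapq >= min_mapq
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("match_table", "data.frame")
  kf_log("INFO",
         sprintf("filter_matches(min_len=%g, min_mapq=%d): kept %d of %d",
                 min_len, as.integer(min_mapq), nrow(out), nrow(table)),
         counts = list(n_in = nrow(table), n_kept = nrow(out),
                       n_dropped = nrow(table) - nrow(out)))
  out
}

#' Length-weighted sequence identity per reference chromosome
#'
#' For each reference chromosome, the identity of every match region is
#' multiplied by the match length (the reference span), summed, and divided by
#' the total match length on that chromosome:
#' \deqn{\%id = 100 \cdot \sum_i id_i \, len_i / \sum_i len_i.}
#' The caller is expected to have filtered the table (matches >= 1 kbp by
#' default) beforehand.
#'
#' @param matches a filtered [match_table()].
#' @return a `data.frame` with columns `chromosome`, `pct_id`, `n_matches`,
#'   `total_match_len`, one row per chromosome carrying at least one match.
#' @export
weighted_identity <- function(matches) {
  stopifnot(inherits(matches, "match_table"))
  if (nrow(matches) == 0L) {
    warning("no matches; returning empty summary")
    return(data.frame(chromosome = character(), pct_id = numeric(),
                      n_matches = integer(), total_match_len = numeric(),
                      stringsAsFactors = FALSE))
  }
  len <- matches$target_end - matches$target_start
  chrom <- matches$target_id
  num <- tapply(matches$identity_fraction * len, chrom, sum)
  den <- tapply(len, chrom, sum)
  out <- data.frame(
    chromosome = names(den),
    pct_id = 100 * as.numeric(num) / as.numeric(den),
    n_matches = as.integer(tapply(len, chrom, length)),
    total_match_len = as.numeric(den),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$chromosome), , drop = FALSE]
}

#' Covered fraction of each reference chromosome
#'
#' Computes, per chromosome, the fraction of reference bases covered by at
#' least one match: overlapping match intervals are merged (union) before
#' summing, so splitting a match into adjacent pieces does not change the
#' result.
#'
#' @param matches a [match_table()].
#' @param chrom_lengths named numeric vector of reference chromosome lengths.
#' @return a `data.frame` with columns `chromosome` and `pct_cov` covering
#'   every chromosome named in `chrom_lengths`.
#' @export
coverage_fraction <- function(matches, chrom_lengths) {
  stopifnot(inherits(matches, "match_table"),
            is.numeric(chrom_lengths), !is.null(names(chrom_lengths)))
  pct <- vapply(names(chrom_lengths), function(ch) {
    m <- matches[matches$target_id == ch, , drop = FALSE]
    if (nrow(m) == 0L) return(0)
    if (any(m$target_end > chrom_lengths[[ch]])) {
      stop("match beyond stated length of chromosome ", ch)
    }
    ir <- IRanges::reduce(IRanges::IRanges(start = m$target_start + 1,
                                           end = m$target_end))
    100 * sum(IRanges::width(ir)) / chrom_lengths[[ch]]
  }, 0)
  data.frame(chromosome = names(chrom_lengths), pct_cov = as.numeric(pct),
             stringsAsFactors = FALSE)
}

#' Assign contigs to reference chromosomes with order and orientation
#'
#' Each contig is assigned to the chromosome holding the largest summed
#' reference-span length of its matches. Orientation is the strand carrying
#' the majority of matched bases on the winning chromosome; order along the
#' chromosome is by the median reference position of the contig's matches.
#' A contig whose winning chromosome holds less than `ambiguous_below` of its
#' matched bases is flagged ambiguous but still assigned. Ties are broken by
#' contig name.
#'
#' @param matches a filtered [match_table()].
#' @param ambiguous_below support fraction below which the assignment is
#'   flagged; default 0.5.
#' @return a `data.frame` with columns `contig`, `chromosome`, `orientation`,
#'   `order_index`, `support_fraction`, `ambiguous`.
#' @export
assign_contigs <- function(matches, ambiguous_below = 0.5) {
  stopifnot(inherits(matches, "match_table"))
  if (nrow(matches) == 0L) {
    return(data.frame(contig = character(), chromosome = character(),
                      orientation = character(), order_index = integer(),
                      support_fraction = numeric(), ambiguous = logical(),
                      stringsAsFactors = FALSE))
  }
  len <- matches$target_end - matches$target_start
  contigs <- sort(unique(matches$query_id))
  rows <- lapply(contigs, function(ctg) {
    m <- matches$query_id == ctg
    by_chr <- tapply(len[m], matches$target_id[m], sum)
    best <- names(by_chr)[order(-as.numeric(by_chr), names(by_chr))][1]
    support <- as.numeric(by_chr[[best]]) / sum(len[m])
    on_best <- m & matches$target_id == best
    fwd <- sum(len[on_best & matches$strand == "+"])
    rev <- sum(len[on_best & matches$strand == "-"])
    midpos <- (matches$target_start[on_best] + matches$target_end[on_best]) / 2
    data.frame(
      contig = ctg, chromosome = best,
      orientation = if (rev > fwd) "reverse" else "forward",
      median_pos = weighted_median(midpos, len[on_best]),
      support_fraction = support,
      ambiguous = support < ambiguous_below,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chromosome, out$median_pos, out$contig), , drop = FALSE]
  out$order_index <- as.integer(stats::ave(
    seq_len(nrow(out)), out$chromosome, FUN = seq_along))
  rownames(out) <- NULL
  out[, c("contig", "chromosome", "orientation", "order_index",
          "support_fraction", "ambiguous")]
}

# length-weighted median of match midpoints
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' Assembly summary metrics
#'
#' Computes total assembly size, contig count, N50 (the length of the contig
#' at which the cumulative length of contigs sorted in descending order first
#' reaches half the assembly size), the rank of that contig (N50 number), the
#' longest contig, and the summed length of the four largest contigs.
#'
#' @param contig_lengths numeric vector of positive contig lengths.
#' @return a one-row `data.frame` with columns `total_size`, `n_contigs`,
#'   `n50`, `n50_number`, `longest`, `sum_top4`.
#' @export
assembly_metrics <- function(contig_lengths) {
  if (length(contig_lengths) == 0L) stop("no contig lengths given")
  stopifnot(all(contig_lengths > 0))
  s <- sort(as.numeric(contig_lengths), decreasing = TRUE)
  total <- sum(s)
  idx <- which(cumsum(s) >= total / 2)[1]
  data.frame(
    total_size = total,
    n_contigs = length(s),
    n50 = s[idx],
    n50_number = as.integer(idx),
    longest = s[1],
    sum_top4 = sum(s[seq_len(min(4L, length(s)))]),
    stringsAsFactors = FALSE
  )
}

#' Export a link table for external circular plotting
#'
#' Applies the display filter (matches spanning at least
#' `display_min_len` bases, 10 kbp by default) and drops contigs without any
#' remaining match, logging the dropped count. The output has one row per
#' link with query and target spans and identity, suitable as input for
#' external synteny/Circos tooling.
#'
#' @param matches a [match_table()].
#' @param display_min_len minimum span in bases; default 10000.
#' @return a `data.frame` of links.
#' @export
link_table <- function(matches, display_min_len = 10000) {
  kept <- filter_matches(matches, min_len = display_min_len, min_mapq = 0)
  dropped <- setdiff(unique(matches$query_id), unique(kept$query_id))
  if (length(dropped) > 0) {
    kf_log("INFO", sprintf("link_table: removed %d contig(s) without a match",
                           length(dropped)),
           counts = list(n_in = length(unique(matches$query_id)),
                         n_kept = length(unique(kept$query_id)),
                         n_dropped = length(dropped)))
  }
  out <- as.data.frame(kept)
  rownames(out) <- NULL
  out
}

#' Published assembly metrics for the sequenced Komagataella strains
#'
#' The packaged table of published assembly metrics (total size, contig
#' count, N50 and its rank, longest contig, sum of the four largest) for the
#' eight newly sequenced strains and the two pre-existing reference
#' assemblies, in Mbp.
#'
#' @return a `data.frame` with one row per assembly and a logical
#'   `new_assembly` column separating the newly sequenced strains from the
#'   reference assemblies.
#' @export
komagataella_assembly_metrics <- function() {
  utils::read.csv(system.file("extdata",
                              "komagataella_assembly_metrics_published.csv",
                              package = "komaflux", mustWork = TRUE),
                  comment.char = "#", stringsAsFactors = FALSE)
}
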