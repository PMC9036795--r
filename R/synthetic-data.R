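# Seeded generators producing inputs with the statistical structure each
# pipeline stage assumes: genome pairs with programmed divergence and
# rearrangements (plus the matching alignment table), additive tree
# distances with optional noise, and raw GC-TOFMS isotopologue intensities
# derived from known fluxes. Every generator returns its ground truth
# alongside the data; identical seeds give identical output.

.random_chromosome <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Generate a reference/query genome pair with known divergence
#'
#' Builds a random reference genome, derives a query assembly from it by
#' splitting chromosomes into contigs, inverting and reordering a subset
#' (the programmed rearrangements), and introducing point mutations at
#' `snp_rate`, and emits a directly constructed alignment match table whose
#' per-match identity equals the realised (binomially distributed) mutation
#' fraction, so the expected weighted identity is `100 (1 - snp_rate)`.
#'
#' @param seed integer seed.
#' @param n_chromosomes number of reference chromosomes; default 4.
#' @param chrom_length length of each chromosome in bases.
#' @param snp_rate per-base substitution probability in `[0, 0.3]`.
#' @param n_inversions number of contigs emitted reverse-complemented.
#' @param n_translocations number of contigs moved out of order.
#' @param n_contigs total number of query contigs (>= n_chromosomes).
#' @param dir if given, FASTA files `ref.fa` and `query.fa` are written
#'   there.
#' @return a list with `ref`, `query` (named character vectors of
#'   sequences), `matches` (a [match_table()]), `truth` (contig to
#'   chromosome map with orientation), `chrom_lengths`, and `files`.
#' @export
gen_genome_pair <- function(seed, n_chromosomes = 4, chrom_length = 100000,
                            snp_rate = 0.02, n_inversions = 1,
                            n_translocations = 1, n_contigs = 8,
                            dir = NULL) {
  stopifnot(snp_rate >= 0, snp_rate <= 0.3, n_contigs >= n_chromosomes,
            n_inversions + n_translocations <= n_contigs)
  out <- local_seed(seed, {
    ref <- stats::setNames(
      vapply(seq_len(n_chromosomes), function(i)
        .random_chromosome(chrom_length), ""),
      paste0("chr", seq_len(n_chromosomes)))
    # distribute contigs round-robin over chromosomes, cut at random points
    per_chr <- tabulate(rep(seq_len(n_chromosomes),
                            length.out = n_contigs), n_chromosomes)
    plan <- list()
    for (ci in seq_len(n_chromosomes)) {
      k <- per_chr[ci]
      cuts <- if (k > 1) {
        sort(sample(seq(round(chrom_length * 0.2),
                        round(chrom_length * 0.8)), k - 1))
      } else integer()
      bounds <- c(0, cuts, chrom_length)
      for (j in seq_len(k)) {
        plan[[length(plan) + 1L]] <- list(chrom = ci, start = bounds[j],
                                          end = bounds[j + 1])
      }
    }
    n <- length(plan)
    inverted <- sample(n, n_inversions)
    emit_order <- seq_len(n)
    if (n_translocations > 0) {
      moved <- sample(n, n_translocations)
      emit_order <- c(setdiff(emit_order, moved), moved)
    }
    contig_names <- paste0("contig", seq_len(n))
    query <- character(n)
    rows <- list()
    truth <- list()
    for (j in seq_len(n)) {
      src <- plan[[emit_order[j]]]
      seq0 <- substr(ref[[src$chrom]], src$start + 1, src$end)
      len <- nchar(seq0)
      nmut <- stats::rbinom(1, len, snp_rate)
      if (nmut > 0) {
        pos <- sample(len, nmut)
        chars <- strsplit(seq0, "")[[1]]
        chars[pos] <- vapply(chars[pos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
        seq0 <- paste(chars, collapse = "")
      }
      rev <- emit_order[j] %in% inverted
      query[j] <- if (rev) .revcomp(seq0) else seq0
      rows[[j]] <- data.frame(
        query_id = contig_names[j], query_start = 0, query_end = len,
        target_id = paste0("chr", src$chrom),
        target_start = src$start, target_end = src$end,
        strand = if (rev) "-" else "+",
        identity_fraction = 1 - nmut / len,
        mapq = 60L, stringsAsFactors = FALSE)
      truth[[j]] <- data.frame(
        contig = contig_names[j], chromosome = paste0("chr", src$chrom),
        orientation = if (rev) "reverse" else "forward",
        source_start = src$start, source_end = src$end,
        snps = nmut, stringsAsFactors = FALSE)
    }
    names(query) <- contig_names
    m <- do.call(rbind, rows)
    matches <- match_table(m$query_id, m$query_start, m$query_end,
                           m$target_id, m$target_start, m$target_end,
                           m$strand, m$identity_fraction, m$mapq)
    list(ref = ref, query = query, matches = matches,
         truth = do.call(rbind, truth),
         chrom_lengths = stats::setNames(rep(chrom_length, n_chromosomes),
                                         names(ref)))
  })
  out$files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ref_fa <- file.path(dir, "ref.fa")
    qry_fa <- file.path(dir, "query.fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(out$ref), ref_fa)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(out$query), qry_fa)
    out$files <- c(ref = ref_fa, query = qry_fa)
  }
  out
}

#' Generate tree-structured distances with optional noise
#'
#' Draws a random unrooted binary tree (or uses the named 11-taxon preset
#' mirroring the clade structure of the sequenced yeast genomes: two sister
#' species pairs, a distant three-species clade, and an outgroup) and
#' returns its additive path-length distance matrix with optional truncated
#' Gaussian noise.
#'
#' @param seed integer seed.
#' @param n_taxa number of taxa (>= 4) for random trees.
#' @param noise_sd standard deviation of additive Gaussian noise (distances
#'   truncated at 0).
#' @param preset `NULL` or `"komagataella"` for the fixed 11-taxon clade
#'   structure.
#' @return list with `D` (distance matrix) and `tree` (the generating
#'   `phylo`).
#' @export
gen_tree_distances <- function(seed, n_taxa = 8, noise_sd = 0,
                               preset = NULL) {
  tree <- if (!is.null(preset)) {
    if (preset != "komagataella") stop("unknown preset: ", preset)
    read_newick(text = paste0(
      "(((phaffii_a:0.002,phaffii_b:0.002):0.030,kurtzmanii:0.032):0.050,",
      "(((pastoris_a:0.001,pastoris_b:0.001):0.001,pastoris_c:0.002):0.030,",
      "ulmi:0.032):0.050,((mondaviorum:0.050,(populi:0.040,",
      "pseudopastoris:0.040):0.010):0.120,outgroup:0.300):0.060);"))
  } else {
    stopifnot(n_taxa >= 4)
    local_seed(seed, {
      tr <- ape::rtree(n_taxa, rooted = FALSE,
                       br = function(k) stats::runif(k, 0.02, 0.30))
      tr$tip.label <- paste0("t", seq_len(n_taxa))
      tr
    })
  }
  D <- ape::cophenetic.phylo(tree)
  D <- D[sort(rownames(D)), sort(rownames(D))]
  if (noise_sd > 0) {
    D <- local_seed(seed + 1L, {
      n <- nrow(D)
      eps <- matrix(0, n, n)
      eps[upper.tri(eps)] <- stats::rnorm(sum(upper.tri(eps)), 0, noise_sd)
      eps <- eps + t(eps)
      pmax(D + eps, 0)
    })
    diag(D) <- 0
  }
  list(D = D, tree = tree)
}

#' Synthetic derivatized-fragment table for the packaged model
#'
#' Ethoxime-TMS-style fragment ion compositions for the measurable
#' metabolites of the packaged network. These are synthetic reconstructions
#' with plausible derivative chemistry (ethoxime protection of carbonyls,
#' trimethylsilylation of hydroxyl/phosphate groups), not instrument-derived
#' values.
#'
#' @return a named list of [fragment_spec()] objects.
#' @export
synthetic_fragments <- function() {
  tab <- list(
    G6P = c("C26H65NO9PSi6", 6), GLC = c("C23H58NO6Si5", 6),
    F6P = c("C26H65NO9PSi6", 6), PG6 = c("C27H69O10PSi7", 6),
    X5P = c("C19H50NO8PSi4", 5), Ru5P = c("C19H50NO8PSi4", 5),
    R5P = c("C19H50NO8PSi4", 5), S7P = c("C27H68NO10PSi6", 7),
    PG3 = c("C15H40O7PSi4", 3), OAA = c("C13H30O5Si3", 4),
    AKG = c("C13H27NO5Si2", 5)
  )
  out <- lapply(names(tab), function(m) {
    fragment_spec(m, tab[[m]][1], as.integer(tab[[m]][2]))
  })
  stats::setNames(out, names(tab))
}

#' Generate a synthetic 13C labeling dataset from known fluxes
#'
#' Simulates steady-state backbone MDVs for the scenario's measured
#' metabolites under the given tracer and ground-truth fluxes, convolves
#' each through its fragment's natural-abundance correction matrix to raw
#' isotopologue intensities, scales to plausible peak areas, and adds
#' Gaussian noise. Returns the measurement set together with the generating
#' truth.
#'
#' @param seed integer seed.
#' @param net a `reaction_network`; default the packaged model.
#' @param scenario a [flux_scenario()]; default `"oxppp_zero"`.
#' @param tracer a [tracer_spec()]; default 1-13C xylose.
#' @param noise_sd Gaussian noise SD as a fraction of each fragment's
#'   largest clean intensity; default 0.005.
#' @param area_scale total-area scale of the raw intensities.
#' @param fragments fragment table; default [synthetic_fragments()].
#' @param path optional CSV output path (written with
#'   [write_measurements()]).
#' @return list with `measurements` (a `measurement_set`), `truth` (list
#'   with `flux` and `cids`, the clean backbone CIDs in percent), and
#'   `path`.
#' @export
gen_mfa_dataset <- function(seed, net = komagataella_model(),
                            scenario = flux_scenario("oxppp_zero"),
                            tracer = tracer_1_13c_xylose(),
                            noise_sd = 0.005, area_scale = 1e6,
                            fragments = synthetic_fragments(),
                            path = NULL) {
  v <- scenario_true_flux(net, scenario)
  mdvs <- simulate_mdv(net, v, tracer, scenario$measured)
  records <- local_seed(seed, {
    lapply(scenario$measured, function(met) {
      frag <- fragments[[met]]
      if (is.null(frag)) stop("no fragment defined for ", met)
      M <- correction_matrix(frag)
      clean <- area_scale * as.numeric(M %*% mdvs[[met]])
      sd <- max(noise_sd, 1e-4) * max(clean)
      raw <- pmax(clean + stats::rnorm(length(clean), 0, noise_sd * max(clean)),
                  0)
      list(frag = frag, raw = raw, sd = rep(sd, length(raw)))
    })
  })
  measurements <- structure(records, class = "measurement_set")
  if (!is.null(path)) write_measurements(measurements, path)
  list(
    measurements = measurements,
    truth = list(flux = v, cids = lapply(mdvs, function(m) 100 * m)),
    path = path
  )
}

#' Generate a 50:50 labeling QC sample
#'
#' Raw intensities of a fragment whose backbone follows the binomial
#' (Pascal's triangle) distribution expected from growth on a 50:50 mixture
#' of unlabeled and fully labeled carbon source.
#'
#' @param frag a [fragment_spec()].
#' @param seed integer seed.
#' @param noise_sd noise fraction as in [gen_mfa_dataset()].
#' @param area_scale total-area scale.
#' @return list with `raw` intensities and `expected` CID (percent).
#' @export
gen_qc_sample <- function(frag, seed = 1, noise_sd = 0, area_scale = 1e6) {
  n <- frag$n_backbone_carbons
  cid <- stats::dbinom(0:n, n, 0.5)
  M <- correction_matrix(frag)
  clean <- area_scale * as.numeric(M %*% cid)
  raw <- local_seed(seed, {
    pmax(clean + stats::rnorm(length(clean), 0, noise_sd * max(clean)), 0)
  })
  list(raw = raw, expected = 100 * cid)
}
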