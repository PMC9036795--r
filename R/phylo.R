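# Distance-based phylogeny: Fitch-Margoliash weighted least squares on an
# unrooted binary topology, with stepwise taxon addition over jumbled input
# orders and NNI rearrangements.
#
# Internally trees are held as a plain undirected edge list over node ids
# (tips 1..n, internal nodes above n); conversion to ape's "phylo" happens at
# the interface. This keeps insertion and NNI edits trivial.

# -- internal tree representation --------------------------------------------

.tree_new <- function(tip_ids, n_total) {
  # star tree over the given tips (>= 3) around one internal hub; internal
  # node ids start above the total tip count so they never collide with tips
  stopifnot(length(tip_ids) >= 3)
  hub <- as.integer(n_total) + 1L
  edges <- cbind(rep(hub, length(tip_ids)), as.integer(tip_ids))
  list(edges = edges, next_node = hub + 1L)
}

.tree_insert_tip <- function(tr, edge_idx, tip_id) {
  u <- tr$edges[edge_idx, 1]; v <- tr$edges[edge_idx, 2]
  w <- tr$next_node
  edges <- tr$edges[-edge_idx, , drop = FALSE]
  edges <- rbind(edges, c(u, w), c(w, v), c(w, tip_id))
  list(edges = edges, next_node = w + 1L)
}

.tree_adjacency <- function(edges) {
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges[i, 1]); b <- as.character(edges[i, 2])
    adj[[a]] <- c(adj[[a]], list(c(edges[i, 2], i)))
    adj[[b]] <- c(adj[[b]], list(c(edges[i, 1], i)))
  }
  adj
}

# edge indices on the path between two nodes (BFS; trees are tiny)
.tree_paths <- function(edges, tips) {
  adj <- .tree_adjacency(edges)
  paths <- list()
  for (from in tips) {
    # BFS from 'from' recording predecessor edge
    pred <- list()
    visited <- as.character(from)
    queue <- from
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[as.character(cur)]]) {
        key <- as.character(nb[1])
        if (!key %in% visited) {
          visited <- c(visited, key)
          pred[[key]] <- c(cur, nb[2])
          queue <- c(queue, nb[1])
        }
      }
    }
    for (to in tips) {
      if (to <= from) next
      path <- integer()
      cur <- to
      while (cur != from) {
        p <- pred[[as.character(cur)]]
        path <- c(path, p[2])
        cur <- p[1]
      }
      paths[[paste(from, to, sep = "-")]] <- path
    }
  }
  paths
}

# Fitch-Margoliash weighted least-squares fit of branch lengths (>= 0) for a
# fixed topology: minimize sum_{i<j} ((d_ij - p_ij)/d_ij)^2.
.fm_fit <- function(edges, tips, dvec, epsilon = 1e-6) {
  paths <- .tree_paths(edges, tips)
  npair <- length(paths)
  A <- matrix(0, npair, nrow(edges))
  for (i in seq_len(npair)) A[i, paths[[i]]] <- 1
  d <- dvec
  dsafe <- ifelse(d <= 0, epsilon, d)
  W <- 1 / dsafe
  fit <- pracma::lsqnonneg(A * W, d * W)
  b <- fit$x
  p <- as.numeric(A %*% b)
  crit <- sum(((d - p) / dsafe)^2)
  list(lengths = b, criterion = crit, fitted = p, A = A)
}

# pair distances for the tips currently in the tree, in .tree_paths order
.dvec_for <- function(D, tips) {
  out <- numeric()
  for (from in tips) {
    for (to in tips) {
      if (to <= from) next
      out <- c(out, D[from, to])
    }
  }
  out
}

.tree_internal_edges <- function(edges, n_tips) {
  which(edges[, 1] > n_tips & edges[, 2] > n_tips)
}

# the two NNI neighbours across internal edge e
.tree_nni <- function(tr, e, n_tips) {
  u <- tr$edges[e, 1]; v <- tr$edges[e, 2]
  u_edges <- setdiff(which(tr$edges[, 1] == u | tr$edges[, 2] == u), e)
  v_edges <- setdiff(which(tr$edges[, 1] == v | tr$edges[, 2] == v), e)
  if (length(u_edges) != 2 || length(v_edges) != 2) return(list())
  other <- function(i, node) {
    if (tr$edges[i, 1] == node) tr$edges[i, 2] else tr$edges[i, 1]
  }
  b <- other(u_edges[2], u)
  swaps <- list(c(v_edges[1], u_edges[2]), c(v_edges[2], u_edges[2]))
  lapply(swaps, function(sw) {
    ve <- sw[1]; ue <- sw[2]
    c_node <- other(ve, v)
    edges <- tr$edges
    edges[ue, ] <- c(u, c_node)
    edges[ve, ] <- c(v, b)
    list(edges = edges, next_node = tr$next_node)
  })
}

# convert internal rep (+ branch lengths per edge row) to an ape phylo
.tree_to_phylo <- function(tr, lengths, labels) {
  adj <- .tree_adjacency(tr$edges)
  n_tips <- length(labels)
  root <- max(tr$edges) # an internal node
  recurse <- function(node, parent) {
    nbs <- adj[[as.character(node)]]
    parts <- character()
    for (nb in nbs) {
      child <- nb[1]; eidx <- nb[2]
      if (!is.na(parent) && child == parent) next
      if (child <= n_tips) {
        parts <- c(parts, sprintf("%s:%.10g", labels[child], lengths[eidx]))
      } else {
        parts <- c(parts, sprintf("%s:%.10g", recurse(child, node),
                                  lengths[eidx]))
      }
    }
    paste0("(", paste(parts, collapse = ","), ")")
  }
  ape::read.tree(text = paste0(recurse(root, NA), ";"))
}

# ape phylo -> internal rep (node ids reused from ape's numbering)
.phylo_to_tree <- function(phy) {
  list(edges = phy$edge, next_node = max(phy$edge) + 1L)
}

# -- exported operations ------------------------------------------------------

#' Fit branch lengths on a fixed topology (Fitch-Margoliash criterion)
#'
#' Finds nonnegative branch lengths minimizing the weighted least-squares
#' criterion \deqn{\sum_{i<j} \left(\frac{d_{ij} - p_{ij}}{d_{ij}}\right)^2,}
#' where \eqn{p_{ij}} is the path length between leaves i and j on the tree
#' (weighting power 2). The fit is a nonnegative least-squares solve on the
#' path incidence matrix; negative branch lengths are not allowed. Zero
#' off-diagonal distances would give infinite weight and are replaced by
#' `epsilon` in the weighting, with a warning.
#'
#' @param tree an unrooted `phylo` object whose tip labels match the row
#'   names of `D`.
#' @param D symmetric distance matrix with matching labels.
#' @param epsilon substitute for zero distances in the weights.
#' @return a list with `tree` (branch lengths replaced by the fitted values),
#'   `criterion` (the minimized value), and `fitted` (tree path lengths per
#'   leaf pair, a `dist`-style vector in row-major pair order).
#' @export
evaluate_tree <- function(tree, D, epsilon = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  labels <- tree$tip.label
  if (!setequal(labels, rownames(D))) {
    stop("tree leaves and distance-matrix labels differ")
  }
  if (any(D[upper.tri(D)] <= 0)) {
    warning("zero off-diagonal distance; using epsilon weight ", epsilon)
  }
  D <- D[labels, labels]
  tr <- .phylo_to_tree(tree)
  n <- length(labels)
  fit <- .fm_fit(tr$edges, seq_len(n), .dvec_for(D, seq_len(n)),
                 epsilon = epsilon)
  phy <- .tree_to_phylo(tr, fit$lengths, labels)
  list(tree = phy, criterion = fit$criterion, fitted = fit$fitted)
}

#' Build a least-squares distance tree by stepwise addition and NNI
#'
#' For each of `n_jumbles` seeded random taxon orders, taxa are added one at
#' a time, each placed on the branch minimizing the Fitch-Margoliash
#' criterion; the completed tree is then improved by nearest-neighbour
#' interchange passes across all internal edges until no swap lowers the
#' criterion. The best tree across all jumbles is returned. Deterministic for
#' a fixed `jumble_seed`.
#'
#' @param D symmetric distance matrix (labels in `rownames`).
#' @param n_jumbles number of random addition orders; default 10.
#' @param jumble_seed seed for the addition orders; default 23893.
#' @param epsilon zero-distance substitute passed to the criterion.
#' @return a list with `tree` (an unrooted `phylo` with fitted branch
#'   lengths) and `criterion`.
#' @export
build_tree <- function(D, n_jumbles = 10, jumble_seed = 23893,
                       epsilon = 1e-6) {
  labels <- rownames(D)
  n <- length(labels)
  if (is.null(labels) || n < 3) stop("need >= 3 labelled taxa")
  stopifnot(isSymmetric(unname(D)))
  orders <- local_seed(jumble_seed, {
    lapply(seq_len(n_jumbles), function(i) sample.int(n))
  })
  best <- NULL
  for (ord in orders) {
    tr <- .tree_new(ord[1:3], n)
    for (idx in seq(4, length.out = max(0, n - 3))) {
      tip <- ord[idx]
      tips <- sort(ord[seq_len(idx)])
      dvec <- .dvec_for(D, tips)
      cand_best <- NULL
      for (e in seq_len(nrow(tr$edges))) {
        cand <- .tree_insert_tip(tr, e, tip)
        fit <- .fm_fit(cand$edges, tips, dvec, epsilon)
        if (is.null(cand_best) || fit$criterion < cand_best$fit$criterion) {
          cand_best <- list(tree = cand, fit = fit)
        }
      }
      tr <- cand_best$tree
    }
    tips <- seq_len(n)
    dvec <- .dvec_for(D, tips)
    fit <- .fm_fit(tr$edges, tips, dvec, epsilon)
    # NNI until no improvement
    repeat {
      improved <- FALSE
      for (e in .tree_internal_edges(tr$edges, n)) {
        for (nb in .tree_nni(tr, e, n)) {
          f2 <- .fm_fit(nb$edges, tips, dvec, epsilon)
          if (f2$criterion < fit$criterion - 1e-14) {
            tr <- nb; fit <- f2; improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    if (is.null(best) || fit$criterion < best$criterion) {
      best <- list(tree = tr, fit = fit, criterion = fit$criterion)
    }
  }
  phy <- .tree_to_phylo(best$tree, best$fit$lengths, labels)
  list(tree = phy, criterion = best$criterion)
}

#' Write / read trees in Newick format
#'
#' Thin wrappers around [ape::write.tree()] and [ape::read.tree()]. Writing
#' then reading returns the same tree up to rotation of children; branch
#' lengths are serialized with at least 6 significant digits.
#'
#' @param tree a `phylo` object.
#' @param path optional file path; if `NULL` the Newick string is returned.
#' @return `write_newick`: the Newick string (invisibly if written to file);
#'   `read_newick`: a `phylo` object.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 10)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname write_newick
#' @param text a Newick string (used when `path` is `NULL`).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (!is.null(path)) {
    tree <- ape::read.tree(path)
  } else {
    tree <- ape::read.tree(text = text)
  }
  if (is.null(tree)) stop("Newick parse error")
  tree
}

# run code with a temporary RNG seed, restoring global RNG state afterwards
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
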