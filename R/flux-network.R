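# Stoichiometric reaction network with carbon atom transitions.
#
# Model files are CSV with columns id, equation, reversible, block, alias.
# An equation is written with per-entry atom maps, e.g.
#   "X5P (abcde) + R5P (fghij) -> GAP (cde) + S7P (abfghij)"
# Each lowercase letter names one carbon atom; letters are unique within a
# side and must balance between the two sides (carbon conservation).
# Metabolite roles are inferred from topology: a metabolite never produced is
# an external substrate, one never consumed is a sink, everything else is
# balanced and subject to the steady-state constraint S v = 0.

.parse_side <- function(txt, rxn_id) {
  parts <- strsplit(txt, "+", fixed = TRUE)[[1]]
  entries <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^\\s*([A-Za-z0-9_.]+)\\s*\\(([A-Za-z]*)\\)\\s*$", p))[[1]]
    if (length(m) == 0) {
      stop("reaction ", rxn_id, ": cannot parse species entry '", trimws(p), "'")
    }
    list(met = m[2], atoms = strsplit(m[3], "")[[1]])
  })
  entries
}

#' Read a stoichiometric model with atom transitions
#'
#' Parses the model CSV dialect described above and validates atom maps:
#' every carbon letter must be unique within a reaction side and the letter
#' sets on both sides must be identical (no carbon appears or disappears).
#' Metabolite carbon counts are inferred from the atom maps and must be
#' consistent across reactions.
#'
#' @param path path to a model CSV.
#' @return an object of class `reaction_network`: a list with `reactions`,
#'   `metabolites` (data.frame with `id`, `n_carbons`, `role`), `S` (the
#'   stoichiometric matrix over balanced metabolites), and `dof` (number of
#'   free fluxes, i.e. reactions minus rank of S).
#' @export
read_model <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "equation", "reversible", "block")
  if (!all(need %in% names(df))) {
    stop("model file must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate reaction id: ", df$id[duplicated(df$id)][1])
  }
  reactions <- lapply(seq_len(nrow(df)), function(i) {
    eq <- df$equation[i]
    sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
    if (length(sides) != 2) stop("reaction ", df$id[i], ": need exactly one '->'")
    subs <- .parse_side(sides[1], df$id[i])
    prods <- .parse_side(sides[2], df$id[i])
    lhs <- unlist(lapply(subs, `[[`, "atoms"))
    rhs <- unlist(lapply(prods, `[[`, "atoms"))
    if (anyDuplicated(lhs) || anyDuplicated(rhs)) {
      stop("reaction ", df$id[i], ": duplicate atom letter within one side")
    }
    if (!setequal(lhs, rhs) || length(lhs) != length(rhs)) {
      stop("reaction ", df$id[i],
           ": carbon atoms not conserved between sides")
    }
    list(id = df$id[i], substrates = subs, products = prods,
         reversible = isTRUE(as.logical(df$reversible[i])),
         block = df$block[i],
         alias = if ("alias" %in% names(df)) df$alias[i] else NA_character_)
  })
  names(reactions) <- df$id

  # metabolite carbon counts and roles
  carbons <- list(); produced <- character(); consumed <- character()
  for (r in reactions) {
    for (e in r$substrates) {
      consumed <- c(consumed, e$met)
      if (r$reversible) produced <- c(produced, e$met)
      if (!is.null(carbons[[e$met]]) && carbons[[e$met]] != length(e$atoms)) {
        stop("metabolite ", e$met, " appears with inconsistent carbon counts")
      }
      carbons[[e$met]] <- length(e$atoms)
    }
    for (e in r$products) {
      produced <- c(produced, e$met)
      if (r$reversible) consumed <- c(consumed, e$met)
      if (!is.null(carbons[[e$met]]) && carbons[[e$met]] != length(e$atoms)) {
        stop("metabolite ", e$met, " appears with inconsistent carbon counts")
      }
      carbons[[e$met]] <- length(e$atoms)
    }
  }
  mets <- names(carbons)
  role <- ifelse(!mets %in% produced, "substrate",
                 ifelse(!mets %in% consumed, "sink", "balanced"))
  metabolites <- data.frame(id = mets,
                            n_carbons = as.integer(unlist(carbons[mets])),
                            role = role, stringsAsFactors = FALSE)

  balanced <- mets[role == "balanced"]
  S <- matrix(0, length(balanced), length(reactions),
              dimnames = list(balanced, names(reactions)))
  for (r in reactions) {
    for (e in r$substrates) {
      if (e$met %in% balanced) S[e$met, r$id] <- S[e$met, r$id] - 1
    }
    for (e in r$products) {
      if (e$met %in% balanced) S[e$met, r$id] <- S[e$met, r$id] + 1
    }
  }
  net <- list(reactions = reactions, metabolites = metabolites, S = S,
              rank = qr(S)$rank)
  net$dof <- length(reactions) - net$rank
  class(net) <- "reaction_network"
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf(
    "reaction_network: %d reactions (%d reversible), %d metabolites (%d balanced)\n",
    length(x$reactions), sum(vapply(x$reactions, `[[`, TRUE, "reversible")),
    nrow(x$metabolites), sum(x$metabolites$role == "balanced")))
  cat(sprintf("rank(S) = %d, free fluxes = %d\n", x$rank, x$dof))
  invisible(x)
}

#' The packaged central-carbon + xylose model
#'
#' Loads the synthetic reconstruction of the yeast central carbon metabolism
#' network shipped with the package, whose `xylose_extension` block holds the
#' five xylose reactions (transport of xylose and xylitol, xylose reductase,
#' xylitol dehydrogenase, xylulokinase).
#'
#' @return a `reaction_network`.
#' @export
komagataella_model <- function() {
  read_model(system.file("extdata", "ccm_xylose_model_synthetic.csv",
                         package = "komaflux", mustWork = TRUE))
}

#' Validate a reaction network
#'
#' Runs structural checks and returns a report rather than erroring: carbon
#' conservation per reaction (enforced at parse time and re-checked),
#' producibility and consumability of every balanced metabolite, orphan
#' detection (a metabolite that is never consumed, or never produced, and
#' does not look like a declared boundary species), and the rank and degrees
#' of freedom of the stoichiometric matrix.
#'
#' @param net a `reaction_network`.
#' @param boundary_pattern regex marking legitimate boundary metabolites
#'   (external substrates and sinks); anything else that is never produced
#'   or never consumed is reported as a violation.
#' @return a list with `violations` (character vector, empty when clean),
#'   `rank`, `dof`, `n_balanced`.
#' @export
validate_network <- function(net, boundary_pattern = "\\.(ext|bio)$") {
  stopifnot(inherits(net, "reaction_network"))
  violations <- character()
  for (i in seq_len(nrow(net$metabolites))) {
    m <- net$metabolites[i, ]
    if (m$role != "balanced" && !grepl(boundary_pattern, m$id)) {
      violations <- c(violations, sprintf(
        "%s: never %s", m$id,
        if (m$role == "substrate") "produced" else "consumed"))
    }
  }
  for (r in net$reactions) {
    lhs <- unlist(lapply(r$substrates, `[[`, "atoms"))
    rhs <- unlist(lapply(r$products, `[[`, "atoms"))
    if (anyDuplicated(lhs) || anyDuplicated(rhs)) {
      violations <- c(violations,
                      sprintf("%s: duplicate atom letter on one side", r$id))
    }
    if (!setequal(lhs, rhs)) {
      violations <- c(violations,
                      sprintf("%s: carbon not conserved", r$id))
    }
  }
  for (m in rownames(net$S)) {
    if (!any(net$S[m, ] > 0) &&
        !any(vapply(net$reactions, function(r) r$reversible &&
                      net$S[m, r$id] < 0, TRUE))) {
      violations <- c(violations, sprintf("%s: never produced", m))
    }
    if (!any(net$S[m, ] < 0) &&
        !any(vapply(net$reactions, function(r) r$reversible &&
                      net$S[m, r$id] > 0, TRUE))) {
      violations <- c(violations, sprintf("%s: never consumed", m))
    }
  }
  list(violations = violations, rank = net$rank, dof = net$dof,
       n_balanced = nrow(net$S))
}

#' Solve net fluxes from fixed and free values
#'
#' Given values for a subset of reactions (the fixed constraints plus any
#' free fluxes), solves the steady-state balance `S v = 0` for the remaining
#' net fluxes. Errors if the remaining system is underdetermined (more free
#' fluxes must be specified) or inconsistent.
#'
#' @param net a `reaction_network`.
#' @param values named numeric vector of known net fluxes.
#' @param tol consistency tolerance.
#' @return named numeric vector of net fluxes for all reactions.
#' @export
solve_fluxes <- function(net, values, tol = 1e-8) {
  rxns <- names(net$reactions)
  stopifnot(all(names(values) %in% rxns))
  unknown <- setdiff(rxns, names(values))
  S <- net$S
  rhs <- -as.numeric(S[, names(values), drop = FALSE] %*% values)
  Su <- S[, unknown, drop = FALSE]
  dec <- qr(Su)
  if (dec$rank < length(unknown)) {
    stop("flux system underdetermined: specify ",
         length(unknown) - dec$rank, " more free flux value(s)")
  }
  u <- qr.coef(dec, rhs)
  resid <- max(abs(Su %*% u - rhs))
  scale <- max(1, max(abs(c(u, values))))
  if (resid > tol * scale) {
    stop("flux constraints inconsistent (residual ", format(resid), ")")
  }
  v <- c(values, stats::setNames(as.numeric(u), unknown))[rxns]
  names(v) <- rxns
  v
}

#' Construct a flux vector (net + exchange)
#'
#' @param net a `reaction_network`.
#' @param net_flux named numeric vector of net fluxes (all reactions).
#' @param exch named numeric vector of exchange fluxes (>= 0) for reversible
#'   reactions; missing entries default to 0.
#' @return an object of class `flux_vector`.
#' @export
flux_vector <- function(net, net_flux, exch = NULL) {
  rxns <- names(net$reactions)
  stopifnot(setequal(names(net_flux), rxns))
  rev_ids <- rxns[vapply(net$reactions, `[[`, TRUE, "reversible")]
  e <- stats::setNames(rep(0, length(rev_ids)), rev_ids)
  if (!is.null(exch)) {
    stopifnot(all(names(exch) %in% rev_ids), all(exch >= 0))
    e[names(exch)] <- exch
  }
  irrev <- setdiff(rxns, rev_ids)
  bad <- irrev[net_flux[irrev] < -1e-9]
  if (length(bad) > 0) {
    stop("negative net flux on irreversible reaction(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(net = net_flux[rxns], exch = e), class = "flux_vector")
}

#' Maximum steady-state residual of a flux vector
#'
#' @param net a `reaction_network`.
#' @param v a `flux_vector` or named net-flux vector.
#' @return `max |S v|`.
#' @export
steady_state_residual <- function(net, v) {
  nv <- if (inherits(v, "flux_vector")) v$net else v
  max(abs(net$S %*% nv[colnames(net$S)]))
}

#' Per-carbon flux rates
#'
#' Converts molar net fluxes to the per-carbon reporting convention: each
#' reaction's rate is multiplied by the total number of carbon atoms it
#' transfers (the carbons on its substrate side).
#'
#' @param net a `reaction_network`.
#' @param v a `flux_vector` or named net-flux vector.
#' @return named numeric vector of per-carbon rates.
#' @export
flux_per_carbon <- function(net, v) {
  nv <- if (inherits(v, "flux_vector")) v$net else v
  nc <- vapply(net$reactions, function(r) {
    sum(vapply(r$substrates, function(e) length(e$atoms), 0L))
  }, 0L)
  nv[names(nc)] * nc
}

#' Sample a feasible flux vector
#'
#' Draws free net fluxes uniformly within their ranges, solves the remaining
#' net fluxes from `S v = 0` and the fixed values, and rejects draws that
#' violate irreversibility. Exchange fluxes for reversible reactions are
#' drawn uniformly in `[0, exch_max]`. Deterministic per `rng_seed`.
#'
#' @param net a `reaction_network`.
#' @param constraints a list with `fixed` (named values) and optionally
#'   `free_ranges` (named list of `c(lb, ub)`) and `exch_max`.
#' @param rng_seed integer seed.
#' @param max_tries rejection-sampling attempts before giving up.
#' @return a [flux_vector()].
#' @export
sample_feasible_flux <- function(net, constraints, rng_seed = 1,
                                 max_tries = 200) {
  fixed <- constraints$fixed
  ranges <- constraints$free_ranges
  exch_max <- if (is.null(constraints$exch_max)) 0 else constraints$exch_max
  rev_ids <- names(net$reactions)[vapply(net$reactions, `[[`, TRUE,
                                         "reversible")]
  irrev <- setdiff(names(net$reactions), rev_ids)
  out <- local_seed(rng_seed, {
    result <- NULL
    for (try in seq_len(max_tries)) {
      free_vals <- if (length(ranges) > 0) {
        vapply(ranges, function(rg) stats::runif(1, rg[1], rg[2]), 0)
      } else numeric()
      vals <- c(fixed, free_vals)
      v <- tryCatch(solve_fluxes(net, vals), error = function(e) NULL)
      if (is.null(v)) next
      if (any(v[irrev] < -1e-9)) next
      v[irrev] <- pmax(v[irrev], 0)
      exch <- stats::setNames(stats::runif(length(rev_ids), 0, exch_max),
                              rev_ids)
      result <- flux_vector(net, v, exch)
      break
    }
    result
  })
  if (is.null(out)) {
    stop("no feasible flux vector found under the given constraints")
  }
  out
}
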