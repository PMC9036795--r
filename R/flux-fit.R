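# Flux estimation: weighted least-squares fit of simulated to measured
# (natural-abundance-corrected) isotopologue distributions over the free net
# fluxes and exchange coordinates, with multi-start local optimization and
# Monte-Carlo percentile confidence intervals.

#' Flux-fitting scenario for the packaged model
#'
#' Bundles the constraint set used for fitting on the packaged
#' central-carbon + xylose network: xylose uptake normalized to 1, measured
#' secretion (xylitol, glucose) and biomass precursor drains fixed, and the
#' oxidative-PPP entry (`G6PDH`) free (with the drains fixed, every other
#' net flux is determined by the steady-state balance; in particular the
#' anaplerotic pyruvate-carboxylase flux must equal the summed OAA and AKG
#' drains). The scenario also carries the ground-truth free-flux and exchange
#' values used by the synthetic-data generator: `"oxppp_zero"` has zero
#' oxidative-PPP flux, `"base"` a moderate one.
#'
#' @param name `"oxppp_zero"` or `"base"`.
#' @return a list with `fixed`, `free`, `free_bounds`, `exch_free`,
#'   `free_true`, `exch_true`, `measured`.
#' @export
flux_scenario <- function(name = c("oxppp_zero", "base")) {
  name <- match.arg(name)
  fixed <- c(XYLt = 1, XOLt = 0.05, G6Pase = 0.02,
             BM_R5P = 0.05, BM_E4P = 0.03, BM_G6P = 0.05, BM_GAP = 0.03,
             BM_PG3 = 0.05, BM_PYR = 0.05, BM_ACA = 0.03, BM_OAA = 0.05,
             BM_AKG = 0.05)
  list(
    name = name,
    fixed = fixed,
    free = "G6PDH",
    free_bounds = rbind(G6PDH = c(0, 1)),
    exch_free = c("RPE", "RPI", "TKT1", "TAL", "TKT2", "PGI", "FBA"),
    free_true = c(G6PDH = if (name == "oxppp_zero") 0 else 0.15),
    exch_true = c(RPE = 0.2, RPI = 0.2, TKT1 = 0.05, TAL = 0.05,
                  TKT2 = 0.05, PGI = 0.3, FBA = 0.05, GAPDH = 0),
    measured = c("G6P", "GLC", "F6P", "PG6", "X5P", "Ru5P", "R5P", "S7P",
                 "PG3", "OAA", "AKG")
  )
}

#' Ground-truth flux vector of a scenario
#' @param net a `reaction_network`.
#' @param scenario a [flux_scenario()].
#' @return a [flux_vector()].
#' @export
scenario_true_flux <- function(net, scenario) {
  v <- solve_fluxes(net, c(scenario$fixed, scenario$free_true))
  flux_vector(net, v, scenario$exch_true)
}

# map a raw exchange coordinate in [0, 1) to an exchange flux in [0, inf)
.exch_map <- function(x) x / (1 - x)
.exch_unmap <- function(e) e / (1 + e)

# build the SSR objective over theta = (free net fluxes, raw exchange coords)
.make_objective <- function(net, cids, tracer, scenario, decomp, natural) {
  if (inherits(tracer, "tracer_spec")) tracer <- list(tracer)
  tracers <- stats::setNames(tracer, vapply(tracer, `[[`, "", "substrate"))
  rxns <- names(net$reactions)
  irrev <- rxns[!vapply(net$reactions, `[[`, TRUE, "reversible")]
  rev_ids <- setdiff(rxns, irrev)
  nfree <- length(scenario$free)
  meas_mets <- vapply(cids, `[[`, "", "metabolite")
  meas_cid <- lapply(cids, `[[`, "cid")
  meas_sd <- lapply(cids, `[[`, "sd")
  ncarb <- stats::setNames(net$metabolites$n_carbons, net$metabolites$id)
  target_keys <- vapply(meas_mets, function(m) {
    .emu_key(m, seq_len(ncarb[[m]]))
  }, "")
  input_mids <- .emu_input_mids(decomp, tracers, natural)
  # the balance solve is affine in the free-flux values: precompute the base
  # solution and one direction per free flux
  zero_free <- stats::setNames(rep(0, nfree), scenario$free)
  v0 <- solve_fluxes(net, c(scenario$fixed, zero_free))
  dirs <- vapply(seq_len(nfree), function(i) {
    ei <- zero_free; ei[i] <- 1
    solve_fluxes(net, c(scenario$fixed, ei)) - v0
  }, v0)
  function(theta) {
    vnet <- v0 + as.numeric(dirs %*% theta[seq_len(nfree)])
    names(vnet) <- names(v0)
    neg <- pmin(vnet[irrev], 0)
    penalty <- 1e8 * sum(neg^2)
    vnet[irrev] <- pmax(vnet[irrev], 0)
    exch <- stats::setNames(rep(0, length(rev_ids)), rev_ids)
    exch[scenario$exch_free] <-
      .exch_map(theta[nfree + seq_along(scenario$exch_free)])
    fv <- structure(list(net = vnet, exch = exch), class = "flux_vector")
    vexp <- .expand_fluxes(net, fv, decomp$expanded)
    mids <- tryCatch(
      .emu_solve(decomp, vexp, tracers, natural = natural,
                 input_mids = input_mids),
      error = function(e) NULL)
    if (is.null(mids)) return(1e10)
    ssr <- penalty
    for (i in seq_along(meas_mets)) {
      sim <- 100 * mids[[target_keys[i]]]
      ssr <- ssr + sum(((sim - meas_cid[[i]]) / meas_sd[[i]])^2)
    }
    ssr
  }
}

#' Fit metabolic fluxes to corrected isotopologue measurements
#'
#' Minimizes the weighted sum of squared residuals
#' \deqn{\sum_{f,i} \left(\frac{CID^{sim}_{f,i} - CID^{meas}_{f,i}}{SD_{f,i}}\right)^2}
#' over the scenario's free net fluxes and the exchange coordinates of its
#' reversible reactions, subject to `S v = 0`, irreversibility, and the
#' fixed uptake/secretion/drain constraints. Optimization is bounded
#' quasi-Newton (L-BFGS-B) from `n_restarts` seeded random starting points;
#' the best solution is returned.
#'
#' @param net a `reaction_network`.
#' @param meas a `cid_set` from [correct_measurements()] (or a raw
#'   `measurement_set`, which is corrected first).
#' @param tracer a [tracer_spec()].
#' @param scenario a [flux_scenario()]-style constraint list.
#' @param n_restarts number of random multi-starts; default 10.
#' @param rng_seed seed for the starting points.
#' @param natural natural 13C abundance used in the simulation.
#' @param maxit optimizer iteration cap per start.
#' @param theta0 optional explicit starting point (prepended to the
#'   multi-start list).
#' @param decomp optional precomputed [emu_decompose()] result for the
#'   measured metabolites (reused across refits).
#' @param polish rerun the optimizer once from the best solution; settles
#'   boundary optima cleanly (skipped inside Monte-Carlo refits for speed).
#' @return an object of class `flux_fit`: list with `flux` (fitted
#'   [flux_vector()]), `ssr`, `theta`, `convergence`, `n_restarts`,
#'   `residuals` (per measured fragment), `scenario`.
#' @export
fit_fluxes <- function(net, meas, tracer, scenario, n_restarts = 10,
                       rng_seed = 1, natural = 0.0107, maxit = 200,
                       theta0 = NULL, decomp = NULL, polish = TRUE) {
  if (inherits(meas, "measurement_set")) meas <- correct_measurements(meas)
  if (length(meas) == 0) stop("no measurements to fit")
  meas_mets <- vapply(meas, `[[`, "", "metabolite")
  unknown <- setdiff(meas_mets, net$metabolites$id)
  if (length(unknown) > 0) {
    stop("measured metabolite(s) not in network: ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(decomp)) decomp <- emu_decompose(net, unique(meas_mets))
  obj <- .make_objective(net, meas, tracer, scenario, decomp, natural)
  nfree <- length(scenario$free)
  nex <- length(scenario$exch_free)
  lower <- c(scenario$free_bounds[, 1], rep(0, nex))
  upper <- c(scenario$free_bounds[, 2], rep(0.95, nex))
  starts <- local_seed(rng_seed, {
    lapply(seq_len(n_restarts), function(i) {
      stats::runif(nfree + nex, lower, upper)
    })
  })
  if (!is.null(theta0)) starts <- c(list(theta0), starts)
  best <- NULL
  for (th0 in starts) {
    res <- tryCatch(
      stats::optim(th0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("no optimization start converged")
  if (polish) {
    # a restarted L-BFGS-B from the optimum settles boundary solutions
    # cleanly and yields the meaningful convergence status
    again <- tryCatch(
      stats::optim(best$par, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(again) && again$value <= best$value) best <- again
  }
  theta <- best$par
  free_vals <- stats::setNames(theta[seq_len(nfree)], scenario$free)
  vnet <- solve_fluxes(net, c(scenario$fixed, free_vals))
  rxns <- names(net$reactions)
  irrev <- rxns[!vapply(net$reactions, `[[`, TRUE, "reversible")]
  vnet[irrev] <- pmax(vnet[irrev], 0)
  exch <- stats::setNames(
    .exch_map(theta[nfree + seq_len(nex)]), scenario$exch_free)
  fv <- flux_vector(net, vnet, exch)
  # per-fragment residual contributions at the optimum
  tracers <- if (inherits(tracer, "tracer_spec")) list(tracer) else tracer
  tracers <- stats::setNames(tracers, vapply(tracers, `[[`, "", "substrate"))
  vexp <- .expand_fluxes(net, fv, decomp$expanded)
  mids <- .emu_solve(decomp, vexp, tracers, natural = natural)
  ncarb <- stats::setNames(net$metabolites$n_carbons, net$metabolites$id)
  resid <- vapply(meas, function(r) {
    sim <- 100 * mids[[.emu_key(r$metabolite, seq_len(ncarb[[r$metabolite]]))]]
    sum(((sim - r$cid) / r$sd)^2)
  }, 0)
  names(resid) <- meas_mets
  structure(list(flux = fv, ssr = best$value, theta = theta,
                 convergence = best$convergence == 0,
                 n_restarts = length(starts), residuals = resid,
                 scenario = scenario),
            class = "flux_fit")
}

#' @export
print.flux_fit <- function(x, ...) {
  cat(sprintf("flux_fit: SSR = %.4g (%d starts, converged: %s)\n",
              x$ssr, x$n_restarts, x$convergence))
  fv <- x$flux$net[x$scenario$free]
  cat("free fluxes:", paste(sprintf("%s = %.4g", names(fv), fv),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Monte-Carlo confidence intervals for fitted fluxes
#'
#' Resamples the measured CIDs (independent Gaussian noise at each
#' isotopologue's SD, clipped at zero and rescaled to sum 100), refits from
#' the point estimate, and reports percentile intervals of the resampled net
#' fluxes at the requested level. Deterministic for a fixed seed.
#'
#' @param net a `reaction_network`.
#' @param meas a `cid_set` (or `measurement_set`).
#' @param tracer a [tracer_spec()].
#' @param scenario the scenario used for the fit.
#' @param fit the [fit_fluxes()] result.
#' @param n_samples Monte-Carlo samples; default 1000.
#' @param level confidence level; default 0.95.
#' @param rng_seed seed.
#' @param maxit optimizer cap per refit (warm-started).
#' @param max_fail_fraction error out when more refits than this fail.
#' @return an object of class `flux_ci`: list with `lower`, `upper` (named
#'   over reactions), `level`, `n_samples`, `samples` (matrix of resampled
#'   net fluxes).
#' @export
monte_carlo_ci <- function(net, meas, tracer, scenario, fit,
                           n_samples = 1000, level = 0.95, rng_seed = 1,
                           maxit = 40, max_fail_fraction = 0.2) {
  if (inherits(meas, "measurement_set")) meas <- correct_measurements(meas)
  stopifnot(inherits(fit, "flux_fit"), n_samples >= 2, level > 0, level < 1)
  meas_mets <- vapply(meas, `[[`, "", "metabolite")
  decomp <- emu_decompose(net, unique(meas_mets))
  rxns <- names(net$reactions)
  samples <- matrix(NA_real_, n_samples, length(rxns),
                    dimnames = list(NULL, rxns))
  n_fail <- 0
  local_seed(rng_seed, {
    for (b in seq_len(n_samples)) {
      pert <- lapply(meas, function(r) {
        x <- r$cid + stats::rnorm(length(r$cid), 0, r$sd)
        x <- pmax(x, 0)
        if (sum(x) <= 0) x <- r$cid
        r$cid <- 100 * x / sum(x)
        r
      })
      class(pert) <- "cid_set"
      refit <- tryCatch(
        fit_fluxes(net, pert, tracer, scenario, n_restarts = 0,
                   rng_seed = rng_seed + b, maxit = maxit,
                   theta0 = fit$theta, decomp = decomp, polish = FALSE),
        error = function(e) NULL)
      if (is.null(refit)) {
        n_fail <- n_fail + 1
      } else {
        samples[b, ] <- refit$flux$net[rxns]
      }
    }
  })
  if (n_fail > max_fail_fraction * n_samples) {
    stop(sprintf("%d of %d Monte-Carlo refits failed", n_fail, n_samples))
  }
  ok <- samples[stats::complete.cases(samples), , drop = FALSE]
  alpha <- (1 - level) / 2
  lower <- apply(ok, 2, stats::quantile, probs = alpha, names = FALSE)
  upper <- apply(ok, 2, stats::quantile, probs = 1 - alpha, names = FALSE)
  structure(list(lower = lower, upper = upper, level = level,
                 n_samples = n_samples, n_failed = n_fail, samples = ok),
            class = "flux_ci")
}

#' @export
print.flux_ci <- function(x, ...) {
  cat(sprintf("flux_ci: %d%% percentile intervals from %d samples (%d failed)\n",
              round(100 * x$level), x$n_samples, x$n_failed))
  invisible(x)
}
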