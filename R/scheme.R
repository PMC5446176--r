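#' Species of the exchange scheme
#'
#' The mant-labeled and unlabeled nucleotide pools are distinct species with
#' identical rate constants (the label is assumed kinetically silent); the
#' suffix \code{m} marks the labeled pool.
#'
#' @return Character vector of the 15 species names.
#' @export
species_names <- function() {
  c("Tu", "TuGDPm", "TuGDP", "TuGTPm", "TuGTP", "TuTs",
    "TuGDPmTs", "TuGDPTs", "TuGTPmTs", "TuGTPTs",
    "GDPm", "GDP", "GTPm", "GTP", "Ts")
}

#' Species whose concentration carries the mant FRET signal
#' @return Character vector of mant-bound EF-Tu complexes.
#' @export
mant_bound_species <- function() c("TuGDPm", "TuGTPm", "TuGDPmTs", "TuGTPmTs")

#' Initial species state
#'
#' Builds a full named concentration vector (molar), zero for anything not
#' supplied.
#'
#' @param ... named concentrations in molar, names from
#'   \code{\link{species_names}}.
#' @return Named numeric vector over all 15 species.
#' @export
species_state <- function(...) {
  given <- c(...)
  y <- stats::setNames(numeric(length(species_names())), species_names())
  if (length(given)) {
    unknown <- setdiff(names(given), species_names())
    if (length(unknown)) {
      stop("unknown species: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(given < 0)) stop("concentrations must be >= 0", call. = FALSE)
    y[names(given)] <- given
  }
  y
}

#' Assemble the mass-action reaction system
#'
#' Builds the elementary mass-action reaction network of the exchange scheme
#' over the labeled and unlabeled nucleotide pools. The topology is fixed;
#' a zero rate constant leaves its reaction in place with identically zero
#' flux. When \code{include_direct_ts_path} is \code{FALSE} the direct
#' Tu + Ts binding step (k2/k2r) is omitted.
#'
#' @param params a \code{\link{rate_params}} object.
#' @param include_direct_ts_path include the direct EF-Tu + EF-Ts binding path?
#' @return An object of class \code{reaction_system}: species, stoichiometry
#'   matrix, reactant index matrix, rate-constant vector and a reactions table.
#' @export
assemble_scheme <- function(params, include_direct_ts_path = TRUE) {
  stopifnot(is_rate_params(params))
  sp <- species_names()
  rx <- list()
  add <- function(name, k, reactants, products, pair) {
    rx[[length(rx) + 1L]] <<- list(name = name, k = k,
                                   reactants = match(reactants, sp),
                                   products = match(products, sp),
                                   pair = pair)
  }
  add_rev <- function(pair, kf, kr, lhs, rhs) {
    add(paste0(pair, ".fwd"), kf, lhs, rhs, pair)
    add(paste0(pair, ".rev"), kr, rhs, lhs, pair)
  }
  for (lab in c("m", "")) {
    GDP <- paste0("GDP", lab); GTP <- paste0("GTP", lab)
    TuGDP <- paste0("TuGDP", lab); TuGTP <- paste0("TuGTP", lab)
    TuGDPTs <- paste0("TuGDP", lab, "Ts"); TuGTPTs <- paste0("TuGTP", lab, "Ts")
    tag <- if (lab == "m") ".mant" else ".unlab"
    add_rev(paste0("gdp_assoc", tag), params[["k1"]], params[["k1r"]],
            c("Tu", GDP), TuGDP)
    add_rev(paste0("ts_on_gdp", tag), params[["k3"]], params[["k3r"]],
            c(TuGDP, "Ts"), TuGDPTs)
    add_rev(paste0("gdp_on_tuts", tag), params[["k4"]], params[["k4r"]],
            c("TuTs", GDP), TuGDPTs)
    add_rev(paste0("gtp_assoc", tag), params[["k5"]], params[["k5r"]],
            c("Tu", GTP), TuGTP)
    add_rev(paste0("ts_on_gtp", tag), params[["k6"]], params[["k6r"]],
            c(TuGTP, "Ts"), TuGTPTs)
    add_rev(paste0("gtp_on_tuts", tag), params[["k7"]], params[["k7r"]],
            c("TuTs", GTP), TuGTPTs)
  }
  if (isTRUE(include_direct_ts_path)) {
    add_rev("ts_direct", params[["k2"]], params[["k2r"]], c("Tu", "Ts"), "TuTs")
  }
  n_rx <- length(rx)
  S <- matrix(0, nrow = length(sp), ncol = n_rx,
              dimnames = list(sp, vapply(rx, `[[`, "", "name")))
  reactant_idx <- matrix(NA_integer_, nrow = n_rx, ncol = 2L)
  k <- numeric(n_rx)
  for (j in seq_len(n_rx)) {
    r <- rx[[j]]
    for (i in r$reactants) S[i, j] <- S[i, j] - 1
    for (i in r$products) S[i, j] <- S[i, j] + 1
    reactant_idx[j, seq_along(r$reactants)] <- r$reactants
    k[j] <- r$k
  }
  reactions <- data.frame(
    name = vapply(rx, `[[`, "", "name"),
    pair = vapply(rx, `[[`, "", "pair"),
    k = k,
    stringsAsFactors = FALSE
  )
  structure(list(species = sp, S = S, reactant_idx = reactant_idx, k = k,
                 reactions = reactions, params = params,
                 include_direct_ts_path = isTRUE(include_direct_ts_path)),
            class = "reaction_system")
}

reaction_fluxes <- function(system, y) {
  i1 <- system$reactant_idx[, 1L]
  i2 <- system$reactant_idx[, 2L]
  v <- system$k * y[i1]
  has2 <- !is.na(i2)
  v[has2] <- v[has2] * y[i2[has2]]
  v
}

scheme_deriv <- function(t, y, system) {
  v <- reaction_fluxes(system, y)
  list(as.numeric(system$S %*% v))
}

#' Integrate the reaction system
#'
#' Adaptive-step stiff integration (\code{deSolve::lsoda}) of the mass-action
#' ODEs. Default tolerances are tight enough that the conservation totals
#' (EF-Tu, EF-Ts, each nucleotide pool) hold to better than 1e-9 relative
#' over the time horizons used in the generators.
#'
#' @param system a \code{reaction_system} from \code{\link{assemble_scheme}}.
#' @param initial named concentration vector (molar) over all species, e.g.
#'   from \code{\link{species_state}}.
#' @param t_end end time (s), > 0.
#' @param grid optional explicit time grid (s, starting at 0, increasing).
#' @param n_points number of intervals when \code{grid} is NULL.
#' @param rtol,atol relative / absolute integration tolerances (molar).
#' @return Object of class \code{trajectory}: \code{time}, concentration
#'   matrix \code{conc} (rows = time points), generating \code{params} and
#'   integrator \code{diagnostics}.
#' @export
simulate_trajectory <- function(system, initial, t_end = NULL, grid = NULL,
                                n_points = 400, rtol = 1e-10, atol = 1e-16) {
  stopifnot(inherits(system, "reaction_system"))
  y0 <- species_state()
  y0[names(initial)] <- initial
  if (any(y0 < 0)) stop("initial concentrations must be >= 0", call. = FALSE)
  if (is.null(grid)) {
    if (is.null(t_end) || t_end <= 0) stop("t_end must be > 0", call. = FALSE)
    grid <- seq(0, t_end, length.out = n_points + 1L)
  } else {
    if (grid[1] != 0 || is.unsorted(grid, strictly = TRUE)) {
      stop("grid must start at 0 and be strictly increasing", call. = FALSE)
    }
  }
  out <- deSolve::lsoda(y = y0, times = grid, func = scheme_deriv,
                        parms = system, rtol = rtol, atol = atol,
                        maxsteps = 50000)
  istate <- attr(out, "istate")[1L]
  diag <- list(istate = istate, n_steps = attr(out, "istate")[2L])
  if (istate < 0) {
    stop(sprintf(
      "integrator failed (istate = %d) at t = %.6g s; last accepted step returned",
      istate, max(out[, "time"])), call. = FALSE)
  }
  conc <- unclass(out)[, -1L, drop = FALSE]
  structure(list(time = out[, "time"], conc = conc, params = system$params,
                 system = system, diagnostics = diag),
            class = "trajectory")
}

#' Conserved pool totals of a concentration matrix
#'
#' Sums species into the six conserved pools (EF-Tu, EF-Ts and the four
#' nucleotide pools); each row of the result corresponds to a row (time
#' point) of \code{conc}.
#'
#' @param conc species concentration matrix with named columns (a single
#'   state vector can be passed as a one-row matrix).
#' @return Matrix with columns \code{Tu}, \code{Ts}, \code{GDPm},
#'   \code{GDP}, \code{GTPm}, \code{GTP}.
#' @export
pool_totals <- function(conc) {
  if (is.null(dim(conc))) conc <- matrix(conc, nrow = 1,
                                         dimnames = list(NULL, names(conc)))
  gm <- function(cols) rowSums(conc[, cols, drop = FALSE])
  cbind(
    Tu  = gm(c("Tu", "TuGDPm", "TuGDP", "TuGTPm", "TuGTP", "TuTs",
               "TuGDPmTs", "TuGDPTs", "TuGTPmTs", "TuGTPTs")),
    Ts  = gm(c("Ts", "TuTs", "TuGDPmTs", "TuGDPTs", "TuGTPmTs", "TuGTPTs")),
    GDPm = gm(c("GDPm", "TuGDPm", "TuGDPmTs")),
    GDP  = gm(c("GDP", "TuGDP", "TuGDPTs")),
    GTPm = gm(c("GTPm", "TuGTPm", "TuGTPmTs")),
    GTP  = gm(c("GTP", "TuGTP", "TuGTPTs"))
  )
}

#' Maximum relative conservation error of a trajectory
#'
#' @param traj a \code{trajectory}.
#' @return Largest relative deviation of any conserved pool (EF-Tu, EF-Ts,
#'   each of the four nucleotide pools) from its initial total; pools with
#'   zero initial total must stay exactly zero.
#' @export
conservation_error <- function(traj) {
  tot <- pool_totals(traj$conc)
  t0 <- tot[1L, ]
  err <- 0
  for (j in seq_along(t0)) {
    dev <- abs(tot[, j] - t0[j])
    err <- max(err, if (t0[j] > 0) max(dev) / t0[j] else max(dev))
  }
  err
}

eq_constants <- function(params) {
  rat <- function(num, den) if (den > 0) num / den else if (num > 0) Inf else 0
  list(K1 = rat(params[["k1"]], params[["k1r"]]),
       K2 = rat(params[["k2"]], params[["k2r"]]),
       K3 = rat(params[["k3"]], params[["k3r"]]),
       K4 = rat(params[["k4"]], params[["k4r"]]),
       K5 = rat(params[["k5"]], params[["k5r"]]),
       K6 = rat(params[["k6"]], params[["k6r"]]),
       K7 = rat(params[["k7"]], params[["k7r"]]))
}

#' Equilibrium state of the exchange scheme
#'
#' Solves the detailed-balanced equilibrium of the binding scheme from its
#' equilibrium constants by a damped Newton iteration on the free-species
#' mass balances. The effective EF-Ts association constant is taken from the
#' direct path when present, otherwise from either nucleotide branch
#' (\code{K1*K3/K4} or \code{K5*K6/K7}); when several definitions are
#' available they must agree (thermodynamic consistency), otherwise an error
#' is raised because a detailed-balanced equilibrium does not exist.
#'
#' @param system a \code{reaction_system}.
#' @param totals named totals (molar) with any of \code{Tu}, \code{Ts},
#'   \code{GDPm}, \code{GDP}, \code{GTPm}, \code{GTP}; omitted pools are 0.
#' @param tol relative tolerance on the mass balances.
#' @return Named species concentration vector at equilibrium.
#' @export
equilibrium_state <- function(system, totals, tol = 1e-12) {
  stopifnot(inherits(system, "reaction_system"))
  pool_names <- c("Tu", "Ts", "GDPm", "GDP", "GTPm", "GTP")
  tt <- stats::setNames(numeric(6), pool_names)
  unknown <- setdiff(names(totals), pool_names)
  if (length(unknown)) stop("unknown pools: ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  tt[names(totals)] <- unlist(totals)
  if (any(tt < 0)) stop("totals must be >= 0", call. = FALSE)
  K <- eq_constants(system$params)

  # effective Ts association constant, with consistency check across routes
  # (only relevant when EF-Ts is actually present)
  Kts <- 0
  if (tt[["Ts"]] > 0) {
    kts_routes <- c()
    if (system$include_direct_ts_path && K$K2 > 0) kts_routes <- c(kts_routes, K$K2)
    if (K$K1 > 0 && K$K3 > 0 && K$K4 > 0 && is.finite(K$K4)) {
      kts_routes <- c(kts_routes, K$K1 * K$K3 / K$K4)
    }
    if (K$K5 > 0 && K$K6 > 0 && K$K7 > 0 && is.finite(K$K7)) {
      kts_routes <- c(kts_routes, K$K5 * K$K6 / K$K7)
    }
    if (length(kts_routes) > 1 &&
        diff(range(kts_routes)) > 1e-6 * max(kts_routes)) {
      stop("rate constants violate thermodynamic consistency; ",
           "no detailed-balanced equilibrium exists", call. = FALSE)
    }
    Kts <- if (length(kts_routes)) kts_routes[1] else 0
  }

  assemble <- function(free) {
    # free: named vector over pool_names (free concentrations)
    y <- species_state()
    y["Tu"] <- free["Tu"]; y["Ts"] <- free["Ts"]
    y["GDPm"] <- free["GDPm"]; y["GDP"] <- free["GDP"]
    y["GTPm"] <- free["GTPm"]; y["GTP"] <- free["GTP"]
    y["TuGDPm"] <- K$K1 * free["Tu"] * free["GDPm"]
    y["TuGDP"]  <- K$K1 * free["Tu"] * free["GDP"]
    y["TuGTPm"] <- K$K5 * free["Tu"] * free["GTPm"]
    y["TuGTP"]  <- K$K5 * free["Tu"] * free["GTP"]
    y["TuTs"]   <- Kts * free["Tu"] * free["Ts"]
    y["TuGDPmTs"] <- K$K3 * y["TuGDPm"] * free["Ts"]
    y["TuGDPTs"]  <- K$K3 * y["TuGDP"] * free["Ts"]
    y["TuGTPmTs"] <- K$K6 * y["TuGTPm"] * free["Ts"]
    y["TuGTPTs"]  <- K$K6 * y["TuGTP"] * free["Ts"]
    y
  }
  active <- pool_names[tt > 0]
  if (!length(active)) return(species_state())
  scale <- tt[active]
  resid <- function(logf) {
    free <- stats::setNames(numeric(6), pool_names)
    free[active] <- exp(logf)
    y <- assemble(free)
    tot <- pool_totals(matrix(y, nrow = 1, dimnames = list(NULL, names(y))))
    (as.numeric(tot[1, active]) - tt[active]) / scale
  }
  x <- log(tt[active] * 0.5)
  f <- resid(x)
  for (iter in seq_len(200)) {
    if (max(abs(f)) < tol) break
    n <- length(x)
    J <- matrix(0, n, n)
    h <- 1e-7
    for (j in seq_len(n)) {
      xj <- x; xj[j] <- xj[j] + h
      J[, j] <- (resid(xj) - f) / h
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) stop("equilibrium solver: singular Jacobian", call. = FALSE)
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      fn <- resid(xn)
      if (max(abs(fn)) < max(abs(f)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    x <- xn; f <- fn
  }
  if (max(abs(f)) >= max(tol, 1e-9)) {
    stop(sprintf("equilibrium solver did not converge; residual norm %.3g",
                 max(abs(f))), call. = FALSE)
  }
  free <- stats::setNames(numeric(6), pool_names)
  free[active] <- exp(x)
  assemble(free)
}
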