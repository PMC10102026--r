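## Deterministic simulation of the transport network.
##
## The internal state is the vector of species amounts (concentration x
## compartment volume, in uM.fL), which makes conservation exact under the
## stoichiometry and lets pore translocation enter as plain first-order
## steps. Mass-action rates in a compartment of volume V are
## v = k / V^(order-1) * prod(amounts); for first-order steps v = k * A.
## Steady states are found by long-time stiff integration followed by a
## damped Newton refinement restricted to the stoichiometric subspace (which
## preserves all conserved moieties by construction).

## precompile the network into index vectors for fast rate evaluation
.compileNetwork <- function(network) {
  sp <- network@species
  rx <- network@reactions
  n <- nrow(sp); m <- nrow(rx)
  vol <- setNames(network@compartments$volume, network@compartments$name)
  r1 <- integer(m); r2 <- integer(m); kv <- numeric(m)
  S <- matrix(0, n, m)
  for (j in seq_len(m)) {
    re <- as.integer(rx$reactants[[j]])
    pr <- as.integer(rx$products[[j]])
    ord <- length(re)
    r1[j] <- re[1]
    r2[j] <- if (ord >= 2) re[2] else n + 1L  # dummy index -> 1
    V <- if (rx$compartment[j] == "pore") 1 else vol[[rx$compartment[j]]]
    # translocation steps are first-order in amount; within-compartment
    # mass action divides by V^(order-1)
    kv[j] <- rx$k[j] / (if (ord >= 2) V^(ord - 1) else 1)
    for (i in re) S[i, j] <- S[i, j] - 1
    for (i in pr) S[i, j] <- S[i, j] + 1
  }
  vols <- vol[sp$compartment]
  list(n = n, m = m, r1 = r1, r2 = r2, kv = kv, S = S, vols = unname(vols),
       species = sp, rx = rx)
}

.rates <- function(cm, A) {
  Ax <- c(A, 1)
  cm$kv * Ax[cm$r1] * Ax[cm$r2]
}

.deriv <- function(cm, A) as.vector(cm$S %*% .rates(cm, A))

.jacobian <- function(cm, A) {
  Ax <- c(A, 1)
  m <- cm$m; n <- cm$n
  Dv <- matrix(0, m, n)
  for (j in seq_len(m)) {
    i1 <- cm$r1[j]; i2 <- cm$r2[j]
    if (i2 > n) {
      Dv[j, i1] <- cm$kv[j]
    } else if (i1 == i2) {
      Dv[j, i1] <- 2 * cm$kv[j] * Ax[i1]
    } else {
      Dv[j, i1] <- cm$kv[j] * Ax[i2]
      Dv[j, i2] <- cm$kv[j] * Ax[i1]
    }
  }
  cm$S %*% Dv
}

.initialAmounts <- function(network, cm) {
  network@species$init * cm$vols
}

## residual in concentration units (uM/s): max |dC/dt|
.residual <- function(cm, A) max(abs(.deriv(cm, A) / cm$vols))

## amount totals per conserved moiety
.moietyAmounts <- function(cm, A) {
  moieties <- unique(unlist(lapply(cm$species$composition, names)))
  out <- setNames(numeric(length(moieties)), moieties)
  for (i in seq_len(nrow(cm$species))) {
    co <- cm$species$composition[[i]]
    for (mo in names(co)) out[mo] <- out[mo] + co[[mo]] * A[i]
  }
  out
}

## adapt a warm-start state to the network's conserved totals: any moiety
## deficit/excess is placed on that moiety's largest free-species pool.
## Newton then conserves the corrected totals exactly. If a correction
## would drive a pool negative the warm start is unusable and the
## network's own initial conditions are returned instead.
.projectToTotals <- function(cm, Awarm, Ainit) {
  bNew <- .moietyAmounts(cm, Ainit)
  bOld <- .moietyAmounts(cm, Awarm)
  A <- Awarm
  for (mo in names(bNew)) {
    d <- bNew[[mo]] - (if (mo %in% names(bOld)) bOld[[mo]] else 0)
    if (abs(d) <= 1e-9 * max(bNew[[mo]], 1)) next
    free <- which(vapply(cm$species$composition, function(co)
      length(co) == 1L && names(co) == mo && co[[1]] == 1L, FALSE))
    if (!length(free)) return(Ainit)
    i <- free[which.max(A[free])]
    if (A[i] + d < 0) return(Ainit)
    A[i] <- A[i] + d
  }
  A
}

#' Integrate a transport network through time
#'
#' Solves the mass-action ODE system with a stiff solver (lsoda) using the
#' analytic Jacobian. Output concentrations are micromolar per compartment.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param t_end end time in seconds (> 0, or 0 to return the initial state).
#' @param times optional explicit output times; default 100 points to t_end.
#' @param rtol,atol relative/absolute solver tolerances.
#' @param state optional starting concentrations (uM) overriding the
#'   network's initial conditions.
#' @return a data.frame with a \code{time} column and one column per
#'   species-in-compartment ("species@compartment"), in uM.
#' @examples
#' net <- buildNetwork()
#' tc <- integrateNetwork(net, t_end = 10)
#' tail(tc[, 1:4], 2)
#' @export
integrateNetwork <- function(network, t_end, times = NULL, rtol = 1e-8,
                             atol = 1e-10, state = NULL) {
  if (t_end < 0) stop("t_end must be >= 0")
  cm <- .compileNetwork(network)
  A0 <- if (is.null(state)) .initialAmounts(network, cm) else state * cm$vols
  keys <- .stateKey(cm$species$name, cm$species$compartment)
  if (t_end == 0) {
    out <- data.frame(time = 0, t(A0 / cm$vols))
    names(out) <- c("time", keys)
    return(out)
  }
  if (is.null(times)) times <- seq(0, t_end, length.out = 101)
  f <- function(t, A, p) list(.deriv(cm, A))
  jac <- function(t, A, p) .jacobian(cm, A)
  sol <- deSolve::lsoda(y = A0, times = times, func = f, parms = NULL,
                        jacfunc = jac, jactype = "fullusr",
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed to converge (istate = ",
         attr(sol, "istate")[1], ")")
  conc <- sweep(sol[, -1, drop = FALSE], 2, cm$vols, "/")
  out <- data.frame(time = sol[, 1], conc)
  names(out) <- c("time", keys)
  out
}

## damped Newton on the stoichiometric subspace: A = A0 + B z with B an
## orthonormal basis of the column space of S, so conserved totals are fixed
.newtonRefine <- function(cm, A, tol = 1e-9, maxit = 60) {
  qrS <- qr(cm$S)
  r <- qrS$rank
  if (r == 0) return(list(A = A, ok = TRUE))
  B <- qr.Q(qrS)[, seq_len(r), drop = FALSE]
  for (it in seq_len(maxit)) {
    F <- .deriv(cm, A)
    res <- max(abs(F / cm$vols))
    if (res < tol) return(list(A = A, ok = TRUE))
    J <- .jacobian(cm, A)
    G <- crossprod(B, F)
    JG <- crossprod(B, J %*% B)
    step <- tryCatch(-solve(JG, G), error = function(e) NULL)
    if (is.null(step)) return(list(A = A, ok = res < tol))
    lam <- 1
    repeat {
      Anew <- A + as.vector(B %*% (lam * step))
      if (all(Anew > -1e-12)) {
        Fn <- .deriv(cm, Anew)
        if (max(abs(Fn / cm$vols)) < res || lam < 1e-4) break
      }
      lam <- lam / 2
      if (lam < 1e-6) return(list(A = A, ok = res < tol))
    }
    A <- pmax(Anew, 0)
  }
  list(A = A, ok = .residual(cm, A) < tol)
}

.solveSteady <- function(cm, A0, tol = 1e-9, tmax = 1e6) {
  A <- A0
  t <- 1000
  method <- "newton"
  repeat {
    nr <- .newtonRefine(cm, A, tol = tol)
    if (nr$ok) return(list(A = nr$A, ok = TRUE, method = method))
    # fall back to integration, then retry Newton from the integrated state
    f <- function(tt, AA, p) list(.deriv(cm, AA))
    jac <- function(tt, AA, p) .jacobian(cm, AA)
    # staged integration: a truncated stage (maxsteps) still advances the
    # state and is retried at the next stage, so solver warnings here are
    # expected and suppressed
    sol <- tryCatch(suppressWarnings(
      deSolve::lsoda(y = A, times = c(0, t), func = f,
                     parms = NULL, jacfunc = jac, jactype = "fullusr",
                     rtol = 1e-10, atol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(sol) && nrow(sol) == 2)
      A <- pmax(as.vector(sol[2, -1]), 0)
    method <- "integrate+newton"
    if (t >= tmax) {
      nr <- .newtonRefine(cm, A, tol = tol)
      return(list(A = nr$A, ok = nr$ok, method = method))
    }
    t <- t * 10
  }
}

.cargoTotals <- function(cm, A, cargoNames) {
  sp <- cm$species
  conc <- A / cm$vols
  out <- matrix(0, length(cargoNames), 3,
                dimnames = list(cargoNames,
                                c("cytoplasm", "nucleus", "pore")))
  for (cg in cargoNames) {
    has <- vapply(sp$composition, function(co) cg %in% names(co), FALSE)
    for (cmp in colnames(out)) {
      i <- which(has & sp$compartment == cmp)
      out[cg, cmp] <- sum(conc[i])
    }
  }
  out
}

#' Steady state of a transport network
#'
#' Finds the steady state by damped Newton iteration restricted to the
#' stoichiometric subspace, with staged long-time integration as a fallback
#' for poor starting points. The nuclear-to-cytoplasmic (N/C) ratio of each
#' cargo is the total cargo concentration (free plus all cargo-containing
#' complexes) in the nucleus divided by the same in the cytoplasm;
#' pore-resident cargo is excluded. A non-converged solve is returned with
#' \code{converged = FALSE}, never a fabricated ratio.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param tol residual tolerance, uM/s (default 1e-9).
#' @param state optional starting concentrations (uM).
#' @return a \linkS4class{SteadyStateResult}.
#' @examples
#' net <- addCargo(buildNetwork(), cargoSpec("NLS", "classical", 32))
#' ss <- steadyState(net)
#' ncRatio(ss)
#' @export
steadyState <- function(network, tol = 1e-9, state = NULL) {
  cm <- .compileNetwork(network)
  Ainit <- .initialAmounts(network, cm)
  A0 <- if (is.null(state)) Ainit else
    .projectToTotals(cm, state * cm$vols, Ainit)
  sol <- .solveSteady(cm, A0, tol = tol)
  conc <- sol$A / cm$vols
  keys <- .stateKey(cm$species$name, cm$species$compartment)
  names(conc) <- keys
  cargoNames <- vapply(network@cargoes, slot, "", "name")
  totals <- .cargoTotals(cm, sol$A, cargoNames)
  nc <- if (length(cargoNames)) {
    r <- totals[, "nucleus"] / totals[, "cytoplasm"]
    r[totals[, "nucleus"] == 0] <- 0  # no nuclear cargo: ratio 0 even if
    r                                  # the cytoplasm is also empty
  } else numeric(0)
  if (length(nc)) names(nc) <- cargoNames
  new("SteadyStateResult", concentrations = conc, ncRatio = nc,
      cargoTotals = totals, residualNorm = .residual(cm, sol$A),
      converged = sol$ok, method = sol$method)
}

#' @describeIn steadyState nuclear-to-cytoplasmic total-cargo ratio(s).
#' @param result a SteadyStateResult.
#' @export
ncRatio <- function(result) result@ncRatio

#' @describeIn steadyState residual max |dC/dt| in uM/s.
#' @export
residualNorm <- function(result) result@residualNorm

#' @describeIn steadyState convergence flag.
#' @export
converged <- function(result) result@converged

setMethod("show", "SteadyStateResult", function(object) {
  cat("SteadyStateResult:", if (object@converged) "converged" else
      "NOT converged", sprintf("(residual %.3g uM/s, %s)\n",
      object@residualNorm, object@method))
  if (length(object@ncRatio)) {
    cat("  N/C ratios:\n")
    for (nm in names(object@ncRatio))
      cat(sprintf("    %-12s %.4g\n", nm, object@ncRatio[[nm]]))
  }
})

#' Conserved moiety totals
#'
#' Volume-weighted total amount of each conserved moiety (Ran, importins,
#' CAS, CRM1, NTF2, RanBP1, RanBP3, RCC1, RanGAP and each cargo), summed over
#' free and complexed forms across compartments. Totals are constant along
#' trajectories and at steady state.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param state named concentrations (uM) as returned in a
#'   \linkS4class{SteadyStateResult} or a row of [integrateNetwork()] output;
#'   defaults to the initial conditions.
#' @return named numeric vector of totals (amount units, uM.fL).
#' @export
moietyTotals <- function(network, state = NULL) {
  cm <- .compileNetwork(network)
  A <- if (is.null(state)) .initialAmounts(network, cm) else {
    keys <- .stateKey(cm$species$name, cm$species$compartment)
    as.numeric(state[keys]) * cm$vols
  }
  moieties <- unique(unlist(lapply(cm$species$composition, names)))
  out <- setNames(numeric(length(moieties)), moieties)
  for (i in seq_len(nrow(cm$species))) {
    co <- cm$species$composition[[i]]
    for (mo in names(co)) out[mo] <- out[mo] + co[[mo]] * A[i]
  }
  out
}

#' Scale the initial abundance of one base species
#'
#' Multiplies the initial concentration of the given protein (all
#' compartments) by \code{fold}. "Ran" scales both nucleotide states.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param species base protein name (e.g. "CAS", "Impa", "Ran").
#' @param fold positive multiplier.
#' @return the modified network.
#' @export
scaleSpecies <- function(network, species, fold) {
  if (fold < 0) stop("fold must be >= 0")
  sp <- network@species
  targets <- if (species == "Ran") c("RanGTP", "RanGDP") else species
  hit <- sp$name %in% targets
  if (!any(hit)) stop("unknown species: ", species)
  sp$init[hit] <- sp$init[hit] * fold
  network@species <- sp
  network
}
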