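## ErbB feedback extension: internalized ErbB heterodimers are modelled as
## classical importin-alpha:beta cargo; two antagonistic proportional
## feedbacks couple the cargo's compartmental distribution back to the
## transport machinery (cytoplasmic ErbB induces CAS/CSE1L; nuclear ErbB
## represses importin-alpha through the miR-205-KPNA1 circuit). The
## feedbacks are steady-state algebraic constraints co-solved with the
## transport model by damped fixed-point iteration; continuation from both
## ends of the CSE1L grid detects bistability.

#' ErbB heterodimer cargo
#'
#' Classical cargo standing in for internalized EGFR-ERBB2 heterodimers,
#' whose tripartite NLS binds importin-alpha:beta with unknown affinity
#' (scanned over a strong/medium/weak ladder in practice).
#'
#' @param kdImport importin-alpha:beta dissociation constant, nM.
#' @param totalConcentration total cargo, uM (default 1).
#' @param passivePermeability passive pore permeability (s^-1); the
#'   default 0.01 reflects the large size of internalized receptor
#'   complexes relative to fluorescent reporters.
#' @return a \linkS4class{CargoSpec} named "ErbB".
#' @export
erbbCargo <- function(kdImport = 320, totalConcentration = 1,
                      passivePermeability = 0.01) {
  cargoSpec("ErbB", "classical", kdImport = kdImport,
            totalConcentration = totalConcentration,
            passivePermeability = passivePermeability)
}

#' Feedback-coupled transport model
#'
#' @slot network base network with the ErbB cargo added (CAS/Imp-alpha at
#'   their unscaled base abundances).
#' @slot gainCas proportional gain, cytoplasmic ErbB -> CAS (positive
#'   feedback).
#' @slot gainImpa proportional gain, nuclear ErbB -> importin-alpha
#'   (negative feedback).
#' @slot enabled logical; FALSE solves the uncoupled model.
#' @slot input "free" (default): the CAS feedback senses the free,
#'   carrier-unbound cytoplasmic cargo (the signalling-competent pool);
#'   "total": all cytoplasmic cargo including carrier-bound complexes.
#' @export
setClass("FeedbackModel",
  representation(network = "ReactionNetwork", gainCas = "numeric",
                 gainImpa = "numeric", enabled = "logical",
                 input = "character"))

#' Build the ErbB feedback model
#'
#' @param network base \linkS4class{ReactionNetwork} (no cargo).
#' @param cargo an [erbbCargo()] specification.
#' @param gainCas,gainImpa dimensionless proportional gains (>= 0). With
#'   cytoplasmic amount fraction fc and nuclear fraction fn of total ErbB,
#'   the co-solved constraints are
#'   CAS_eff = CAS0 (1 + gainCas fc) and
#'   Impa_eff = Impa0 max(0, 1 - gainImpa fn).
#' @param enabled FALSE (or both gains 0) reduces exactly to the uncoupled
#'   transport model.
#' @param input feedback sensing mode: "free" (default; the CAS loop
#'   senses free, signalling-competent cytoplasmic cargo) or "total".
#' @return a \linkS4class{FeedbackModel}.
#' @examples
#' fm <- buildFeedbackModel(buildNetwork(), erbbCargo(320), 8, 0.3)
#' @export
buildFeedbackModel <- function(network, cargo = erbbCargo(),
                               gainCas = 8, gainImpa = 0.3,
                               enabled = TRUE,
                               input = c("total", "free")) {
  stopifnot(is(network, "ReactionNetwork"))
  if (gainCas < 0 || gainImpa < 0) stop("gains must be >= 0")
  new("FeedbackModel", network = addCargo(network, cargo),
      gainCas = gainCas, gainImpa = gainImpa, enabled = enabled,
      input = match.arg(input))
}

setMethod("show", "FeedbackModel", function(object) {
  cat(sprintf(
    "FeedbackModel: gains (CAS %.3g, Impa %.3g), feedback %s\n",
    object@gainCas, object@gainImpa,
    if (object@enabled) "enabled" else "disabled"))
})

## solve one grid point: fixed point over (CAS, Impa) effective scales.
## The compiled network is shared across iterations (only initial amounts
## change); the Picard iteration is secant-accelerated per component.
.solveFeedbackPoint <- function(model, casFold, impaFold = 1, cm = NULL,
                                warm = NULL, scales = c(1, 1), tol = 1e-6,
                                maxit = 200, damping = 0.5) {
  if (is.null(cm)) cm <- .compileNetwork(model@network)
  AinitBase <- .initialAmounts(model@network, cm)
  iCas <- which(cm$species$name == "CAS" & AinitBase > 0)
  iImpa <- which(cm$species$name == "Impa" & AinitBase > 0)
  gC <- if (model@enabled) model@gainCas else 0
  gA <- if (model@enabled) model@gainImpa else 0
  cargoIdx <- which(vapply(cm$species$composition,
                           function(co) "ErbB" %in% names(co), FALSE))
  cargoComp <- cm$species$compartment[cargoIdx]
  # the CAS loop can sense either all cytoplasmic cargo or only the free
  # (carrier-unbound, signalling-competent) pool
  cargoFree <- cm$species$name[cargoIdx] == "ErbB"
  fcIdx <- if (model@input == "free") cargoFree & cargoComp == "cytoplasm"
           else cargoComp == "cytoplasm"

  solveAt <- function(sC, sA, Awarm) {
    Ainit <- AinitBase
    Ainit[iCas] <- Ainit[iCas] * casFold * sC
    Ainit[iImpa] <- Ainit[iImpa] * impaFold * sA
    A0 <- if (is.null(Awarm)) Ainit else .projectToTotals(cm, Awarm, Ainit)
    .solveSteady(cm, A0)
  }
  fractions <- function(A) {
    amt <- A[cargoIdx]
    tot <- sum(amt)
    c(fc = sum(amt[fcIdx]) / tot,
      fn = sum(amt[cargoComp == "nucleus"]) / tot)
  }
  gmap <- function(A) {
    fr <- fractions(A)
    c(1 + gC * fr[["fc"]], max(0, 1 - gA * fr[["fn"]]))
  }

  s <- scales
  A <- warm
  sPrev <- NULL; fPrev <- NULL
  for (it in seq_len(maxit)) {
    sol <- solveAt(s[1], s[2], A)
    if (!sol$ok)
      return(list(ok = FALSE, A = sol$A, cm = cm, scales = s, iters = it))
    A <- sol$A
    if (gC == 0 && gA == 0)
      return(list(ok = TRUE, A = A, cm = cm, scales = c(1, 1), iters = it))
    gs <- gmap(A)
    f <- gs - s
    err <- max(abs(f) / pmax(abs(s), 1e-8))
    if (err < tol)
      return(list(ok = TRUE, A = A, cm = cm, scales = s, iters = it))
    # per-component secant step where history permits, damped Picard else
    sNew <- s
    for (k in 1:2) {
      if (!is.null(fPrev) && abs(f[k] - fPrev[k]) > 1e-12) {
        step <- -f[k] * (s[k] - sPrev[k]) / (f[k] - fPrev[k])
        if (!is.finite(step) || abs(step) > 0.5 * max(abs(s[k]), 1))
          step <- damping * f[k]
        sNew[k] <- s[k] + step
      } else {
        sNew[k] <- s[k] + damping * f[k]
      }
    }
    sNew[1] <- max(sNew[1], 1e-6)
    sNew[2] <- max(sNew[2], 0)
    sPrev <- s; fPrev <- f
    s <- sNew
  }
  list(ok = FALSE, A = A, cm = cm, scales = s, iters = maxit)
}

#' Steady-state C/N ratio across a CSE1L abundance grid
#'
#' Co-solves the feedback constraints with the transport steady state at
#' each initial CSE1L fold. Continuation runs from both ends of the grid;
#' when the two branches separate by more than the tolerance the curve is
#' reported with both branches (bistability), otherwise the ascending
#' branch alone.
#'
#' @param model a \linkS4class{FeedbackModel}.
#' @param folds strictly increasing positive grid (>= 10 points) of CSE1L
#'   abundance as fold of base.
#' @param branchTol relative gap above which the two continuation branches
#'   are reported separately (default 0.01).
#' @return a \linkS4class{SwitchCurve}.
#' @examples
#' \donttest{
#' fm <- buildFeedbackModel(buildNetwork(), erbbCargo(2.5), 6, 0.8)
#' cv <- cnCurve(fm, 2^seq(-2, 2, length.out = 11))
#' }
#' @export
cnCurve <- function(model, folds = 2^seq(-2, 2, length.out = 21),
                    branchTol = 0.01) {
  if (any(folds <= 0)) stop("folds must be positive")
  if (is.unsorted(folds, strictly = TRUE))
    stop("folds must be strictly increasing")
  if (length(folds) < 10) stop("need at least 10 grid points")
  cm <- .compileNetwork(model@network)
  runBranch <- function(idx) {
    cn <- numeric(length(folds)); ok <- logical(length(folds))
    warm <- NULL; scales <- c(1, 1)
    for (i in idx) {
      sol <- .solveFeedbackPoint(model, folds[i], cm = cm, warm = warm,
                                 scales = scales)
      ok[i] <- sol$ok
      tot <- .cargoTotals(cm, sol$A, "ErbB")
      nc <- if (tot["ErbB", "cytoplasm"] > 0)
        tot["ErbB", "nucleus"] / tot["ErbB", "cytoplasm"] else Inf
      cn[i] <- if (nc > 0) 1 / nc else Inf
      if (sol$ok) { warm <- sol$A; scales <- sol$scales }
    }
    list(cn = cn, ok = ok)
  }
  up <- runBranch(seq_along(folds))
  down <- runBranch(rev(seq_along(folds)))
  gap <- abs(up$cn - down$cn) / pmax(abs(up$cn), 1e-12)
  if (any(gap > branchTol & up$ok & down$ok)) {
    new("SwitchCurve", folds = c(folds, folds),
        cnRatio = c(up$cn, down$cn),
        converged = c(up$ok, down$ok),
        branch = rep(c("up", "down"), each = length(folds)))
  } else {
    new("SwitchCurve", folds = folds, cnRatio = up$cn, converged = up$ok,
        branch = rep("up", length(folds)))
  }
}

#' Single co-solved feedback steady state
#'
#' Solves the feedback model at one (CSE1L fold, importin-alpha fold)
#' point, returning the C/N ratio and the converged effective-abundance
#' scales.
#'
#' @param model a \linkS4class{FeedbackModel}.
#' @param casFold,impaFold initial-abundance folds of CSE1L and
#'   importin-alpha relative to base.
#' @return list: cn, ncRatio, scales (effective CAS/Impa multipliers),
#'   converged, iterations.
#' @export
feedbackSteadyState <- function(model, casFold = 1, impaFold = 1) {
  sol <- .solveFeedbackPoint(model, casFold, impaFold)
  cm <- sol$cm
  tot <- .cargoTotals(cm, sol$A, "ErbB")
  nc <- if (tot["ErbB", "cytoplasm"] > 0)
    tot["ErbB", "nucleus"] / tot["ErbB", "cytoplasm"] else Inf
  list(cn = if (nc > 0) 1 / nc else Inf, ncRatio = nc,
       scales = sol$scales, converged = sol$ok, iterations = sol$iters)
}

setMethod("show", "SwitchCurve", function(object) {
  nb <- length(unique(object@branch))
  cat("SwitchCurve:", length(object@folds), "points,",
      nb, if (nb > 1) "branches (bistable)\n" else "branch\n")
  cat(sprintf("  C/N range %.4g - %.4g over folds %.3g - %.3g\n",
      min(object@cnRatio, na.rm = TRUE), max(object@cnRatio, na.rm = TRUE),
      min(object@folds), max(object@folds)))
})

#' Ultrasensitivity index of a switch curve
#'
#' Quantifies how switch-like a monotone response is: the maximum local
#' log-log slope (apparent Hill coefficient, by central differences) and
#' the transition width (fold-range of the input spanning 10% to 90% of the
#' response span, from interpolated crossings; smaller is sharper). A
#' non-monotone curve is fitted by isotonic regression first and flagged.
#'
#' @param curve a \linkS4class{SwitchCurve}, or a list/data.frame with
#'   \code{folds} and \code{cnRatio} (an "up" branch is extracted from a
#'   bistable curve).
#' @return list with \code{maxSlope}, \code{transitionWidth} (fold ratio),
#'   \code{monotone} flag.
#' @examples
#' x <- 2^seq(-3, 3, length.out = 50)
#' ultrasensitivityIndex(list(folds = x, cnRatio = x^4 / (1 + x^4)))
#' @export
ultrasensitivityIndex <- function(curve) {
  if (is(curve, "SwitchCurve")) {
    keep <- curve@branch == curve@branch[1] & curve@converged
    x <- curve@folds[keep]; y <- curve@cnRatio[keep]
  } else {
    x <- curve$folds; y <- curve$cnRatio
  }
  fin <- is.finite(x) & is.finite(y) & y > 0
  x <- x[fin]; y <- y[fin]
  if (length(x) < 10) stop("need at least 10 finite points")
  o <- order(x); x <- x[o]; y <- y[o]
  monotone <- !is.unsorted(y)
  if (!monotone) {
    y <- isoreg(log(x), y)$yf
  }
  lx <- log(x); ly <- log(y)
  n <- length(x)
  slopes <- (ly[-(1:2)] - ly[seq_len(n - 2)]) /
            (lx[-(1:2)] - lx[seq_len(n - 2)])
  maxSlope <- max(slopes, na.rm = TRUE)
  span <- range(y)
  y10 <- span[1] + 0.1 * diff(span)
  y90 <- span[1] + 0.9 * diff(span)
  crossing <- function(level) {
    i <- which(y[-n] <= level & y[-1] >= level)
    if (!length(i)) return(NA_real_)
    i <- i[1]
    w <- (level - y[i]) / (y[i + 1] - y[i])
    exp(lx[i] + w * (lx[i + 1] - lx[i]))
  }
  xlo <- crossing(y10); xhi <- crossing(y90)
  list(maxSlope = maxSlope,
       transitionWidth = if (is.na(xlo) || is.na(xhi)) NA_real_ else xhi / xlo,
       monotone = monotone)
}
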