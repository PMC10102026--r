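#' @import methods
#' @importFrom stats quantile median sd var dbinom qbinom pf pchisq p.adjust
#'   wilcox.test t.test rnorm rlnorm rbinom rpois runif setNames isoreg
#'   convolve mad complete.cases aggregate
NULL

#' Reaction network for karyopherin-mediated nucleocytoplasmic transport
#'
#' An S4 container for a three-compartment (cytoplasm, nucleus, nuclear pore)
#' mass-action reaction network of the Ran GTPase transport cycle, importin
#' alpha/beta cargo loading, CAS-mediated importin-alpha recycling and
#' CRM1/RanBP3-dependent export. The state vector is one entry per
#' species-in-compartment; reactions are elementary mass-action steps plus
#' first-order pore translocation steps.
#'
#' @slot species DataFrame with one row per state entry: \code{name} (species
#'   name), \code{compartment}, \code{init} (initial concentration, uM),
#'   \code{carrier} (carrier family used by pore selectivity), and a list
#'   column \code{composition} giving counts of conserved moieties.
#' @slot reactions DataFrame of elementary reactions: reactant/product state
#'   indices, rate-constant name, numeric rate constant, compartment, and the
#'   effective amount-space rate coefficient.
#' @slot compartments data.frame with \code{name} and \code{volume} (fL).
#' @slot pores list describing the pore classes (counts, selectivity).
#' @slot rates named numeric vector of rate constants (uM^-1 s^-1 or s^-1).
#' @slot cargoes list of \linkS4class{CargoSpec} objects added to the network.
#'
#' @seealso [buildNetwork()], [addCargo()], [steadyState()]
#' @export
setClass("ReactionNetwork",
  representation(
    species = "DataFrame",
    reactions = "DataFrame",
    compartments = "data.frame",
    pores = "list",
    rates = "numeric",
    cargoes = "list"
  )
)

setValidity("ReactionNetwork", function(object) {
  msg <- character()
  sp <- object@species
  if (anyDuplicated(paste(sp$name, sp$compartment)))
    msg <- c(msg, "duplicate species/compartment entries")
  if (any(sp$init < 0)) msg <- c(msg, "negative initial concentration")
  cm <- object@compartments
  if (!setequal(cm$name, c("cytoplasm", "nucleus", "pore")))
    msg <- c(msg, "compartments must be exactly cytoplasm, nucleus, pore")
  if (any(cm$volume <= 0)) msg <- c(msg, "compartment volumes must be > 0")
  rx <- object@reactions
  if (nrow(rx) > 0) {
    if (any(rx$k < 0)) msg <- c(msg, "negative rate constant")
    idx <- c(unlist(rx$reactants), unlist(rx$products))
    if (any(idx < 1 | idx > nrow(sp)))
      msg <- c(msg, "reaction references unknown species index")
  }
  if (length(msg)) msg else TRUE
})

#' Transport cargo specification
#'
#' Describes a cargo added to a \linkS4class{ReactionNetwork}: classical
#' cargo binds the importin-alpha:beta heterodimer, IBB-type cargo binds
#' importin-beta directly. Cargo carrying a nuclear export sequence (NES)
#' additionally binds the CRM1:RanBP3:RanGTP export machinery.
#'
#' @slot name cargo name (unique within a network).
#' @slot importMode "classical" or "ibb".
#' @slot kdImport import dissociation constant (nM).
#' @slot hasNes logical; cargo carries an NES.
#' @slot kdExport export dissociation constant (nM; used only if hasNes).
#' @slot totalConcentration total cargo concentration (uM).
#' @slot passivePermeability optional cargo-specific passive pore
#'   permeability (s^-1); NA uses the network's global rate.
#' @export
setClass("CargoSpec",
  representation(
    name = "character", importMode = "character", kdImport = "numeric",
    hasNes = "logical", kdExport = "numeric",
    totalConcentration = "numeric", passivePermeability = "numeric"
  )
)

setValidity("CargoSpec", function(object) {
  msg <- character()
  if (!object@importMode %in% c("classical", "ibb", "none"))
    msg <- c(msg, "importMode must be classical, ibb or none")
  if (length(object@kdImport) && !is.na(object@kdImport) &&
      object@kdImport <= 0)
    msg <- c(msg, "kdImport must be > 0")
  if (object@totalConcentration <= 0)
    msg <- c(msg, "totalConcentration must be > 0")
  if (object@hasNes && (length(object@kdExport) == 0 || is.na(object@kdExport)))
    msg <- c(msg, "hasNes requires kdExport")
  if (length(msg)) msg else TRUE
})

#' Steady-state solution of a transport network
#'
#' @slot concentrations named numeric vector, uM, one entry per
#'   species-in-compartment (names are "species@compartment").
#' @slot ncRatio named numeric; steady-state nuclear/cytoplasmic ratio of
#'   total cargo (free plus all cargo-containing complexes; pore excluded)
#'   for each cargo in the network.
#' @slot cargoTotals matrix of total cargo concentration per compartment.
#' @slot residualNorm max |dC/dt| (uM/s) at the returned state.
#' @slot converged logical.
#' @slot method character; how the state was obtained.
#' @export
setClass("SteadyStateResult",
  representation(
    concentrations = "numeric", ncRatio = "numeric", cargoTotals = "matrix",
    residualNorm = "numeric", converged = "logical", method = "character"
  )
)

#' Inverse-binomial frequency band
#'
#' Interquartile and 90% bands of a binomial count distribution, obtained by
#' exact summation of the probability mass function. Endpoints are the
#' smallest integers k with CDF(k) >= level.
#'
#' @slot n number of trials.
#' @slot p success probability.
#' @slot expected n * p.
#' @slot iqr integer vector [lo, hi] at levels 0.25/0.75.
#' @slot ci90 integer vector [lo, hi] at levels 0.05/0.95.
#' @export
setClass("BinomialBand",
  representation(n = "integer", p = "numeric", expected = "numeric",
                 iqr = "integer", ci90 = "integer")
)

setValidity("BinomialBand", function(object) {
  b <- c(object@ci90[1], object@iqr[1], object@iqr[2], object@ci90[2])
  if (any(diff(b) < 0) || b[1] < 0 || b[4] > object@n)
    "band endpoints must satisfy 0 <= ci90.lo <= iqr.lo <= iqr.hi <= ci90.hi <= n"
  else TRUE
})

#' Switch curve: steady-state C/N versus initial CSE1L abundance
#'
#' @slot folds numeric, strictly increasing grid of CSE1L abundances
#'   (fold of base).
#' @slot cnRatio numeric, steady-state cytoplasmic/nuclear cargo ratio.
#' @slot converged logical per grid point.
#' @slot branch character per grid point ("up" continuation from low CSE1L,
#'   "down" from high); both reported when a bistable gap is detected.
#' @export
setClass("SwitchCurve",
  representation(folds = "numeric", cnRatio = "numeric",
                 converged = "logical", branch = "character")
)

setValidity("SwitchCurve", function(object) {
  ok <- TRUE
  for (b in unique(object@branch)) {
    f <- object@folds[object@branch == b]
    if (any(diff(f) <= 0)) ok <- "folds must be strictly increasing per branch"
  }
  if (any(object@cnRatio < 0, na.rm = TRUE)) ok <- "cnRatio must be >= 0"
  ok
})

#' Labelled object mask
#'
#' A 2D integer label image (0 = background, objects labelled 1..n) with an
#' associated pixel size in micrometres per pixel.
#'
#' @slot labels integer matrix of object labels.
#' @slot pixelSize pixel edge length, um/px.
#' @export
setClass("LabelMask",
  representation(labels = "matrix", pixelSize = "numeric")
)

setValidity("LabelMask", function(object) {
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  l <- object@labels
  if (any(l < 0) || any(l != round(l))) return("labels must be non-negative integers")
  TRUE
})

#' @describeIn LabelMask-class constructor.
#' @param labels integer matrix of object labels.
#' @param pixelSize um per pixel (default 0.142, a confocal step size typical
#'   of photon-counting acquisitions).
#' @export
labelMask <- function(labels, pixelSize = 0.142) {
  storage.mode(labels) <- "integer"
  new("LabelMask", labels = labels, pixelSize = pixelSize)
}
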