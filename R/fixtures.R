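#' @include AllGenerics.R
NULL

#' Reduced ErbB2/3-like receptor/PI3K/PTEN/Akt fixture model
#'
#' A 12-species kinetic model emulating the structural features of ErbB2/3
#' signalling to Akt at reduced size: heregulin (HRG) binding to the ErbB3
#' receptor, ErbB2/ErbB3 heterodimerisation blocked by an ErbB2 antibody
#' inhibitor (Per) that sequesters ErbB2, dimer-driven PI3K activation, a
#' PIP2/PIP3 phosphoinositide cycle with Michaelis-Menten PI3K and PTEN
#' arms, PIP3-dependent Akt membrane recruitment, PDK1-mediated Akt
#' phosphorylation and PP2A-mediated dephosphorylation. All amounts are nM,
#' all times minutes.
#'
#' Nominal protein totals sit inside the standard 10--1000 nM sampling
#' window and the rate constants are chosen so that (i) the no-drug pAkt
#' fraction at 60 min lies between 0.2 and 0.8, (ii) 100 nM inhibitor cuts
#' the pAkt AUC by well over 20%, (iii) the pAkt AUC responds monotonically
#' to each protein total across its 10-fold range, and (iv) without ligand
#' the pathway stays silent. These are construction constraints of the
#' fixture, not estimates for any particular cell line.
#'
#' The model bundles its two standard conditions -- \code{no_drug}
#' (HRG = 1 nM, Per = 0) and \code{with_drug} (HRG = 1 nM, Per = 100 nM) --
#' and the \code{pAkt} readout (pAkt species normalised by total Akt).
#'
#' @return a \linkS4class{KineticModel}.
#' @examples
#' m <- makeReducedErbbModel()
#' m
#' @export
makeReducedErbbModel <- function() {
  species <- data.frame(
    name = c("R3", "HRG_R3", "R2", "R2_Per", "Dim", "PI3K", "PI3K_a",
             "PIP2", "PIP3", "Akt", "Akt_m", "pAkt"),
    initial = 0)
  parameters <- c(
    # receptor module
    k1f = 0.1,   k1r = 0.01,    # HRG binding to R3 (/nM/min, /min)
    k2f = 0.01,  k2r = 0.1,     # HRG_R3 + R2 dimerisation
    k3f = 0.1,   k3r = 0.01,    # inhibitor sequestration of R2
    # PI3K (de)activation by the active dimer
    k4 = 0.001,  k5 = 0.1,
    # phosphoinositide cycle (Michaelis-Menten, catalyst amounts explicit)
    kcat6 = 0.5, Km6 = 200,     # PI3K_a: PIP2 -> PIP3
    kcat7 = 0.2, Km7 = 200,     # PTEN:   PIP3 -> PIP2
    # Akt membrane recruitment on PIP3 (docking, PIP3 not consumed)
    k8f = 0.001, k8r = 0.1,
    kcat9 = 0.3,  Km9 = 200,    # PDK1 phosphorylation of membrane Akt
    kcat10 = 0.3, Km10 = 200,   # PP2A dephosphorylation of pAkt
    # protein totals (nM)
    R3_tot = 100, R2_tot = 300, PI3K_tot = 100, PI_tot = 500,
    Akt_tot = 500, PTEN_tot = 100, PP2A_tot = 100, PDK1_tot = 100,
    # external compounds, fixed by condition (nM)
    HRG = 1, Per = 0)
  units <- c(R3_tot = "nM", R2_tot = "nM", PI3K_tot = "nM", PI_tot = "nM",
             Akt_tot = "nM", PTEN_tot = "nM", PP2A_tot = "nM",
             PDK1_tot = "nM", HRG = "nM", Per = "nM")
  rxn <- function(id, reactants, products, rate)
    list(id = id, reactants = reactants, products = products, rate = rate)
  reactions <- list(
    rxn("ligand_binding", c(R3 = 1), c(HRG_R3 = 1),
        quote(k1f * HRG * R3 - k1r * HRG_R3)),
    rxn("dimerisation", c(HRG_R3 = 1, R2 = 1), c(Dim = 1),
        quote(k2f * HRG_R3 * R2 - k2r * Dim)),
    rxn("inhibitor_binding", c(R2 = 1), c(R2_Per = 1),
        quote(k3f * Per * R2 - k3r * R2_Per)),
    rxn("pi3k_activation", c(PI3K = 1), c(PI3K_a = 1),
        quote(k4 * Dim * PI3K)),
    rxn("pi3k_deactivation", c(PI3K_a = 1), c(PI3K = 1),
        quote(k5 * PI3K_a)),
    rxn("pip2_phosphorylation", c(PIP2 = 1), c(PIP3 = 1),
        quote(kcat6 * PI3K_a * PIP2 / (Km6 + PIP2))),
    rxn("pten_dephosphorylation", c(PIP3 = 1), c(PIP2 = 1),
        quote(kcat7 * PTEN_tot * PIP3 / (Km7 + PIP3))),
    rxn("akt_recruitment", c(Akt = 1), c(Akt_m = 1),
        quote(k8f * PIP3 * Akt - k8r * Akt_m)),
    rxn("akt_phosphorylation", c(Akt_m = 1), c(pAkt = 1),
        quote(kcat9 * PDK1_tot * Akt_m / (Km9 + Akt_m))),
    rxn("akt_dephosphorylation", c(pAkt = 1), c(Akt = 1),
        quote(kcat10 * PP2A_tot * pAkt / (Km10 + pAkt))))
  initialExprs <- list(R3 = quote(R3_tot), R2 = quote(R2_tot),
                       PI3K = quote(PI3K_tot), PIP2 = quote(PI_tot),
                       Akt = quote(Akt_tot))
  conserved <- list(
    R3_pool = list(species = c("R3", "HRG_R3", "Dim"), total = "R3_tot"),
    R2_pool = list(species = c("R2", "R2_Per", "Dim"), total = "R2_tot"),
    PI3K_pool = list(species = c("PI3K", "PI3K_a"), total = "PI3K_tot"),
    PI_pool = list(species = c("PIP2", "PIP3"), total = "PI_tot"),
    Akt_pool = list(species = c("Akt", "Akt_m", "pAkt"), total = "Akt_tot"))
  conditions <- list(
    no_drug = Condition("no_drug", c(HRG = 1, Per = 0)),
    with_drug = Condition("with_drug", c(HRG = 1, Per = 100)))
  readouts <- list(pAkt = Readout("pAkt", species = "pAkt",
                                  normalizer = "Akt_tot"))
  KineticModel("reduced_erbb23", species = species, parameters = parameters,
               reactions = reactions, initialExprs = initialExprs,
               conserved = conserved, parameterUnits = units,
               conditions = conditions, readouts = readouts)
}

#' Parameter space of the fixture model
#'
#' The standard hypercube for \code{\link{makeReducedErbbModel}}: 10-fold
#' ranges around nominal kinetic constants, 10--1000 nM for protein totals,
#' ligand and inhibitor doses fixed (they belong to the conditions).
#'
#' @return a \linkS4class{ParameterSpace} with 26 perturbable parameters.
#' @export
reducedErbbSpace <- function() {
  buildParameterSpace(makeReducedErbbModel(), fixed_names = c("HRG", "Per"))
}

#' Analytic benchmark with known monotone sensitivity structure
#'
#' Constructs a closed-form test function on the unit hypercube,
#' output = sum_i c_i * g_i(u_i) + noise * e, with each g_i strictly
#' monotone increasing and c_i carrying the declared sign; coordinates with
#' sign 0 are dummies that do not enter the output at all. The g_i cycle
#' through distinct strictly monotone shapes (cubic-odd, exponential,
#' logistic) so the dependence is nonlinear but monotone -- exactly the
#' regime rank-based sensitivity analysis is designed for. Noise draws are
#' deterministic under the stored seed.
#'
#' @param k dimension (>= 2).
#' @param signs numeric vector of +1 / -1 / 0 of length k.
#' @param noise standard deviation of additive Gaussian noise (default 0).
#' @param seed integer seed for the noise.
#' @return an object of class \code{AnalyticBenchmark} (a list with elements
#'   \code{k}, \code{signs}, \code{noise}, \code{seed} and the evaluator
#'   \code{fun(U)} mapping an N x k unit matrix to an output vector).
#' @examples
#' b <- makeMonotoneBenchmark(3, c(1, -1, 0), noise = 0.1, seed = 7)
#' y <- b$fun(sobolUnitPoints(3, 128))
#' @export
makeMonotoneBenchmark <- function(k, signs, noise = 0, seed = 1L) {
  if (k < 2L) stop("'k' must be >= 2")
  if (length(signs) != k) stop("'signs' must have length k")
  if (!all(signs %in% c(-1, 0, 1))) stop("signs must be -1, 0 or +1")
  shapes <- list(function(u) u + u^3,
                 function(u) expm1(2 * u) / expm1(2),
                 function(u) stats::plogis(6 * (u - 0.5)))
  fun <- function(U) {
    U <- as.matrix(U)
    if (ncol(U) != k) stop("U must have ", k, " columns")
    out <- numeric(nrow(U))
    for (i in seq_len(k)) {
      if (signs[i] == 0) next
      g <- shapes[[(i - 1L) %% length(shapes) + 1L]]
      out <- out + signs[i] * g(U[, i])
    }
    if (noise > 0) {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      on.exit({
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
      })
      set.seed(seed)
      out <- out + noise * stats::rnorm(nrow(U))
    }
    out
  }
  structure(list(k = as.integer(k), signs = signs, noise = noise,
                 seed = as.integer(seed), fun = fun),
            class = "AnalyticBenchmark")
}

#' @export
print.AnalyticBenchmark <- function(x, ...) {
  cat("AnalyticBenchmark: k = ", x$k, ", signs = (",
      paste(x$signs, collapse = ", "), "), noise = ", x$noise, "\n",
      sep = "")
  invisible(x)
}

#' Analytic AUC benchmark models
#'
#' Tiny kinetic models whose AUC metric has a closed form, for validating
#' the joint-integration AUC and the local sensitivity spectrum:
#' \describe{
#'   \item{exponential_relaxation}{one state relaxing as dy/dt = -y / tau
#'     from y(0) = y_tot; the normalised readout is exp(-t / tau) and
#'     S = tau * (1 - exp(-T / tau)).}
#'   \item{two_state}{activation/deactivation between Y0 and Y,
#'     dY/dt = k1 * Y0 - k2 * Y with Y(0) = 0; the normalised readout tends
#'     to k1 / (k1 + k2) and S = ye * (T - (1 - exp(-lambda T)) / lambda)
#'     with lambda = k1 + k2, ye = k1 / lambda.}
#' }
#' Closed forms are available through \code{\link{analyticAuc}} and
#' \code{\link{analyticLogGain}}.
#'
#' @param kind "exponential_relaxation" or "two_state".
#' @return a \linkS4class{KineticModel} bundling its readout.
#' @export
makeAnalyticAucModel <- function(kind = c("exponential_relaxation",
                                          "two_state")) {
  kind <- match.arg(kind)
  if (kind == "exponential_relaxation") {
    KineticModel("exponential_relaxation",
      species = data.frame(name = "y", initial = 1),
      parameters = c(tau = 10, y_tot = 1),
      reactions = list(list(id = "relaxation", reactants = c(y = 1),
                            products = numeric(), rate = quote(y / tau))),
      initialExprs = list(y = quote(y_tot)),
      parameterUnits = c(y_tot = "nM"),
      readouts = list(y = Readout("y", species = "y", normalizer = "y_tot")))
  } else {
    KineticModel("two_state",
      species = data.frame(name = c("Y0", "Y"), initial = c(1, 0)),
      parameters = c(k1 = 0.2, k2 = 0.1, Y_tot = 1),
      reactions = list(
        list(id = "activation", reactants = c(Y0 = 1), products = c(Y = 1),
             rate = quote(k1 * Y0)),
        list(id = "deactivation", reactants = c(Y = 1), products = c(Y0 = 1),
             rate = quote(k2 * Y))),
      initialExprs = list(Y0 = quote(Y_tot)),
      parameterUnits = c(Y_tot = "nM"),
      conserved = list(Y_pool = list(species = c("Y0", "Y"),
                                     total = "Y_tot")),
      readouts = list(y = Readout("y", species = "Y", normalizer = "Y_tot")))
  }
}

# closed-form S expressions per kind, as unevaluated expressions so that
# analytic derivatives come from symbolic differentiation
.analyticAucExpr <- list(
  exponential_relaxation = quote(tau * (1 - exp(-T_horizon / tau))),
  two_state = quote(k1 / (k1 + k2) *
                    (T_horizon - (1 - exp(-(k1 + k2) * T_horizon)) /
                       (k1 + k2))))

#' Closed-form AUC of an analytic benchmark model
#'
#' @param kind model kind (see \code{\link{makeAnalyticAucModel}}).
#' @param params named list/vector of the model's parameters.
#' @param T_horizon integration horizon, minutes.
#' @return S_y in minutes.
#' @examples
#' analyticAuc("exponential_relaxation", c(tau = 10), 60)
#' @export
analyticAuc <- function(kind, params, T_horizon) {
  expr <- .analyticAucExpr[[kind]]
  if (is.null(expr)) stop("unknown kind: ", kind)
  eval(expr, c(as.list(params), list(T_horizon = T_horizon)))
}

#' Closed-form logarithmic gain d log S / d log p of an analytic model
#'
#' Symbolic derivative of the closed-form AUC, normalised to the logarithmic
#' scale -- the quantity the central-difference local sensitivity
#' coefficient approximates.
#'
#' @inheritParams analyticAuc
#' @param parameter name of the parameter to differentiate with respect to.
#' @return dimensionless logarithmic gain.
#' @export
analyticLogGain <- function(kind, params, parameter, T_horizon) {
  expr <- .analyticAucExpr[[kind]]
  if (is.null(expr)) stop("unknown kind: ", kind)
  dS <- stats::D(expr, parameter)
  env <- c(as.list(params), list(T_horizon = T_horizon))
  eval(dS, env) * env[[parameter]] / eval(expr, env)
}
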