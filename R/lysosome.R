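#' CellModelParams: compartment model parameters
#'
#' Parameters of the Fick-Nernst-Planck single-cell model of drug
#' accumulation. The model tracks total drug concentration in cytosol,
#' lysosome and mitochondrion, exchanging with the external medium across
#' the plasma membrane. Neutral and ionic microspecies diffuse with
#' distinct permeabilities, ions feel the membrane potential through the
#' Goldman flux form, and a logP-driven lipid sorption term binds drug to
#' compartment lipids.
#'
#' All constants are explicit and overridable via
#' \code{\link{cellModelParams}}.
#'
#' @slot compartments data.frame (name, pH, volume_frac, potential_mV,
#'   area_to_volume, lipid_frac); potentials are inside relative to the
#'   adjacent outside compartment (plasma membrane: cytosol vs external;
#'   organelles: organelle vs cytosol).
#' @slot temperature_K absolute temperature.
#' @slot perm_slope,perm_intercept neutral-species membrane permeability:
#'   log10 P_n (um/min) = perm_slope * logP + perm_intercept.
#' @slot ionic_perm_offset log10 units subtracted for ionic species.
#' @slot aqueous_perm aqueous boundary-layer permeability (um/min) capping
#'   the effective membrane permeability.
#' @slot sorption_slope,sorption_intercept lipid sorption coefficient:
#'   log10 K = sorption_slope * logP + sorption_intercept.
#' @slot external_conc_uM external drug concentration (uM).
#' @slot external_finite treat the external medium as a finite reservoir
#'   (closed system) instead of an infinite bath.
#' @slot external_volume_frac external volume relative to cell volume
#'   (used when \code{external_finite}).
#' @export
setClass("CellModelParams", representation(compartments = "data.frame",
  temperature_K = "numeric", perm_slope = "numeric",
  perm_intercept = "numeric", ionic_perm_offset = "numeric",
  aqueous_perm = "numeric", sorption_slope = "numeric",
  sorption_intercept = "numeric", external_conc_uM = "numeric",
  external_finite = "logical", external_volume_frac = "numeric"))

setValidity("CellModelParams", function(object) {
  cmp <- object@compartments
  need <- c("external", "cytosol", "lysosome", "mitochondrion")
  if (!identical(cmp$name, need))
    return("compartments must be external, cytosol, lysosome, mitochondrion")
  if (any(cmp$pH < 0 | cmp$pH > 14)) return("pH must lie in [0, 14]")
  if (any(cmp$volume_frac <= 0)) return("volumes must be > 0")
  TRUE
})

#' Construct cell-model parameters
#'
#' The default preset places the external medium at pH 7.4 (a DMEM-like
#' pH 7.5 is available via \code{medium = "dmem"}), cytosol at pH 7.2,
#' lysosome at pH 5.0 and mitochondrion at pH 8.0, with membrane potentials
#' of -70 mV (plasma), +10 mV (lysosome) and -160 mV (mitochondrion).
#' Neutral permeability is log-linear in logP
#' (\code{log10 P = logP + 1} um/min), capped by an aqueous boundary layer
#' of 1e5 um/min; ionic permeability is 10^-3.5 of neutral. Lipid sorption
#' uses \code{log10 K = logP - 1} with a 5\% lipid volume fraction in the
#' cellular compartments and none outside.
#'
#' @param medium "standard" (pH 7.4) or "dmem" (pH 7.5).
#' @param compartment_pH optional named numeric overriding any of the
#'   compartment pH values (external, cytosol, lysosome, mitochondrion).
#' @param external_conc_uM external drug concentration, default 10 uM.
#' @param potentials_mV named numeric (cytosol, lysosome, mitochondrion).
#' @param ionic_perm_offset log10 ionic/neutral permeability ratio;
#'   \code{-Inf} switches ionic diffusion off (neutral-only limit).
#' @param lipid_frac lipid volume fraction of the cellular compartments;
#'   0 switches sorption off.
#' @param aqueous_perm boundary-layer permeability (um/min).
#' @param perm_slope,perm_intercept neutral permeability model.
#' @param sorption_slope,sorption_intercept sorption coefficient model.
#' @param external_finite,external_volume_frac closed-system configuration.
#' @param temperature_K absolute temperature, default 310 K.
#' @return A \linkS4class{CellModelParams}.
#' @examples
#' cellModelParams()
#' @export
cellModelParams <- function(medium = c("standard", "dmem"),
    compartment_pH = NULL, external_conc_uM = 10,
    potentials_mV = c(cytosol = -70, lysosome = 10, mitochondrion = -160),
    ionic_perm_offset = -3.5, lipid_frac = 0.05, aqueous_perm = 1e5,
    perm_slope = 1, perm_intercept = 0,
    sorption_slope = 1, sorption_intercept = -1,
    external_finite = FALSE, external_volume_frac = 50,
    temperature_K = 310) {
  medium <- match.arg(medium)
  ph_ext <- if (medium == "dmem") 7.5 else 7.4
  cmp <- data.frame(
    name = c("external", "cytosol", "lysosome", "mitochondrion"),
    pH = c(ph_ext, 7.2, 5.0, 8.0),
    volume_frac = c(external_volume_frac, 0.94, 0.01, 0.05),
    potential_mV = c(0, potentials_mV[["cytosol"]],
                     potentials_mV[["lysosome"]],
                     potentials_mV[["mitochondrion"]]),
    area_to_volume = c(0, 0.375, 6, 6),
    lipid_frac = c(0, lipid_frac, lipid_frac, lipid_frac),
    stringsAsFactors = FALSE)
  if (!is.null(compartment_pH))
    for (nm in names(compartment_pH))
      cmp$pH[cmp$name == nm] <- compartment_pH[[nm]]
  new("CellModelParams", compartments = cmp, temperature_K = temperature_K,
      perm_slope = perm_slope, perm_intercept = perm_intercept,
      ionic_perm_offset = ionic_perm_offset, aqueous_perm = aqueous_perm,
      sorption_slope = sorption_slope,
      sorption_intercept = sorption_intercept,
      external_conc_uM = external_conc_uM,
      external_finite = external_finite,
      external_volume_frac = external_volume_frac)
}

#' @export
setMethod("show", "CellModelParams", function(object) {
  cat("CellModelParams\n")
  print(object@compartments, row.names = FALSE)
  cat(sprintf("  ext conc %g uM | ion offset %g | lipid sorption 10^(%g*logP%+g)\n",
              object@external_conc_uM, object@ionic_perm_offset,
              object@sorption_slope, object@sorption_intercept))
})

#' Speciation profile of a compound
#'
#' One of four ionization variants used by the kinetic cell model:
#' \code{monoacid} (neutral/anion), \code{monobase} (neutral/cation),
#' \code{bibase} (neutral/mono-/di-cation) and \code{zwitter} (independent
#' basic and acidic site: neutral, cation, anion, zwitterion). Compounds
#' with no pKa value in the relevant region are treated as a monoacid with
#' pKa 15 (effectively neutral at physiological pH).
#'
#' @param variant one of "monoacid", "monobase", "bibase", "zwitter".
#' @param pka_base1,pka_base2 basic pKa values (base1 >= base2).
#' @param pka_acid acidic pKa.
#' @return list of class \code{SpeciationProfile}.
#' @export
speciationProfile <- function(variant = c("monoacid", "monobase", "bibase",
                                          "zwitter"),
                              pka_base1 = NA_real_, pka_base2 = NA_real_,
                              pka_acid = NA_real_) {
  variant <- match.arg(variant)
  ok <- switch(variant,
    monoacid = is.finite(pka_acid),
    monobase = is.finite(pka_base1),
    bibase = is.finite(pka_base1) && is.finite(pka_base2),
    zwitter = is.finite(pka_base1) && is.finite(pka_acid))
  if (!ok)
    stop(sprintf("variant '%s' lacks the required pKa values", variant),
         call. = FALSE)
  if (variant == "bibase" && pka_base2 > pka_base1)
    stop("pka_base1 must be >= pka_base2", call. = FALSE)
  structure(list(variant = variant, pka_base1 = pka_base1,
                 pka_base2 = pka_base2, pka_acid = pka_acid),
            class = "SpeciationProfile")
}

#' Speciation profile for an ionization category
#'
#' Maps the assay-set ionization categories onto the kinetic model
#' variants; the \code{none} category uses the monoacid model with a pKa
#' of 15.
#'
#' @param category one of "acid", "monobase", "bibase", "zwitter", "none".
#' @param pka_base1,pka_base2,pka_acid pKa values as available.
#' @return A \code{SpeciationProfile}.
#' @export
profileForCategory <- function(category, pka_base1 = NA_real_,
                               pka_base2 = NA_real_, pka_acid = NA_real_) {
  switch(category,
    acid = speciationProfile("monoacid", pka_acid = pka_acid),
    monobase = speciationProfile("monobase", pka_base1 = pka_base1),
    bibase = speciationProfile("bibase", pka_base1 = pka_base1,
                               pka_base2 = pka_base2),
    zwitter = speciationProfile("zwitter", pka_base1 = pka_base1,
                                pka_acid = pka_acid),
    none = speciationProfile("monoacid", pka_acid = 15),
    stop("unknown ionization category: ", category, call. = FALSE))
}

#' Microspecies fractions at a given pH
#'
#' Henderson-Hasselbalch equilibrium fractions of the microspecies
#' \code{neutral}, \code{cation1} (+1), \code{cation2} (+2), \code{anion}
#' (-1) and \code{zwitterion} (net 0 but ionic) for a speciation profile.
#' Fractions sum to 1.
#'
#' @param profile A \code{SpeciationProfile}.
#' @param pH pH in [0, 14].
#' @return named numeric vector of 5 fractions.
#' @examples
#' fractionSpeciation(speciationProfile("monobase", pka_base1 = 9), 9)
#' @export
fractionSpeciation <- function(profile, pH) {
  stopifnot(inherits(profile, "SpeciationProfile"))
  if (pH < 0 || pH > 14) stop("pH must lie in [0, 14]", call. = FALSE)
  f <- c(neutral = 0, cation1 = 0, cation2 = 0, anion = 0, zwitterion = 0)
  if (profile$variant == "monoacid") {
    r <- 10^(pH - profile$pka_acid)        # deprotonated / neutral
    f["neutral"] <- 1 / (1 + r); f["anion"] <- r / (1 + r)
  } else if (profile$variant == "monobase") {
    r <- 10^(profile$pka_base1 - pH)       # protonated / neutral
    f["neutral"] <- 1 / (1 + r); f["cation1"] <- r / (1 + r)
  } else if (profile$variant == "bibase") {
    r1 <- 10^(profile$pka_base1 - pH)
    r2 <- 10^(profile$pka_base2 - pH)
    z <- 1 + r1 + r1 * r2
    f["neutral"] <- 1 / z; f["cation1"] <- r1 / z
    f["cation2"] <- r1 * r2 / z
  } else {
    pb <- 1 / (1 + 10^(pH - profile$pka_base1))   # base protonated
    pa <- 1 / (1 + 10^(profile$pka_acid - pH))    # acid deprotonated
    f["cation1"] <- pb * (1 - pa)
    f["neutral"] <- (1 - pb) * (1 - pa)
    f["anion"] <- (1 - pb) * pa
    f["zwitterion"] <- pb * pa
  }
  f
}

.speciesCharge <- c(neutral = 0, cation1 = 1, cation2 = 2, anion = -1,
                    zwitterion = 0)

# Goldman flux coefficients for charge z across potential V (mV):
# influx J = P * [A * a_out - B * a_in]; A = N/(exp(N)-1), B = A*exp(N),
# N = zFV/RT. z = 0 gives A = B = 1.
.goldmanCoefs <- function(z, V_mV, temperature_K) {
  if (z == 0) return(c(A = 1, B = 1))
  N <- z * 96485 * (V_mV / 1000) / (8.314 * temperature_K)
  if (abs(N) < 1e-9) return(c(A = 1, B = 1))
  A <- N / (exp(N) - 1)
  c(A = A, B = A * exp(N))
}

# Free aqueous fraction given the sorption coefficient and lipid fraction.
.freeFraction <- function(params, logp, lipid_frac) {
  if (lipid_frac <= 0) return(1)
  K <- 10^(params@sorption_slope * logp + params@sorption_intercept)
  1 / (1 + K * lipid_frac)
}

# Per-membrane rate coefficients k_in (on outside conc) and k_out (on
# inside conc), per unit area-to-volume, summed over microspecies.
.membraneRates <- function(profile, params, logp, outside, inside) {
  cmp <- params@compartments
  o <- cmp[cmp$name == outside, ]; i <- cmp[cmp$name == inside, ]
  P_mem <- 10^(params@perm_slope * logp + params@perm_intercept)
  ion_scale <- 10^params@ionic_perm_offset
  f_o <- fractionSpeciation(profile, o$pH)
  f_i <- fractionSpeciation(profile, i$pH)
  W_o <- .freeFraction(params, logp, o$lipid_frac)
  W_i <- .freeFraction(params, logp, i$lipid_frac)
  V <- i$potential_mV
  k_in <- 0; k_out <- 0
  for (s in names(.speciesCharge)) {
    P_s <- if (s == "neutral") P_mem else P_mem * ion_scale
    if (P_s == 0) next
    P_eff <- 1 / (1 / P_s + 1 / params@aqueous_perm)
    g <- .goldmanCoefs(.speciesCharge[[s]], V, params@temperature_K)
    k_in <- k_in + P_eff * g[["A"]] * W_o * f_o[[s]]
    k_out <- k_out + P_eff * g[["B"]] * W_i * f_i[[s]]
  }
  c(k_in = k_in, k_out = k_out)
}

# Assemble the linear system dy/dt = M y + b over
# y = (cytosol, lysosome, mitochondrion[, external]).
.cellSystem <- function(profile, params, logp) {
  cmp <- params@compartments
  avr <- setNames(cmp$area_to_volume, cmp$name)
  vol <- setNames(cmp$volume_frac, cmp$name)
  pm <- .membraneRates(profile, params, logp, "external", "cytosol")
  ly <- .membraneRates(profile, params, logp, "cytosol", "lysosome")
  mt <- .membraneRates(profile, params, logp, "cytosol", "mitochondrion")
  nExt <- if (params@external_finite) 4L else 3L
  M <- matrix(0, nExt, nExt)
  b <- numeric(nExt)
  # cytosol
  M[1, 1] <- -avr[["cytosol"]] * pm[["k_out"]] -
    avr[["lysosome"]] * (vol[["lysosome"]] / vol[["cytosol"]]) * ly[["k_in"]] -
    avr[["mitochondrion"]] * (vol[["mitochondrion"]] / vol[["cytosol"]]) *
      mt[["k_in"]]
  M[1, 2] <- avr[["lysosome"]] * (vol[["lysosome"]] / vol[["cytosol"]]) *
    ly[["k_out"]]
  M[1, 3] <- avr[["mitochondrion"]] *
    (vol[["mitochondrion"]] / vol[["cytosol"]]) * mt[["k_out"]]
  # lysosome
  M[2, 1] <- avr[["lysosome"]] * ly[["k_in"]]
  M[2, 2] <- -avr[["lysosome"]] * ly[["k_out"]]
  # mitochondrion
  M[3, 1] <- avr[["mitochondrion"]] * mt[["k_in"]]
  M[3, 3] <- -avr[["mitochondrion"]] * mt[["k_out"]]
  if (params@external_finite) {
    M[1, 4] <- avr[["cytosol"]] * pm[["k_in"]]
    M[4, 1] <- avr[["cytosol"]] * (vol[["cytosol"]] / vol[["external"]]) *
      pm[["k_out"]]
    M[4, 4] <- -avr[["cytosol"]] * (vol[["cytosol"]] / vol[["external"]]) *
      pm[["k_in"]]
  } else {
    b[1] <- avr[["cytosol"]] * pm[["k_in"]] * params@external_conc_uM
  }
  list(M = M, b = b)
}

#' AccumulationResult: simulated compartment concentrations
#'
#' @slot times time grid (min).
#' @slot conc matrix of total concentrations (uM), one column per
#'   compartment (cytosol, lysosome, mitochondrion[, external]).
#' @slot steady_state steady-state concentrations (uM).
#' @slot ratio_lys_ext steady-state lysosome/external total ratio.
#' @slot time_to_fraction minutes to reach \code{fraction} of the
#'   steady-state lysosomal concentration (NA if beyond the grid).
#' @slot fraction the fraction used.
#' @export
setClass("AccumulationResult", representation(times = "numeric",
  conc = "matrix", steady_state = "numeric", ratio_lys_ext = "numeric",
  time_to_fraction = "numeric", fraction = "numeric"))

#' @export
setMethod("show", "AccumulationResult", function(object) {
  cat(sprintf(
    "AccumulationResult: %d time points to %.1f min\n  steady state (uM): %s\n",
    length(object@times), max(object@times),
    paste(sprintf("%s=%.4g", names(object@steady_state),
                  object@steady_state), collapse = ", ")))
  cat(sprintf("  lysosome/external ratio %.4g; t(%.0f%%) = %.3g min\n",
              object@ratio_lys_ext, 100 * object@fraction,
              object@time_to_fraction))
})

#' Analytic steady state of the cell model
#'
#' The compartment model is linear and time-invariant, so its steady state
#' solves \code{M y = -b} directly; for a finite external reservoir the
#' (singular) conservation system is solved with the mass-balance
#' constraint. Agrees with the long-time ODE limit (verified by the
#' package tests).
#'
#' @param profile A \code{SpeciationProfile}.
#' @param params A \linkS4class{CellModelParams}.
#' @param logp compound logP.
#' @return named steady-state concentrations (uM).
#' @export
steadyStateConcentrations <- function(profile, params, logp) {
  sys <- .cellSystem(profile, params, logp)
  nm <- c("cytosol", "lysosome", "mitochondrion")
  if (!params@external_finite) {
    y <- solve(sys$M, -sys$b)
    setNames(c(y, params@external_conc_uM), c(nm, "external"))
  } else {
    # replace one row by the conservation constraint sum(V_i C_i) = const
    vol <- setNames(params@compartments$volume_frac,
                    params@compartments$name)
    v <- c(vol[nm], vol[["external"]])
    A <- rbind(sys$M[-4, ], v)
    rhs <- c(rep(0, 3), vol[["external"]] * params@external_conc_uM)
    setNames(solve(A, rhs), c(nm, "external"))
  }
}

#' Simulate drug accumulation into cellular compartments
#'
#' Integrates the Fick-Nernst-Planck compartment model: neutral-species
#' flux proportional to the activity difference across each membrane,
#' ionic flux in the Goldman form with the compartment potential, lipid
#' sorption through the free-fraction term. Internal concentrations start
#' at 0; the external medium is an infinite bath unless the parameters say
#' otherwise.
#'
#' @param profile A \code{SpeciationProfile}.
#' @param params A \linkS4class{CellModelParams}.
#' @param logp compound logP.
#' @param duration total simulated time (min), > 0.
#' @param n_steps number of output points (log-spaced plus 0).
#' @param fraction fraction of steady state defining
#'   \code{time_to_fraction} (default 0.95).
#' @return An \linkS4class{AccumulationResult}.
#' @examples
#' pr <- speciationProfile("monobase", pka_base1 = 9)
#' res <- simulateAccumulation(pr, cellModelParams(), logp = 3,
#'                             duration = 60)
#' @export
simulateAccumulation <- function(profile, params, logp, duration,
                                 n_steps = 200L, fraction = 0.95) {
  stopifnot(duration > 0)
  sys <- .cellSystem(profile, params, logp)
  n <- nrow(sys$M)
  y0 <- numeric(n)
  if (params@external_finite) y0[4] <- params@external_conc_uM
  times <- c(0, exp(seq(log(duration / 1e4), log(duration),
                        length.out = n_steps)))
  deriv <- function(t, y, p) list(sys$M %*% y + sys$b)
  out <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed (istate ",
         attr(out, "istate")[1], ")", call. = FALSE)
  conc <- out[, -1, drop = FALSE]
  nm <- c("cytosol", "lysosome", "mitochondrion",
          if (params@external_finite) "external")
  colnames(conc) <- nm
  if (min(conc) < -1e-6 * max(abs(conc), 1))
    stop("negative concentration beyond tolerance", call. = FALSE)
  conc[conc < 0] <- 0
  ss <- steadyStateConcentrations(profile, params, logp)
  ratio <- unname(ss[["lysosome"]] / ss[["external"]])
  target <- fraction * ss[["lysosome"]]
  lys <- conc[, "lysosome"]
  ttf <- NA_real_
  idx <- which(lys >= target)
  if (length(idx)) {
    i <- idx[1]
    if (i == 1L) ttf <- out[1, 1] else {
      t0 <- out[i - 1, 1]; t1 <- out[i, 1]
      y0v <- lys[i - 1]; y1v <- lys[i]
      ttf <- t0 + (target - y0v) / (y1v - y0v) * (t1 - t0)
    }
  }
  new("AccumulationResult", times = out[, 1], conc = conc,
      steady_state = ss, ratio_lys_ext = ratio, time_to_fraction = ttf,
      fraction = fraction)
}

#' Minimal sufficient incubation time
#'
#' First time at which the lysosomal concentration reaches a stated
#' fraction (default 0.95) of its steady-state value. Compounds with very
#' high pKa and/or logP, and bibasic compounds, take markedly longer than
#' the standard 30-minute screening window.
#'
#' @param profile A \code{SpeciationProfile}.
#' @param params A \linkS4class{CellModelParams}.
#' @param logp compound logP.
#' @param fraction fraction of steady state (default 0.95).
#' @param cap maximal considered incubation (min, default 1e5).
#' @return time in minutes, or \code{Inf} when the fraction is not reached
#'   within \code{cap} (reported as "exceeds cap" by the pipeline).
#' @export
requiredIncubation <- function(profile, params, logp, fraction = 0.95,
                               cap = 1e5) {
  stopifnot(fraction > 0, fraction < 1)
  duration <- 60
  repeat {
    res <- simulateAccumulation(profile, params, logp, duration,
                                fraction = fraction)
    if (!is.na(res@time_to_fraction)) return(res@time_to_fraction)
    duration <- duration * 4
    if (duration > cap * 4) return(Inf)
  }
}

#' Calculated lysosomal concentration (CLys)
#'
#' Steady-state total lysosomal drug concentration at the standard preset;
#' used as a molecular descriptor.
#'
#' @param profile A \code{SpeciationProfile}.
#' @param params A \linkS4class{CellModelParams}.
#' @param logp compound logP.
#' @return concentration in uM.
#' @export
clysDescriptor <- function(profile, params = cellModelParams(), logp) {
  unname(steadyStateConcentrations(profile, params, logp)[["lysosome"]])
}
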