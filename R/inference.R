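#' Specification of a model fit
#'
#' Chooses the spatial formulation and the single active combined-effect
#' hypothesis (the one-hypothesis-at-a-time experimental design).
#' Formulations: `"v1"` (sightings-driven Dirichlet occupancy), `"v2"`
#' (density-surface occupancy), `"v3"` (non-spatial; population-level annual
#' covariates, no occupancy).  Exposure-level hypotheses require a spatial
#' formulation; the prolonged-health-on-length hypothesis is only tested in
#' the non-spatial version.
#'
#' @slot formulation `"v1"`, `"v2"` or `"v3"`.
#' @slot hypothesis active combined-effect hypothesis.
#' @slot monitors parameters to monitor in MCMC.
#' @export
setClass("ModelSpec",
  representation(formulation = "character", hypothesis = "character",
                 monitors = "character"))

HEALTH_HYPOTHESES <- c("gearPrey", "sevPrey", "injPrey", "nPrior",
                       "priorAny", "prior2yr")
LENGTH_HYPOTHESES <- c("prolongedHealth", "motherHealthStart",
                       "motherHealthYear", "preyEntWindow", "motherEnt")
EXPOSURE_HYPOTHESES <- c("distEnt", "distStrike", "preyEntRisk",
                         "preyStrikeRisk")

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!object@formulation %in% c("v1", "v2", "v3"))
    msg <- c(msg, "formulation must be v1, v2 or v3")
  ok <- c("none", HEALTH_HYPOTHESES, LENGTH_HYPOTHESES, EXPOSURE_HYPOTHESES)
  if (!object@hypothesis %in% ok)
    msg <- c(msg, paste("unknown hypothesis; valid:", paste(ok, collapse = ", ")))
  if (object@formulation == "v3" && object@hypothesis %in% EXPOSURE_HYPOTHESES)
    msg <- c(msg, "exposure-level combined effects need a spatial formulation (v1/v2)")
  if (object@formulation != "v3" && object@hypothesis == "prolongedHealth")
    msg <- c(msg, "prolonged-health-on-length is only tested in the non-spatial version (v3)")
  if (length(msg)) msg else TRUE
})

#' @describeIn ModelSpec-class Constructor.
#' @param formulation,hypothesis,monitors see slots.
#' @export
modelSpec <- function(formulation = "v1", hypothesis = "none",
                      monitors = character(0)) {
  new("ModelSpec", formulation = formulation, hypothesis = hypothesis,
      monitors = monitors)
}

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec: formulation", object@formulation,
      "| hypothesis", object@hypothesis, "\n")
})

# ---- joint density (pure-R composition, used for toy-model checks) ---------

#' Joint log-density of one individual's latent states and data
#'
#' Pure-R composition of the component densities: health-increment
#' likelihood, ordinal score likelihood, survival likelihood, length
#' measurement likelihood and sighting likelihood.  This mirrors the density
#' the MCMC engine samples from and exists so the composition can be checked
#' term by term.
#'
#' @param h health trajectory (length `T`).
#' @param drifts deterministic health drifts (length `T - 1`).
#' @param surv 0/1 survival outcomes per step (1 = survived the step).
#' @param vhaRows data.frame `(t, variable, score)` of ordinal observations.
#' @param lengthRows data.frame `(t, P, L, platform)` of measurements.
#' @param seen 0/1 sighting indicator per step.
#' @param z occupancy matrix `[step, region]`.
#' @param quarters season index per step.
#' @param healthPar [healthParameters()] list.
#' @param vitalPar [vitalRateParameters()] list.
#' @param obsPar [observationParameters()] list.
#' @return log-density (sum over all components).
#' @export
jointLogDensity <- function(h, drifts, surv, vhaRows, lengthRows, seen, z,
                            quarters, healthPar, vitalPar, obsPar) {
  ll <- healthLoglik(h, drifts, healthPar)
  th <- survivalProbability(h, vitalPar)
  ll <- ll + sum(ifelse(surv == 1, log(th), log(1 - th)))
  if (nrow(vhaRows))
    ll <- ll + sum(mapply(function(t, v, s) vhaLoglik(s, h[t], v, obsPar),
                          vhaRows$t, vhaRows$variable, vhaRows$score))
  if (nrow(lengthRows))
    ll <- ll + sum(mapply(function(P, L, pl)
      lengthMeasurementLoglik(P, L, pl, obsPar),
      lengthRows$P, lengthRows$L, lengthRows$platform))
  alive <- c(rep(TRUE, length(h)))
  ll + sightingLoglik(seen, z, alive, quarters, obsPar)
}

# ---- data preparation -------------------------------------------------------

#' Assemble fit-ready arrays from a dataset
#'
#' Builds the per-individual covariate and observation arrays the MCMC model
#' consumes: step ranges, gear-carrying and event-severity indicators from
#' the observed event records, strike-injury indicators, intrinsic covariates
#' (calf-to-juvenile transition, lactation), the standardized annual prey
#' covariate from the formulation's occupancy, and flattened ordinal-score
#' and survival observations.
#'
#' Individuals enter at their first known step (birth if the birth year is
#' known and inside the frame, otherwise first sighting) and leave at the
#' recorded death step or, if never recovered, their last sighting
#' (right-censored there).
#'
#' @param dataset list with `frame`, `surfaces`, `individuals`,
#'   `observations` (the observed components of [simulateDataset()] output,
#'   or data read by [readIndividuals()] / [readSurfaces()]).
#' @param spec a [modelSpec()].
#' @param maturityAge passed to the occupancy class assignment.
#' @return list of arrays ready for [buildJointModel()].
#' @export
prepareModelData <- function(dataset, spec, maturityAge = 9L) {
  frame <- dataset$frame
  obs <- dataset$observations
  ind <- dataset$individuals
  T <- nSteps(frame)

  # occupancy by formulation
  occ <- switch(spec@formulation,
    v1 = occupancyV1All(fitDirichletOccupancy(obs, ind, frame)),
    v2 = occupancyV2(dataset$surfaces,
                     classPropsFromSightings(obs, ind, frame)),
    v3 = {
      R <- nRegions(frame)
      z <- array(1 / R, c(T, length(DEMOGRAPHIC_CLASSES), R),
                 dimnames = list(NULL, DEMOGRAPHIC_CLASSES,
                                 regionLabels(frame)))
      new("OccupancyDistribution", z = z, classes = DEMOGRAPHIC_CLASSES,
          version = "v3", frame = frame)
    })

  # pooled standardized annual prey from the adult-female occupancy
  preyM <- assay(dataset$surfaces, "prey")
  ci <- match("adult female", occ@classes)
  preyW <- sapply(seq_len(T), function(t)
    individualPreyIndex(occ@z[t, ci, ], preyM[, t]))
  std <- annualizeAndStandardize(preyW, stepYear(frame, seq_len(T)))
  preyStdYear <- std$annual   # named by year
  preyStd <- preyStdYear[as.character(stepYear(frame, seq_len(T)))]

  sg <- obsStream(obs, "sightings")
  ids <- ind$id
  firstSight <- tapply(sg$t, sg$id, min)[ids]
  lastSight <- tapply(sg$t, sg$id, max)[ids]
  first <- unname(firstSight)
  known <- !is.na(ind$birthYear)
  if (any(known))
    first[known] <- stepIndex(
      frame, pmin(pmax(ind$birthYear[known], min(frameYears(frame))),
                  max(frameYears(frame))), 1L)
  last <- ifelse(!is.na(ind$deathStep), ind$deathStep, lastSight)
  keep <- !is.na(first) & !is.na(last) & (last - first >= 2L)
  ind <- ind[keep, ]; first <- as.integer(first[keep]); last <- as.integer(last[keep])
  ids <- ind$id
  N <- length(ids)
  idx <- setNames(seq_len(N), ids)

  zero <- function() matrix(0, N, T)
  gear <- zero(); sev <- array(0, c(N, T, 3L)); inj <- array(0, c(N, T, 4L))
  trans <- zero(); lact <- zero()
  nPriorM <- zero(); anyPriorM <- zero(); prior2yrM <- zero()

  ent <- obsStream(obs, "entanglements")
  ent <- ent[ent$id %in% ids, , drop = FALSE]
  if (nrow(ent)) {
    for (r in seq_len(nrow(ent))) {
      n <- idx[[ent$id[r]]]
      t0 <- ent$t[r]
      if (t0 < first[n] || t0 > last[n]) next
      si <- match(ent$severity[r], SEVERITY_LEVELS)
      sev[n, t0, si] <- 1
      tEnd <- min(t0 + ent$gearSteps[r] - 1L, last[n], T)
      gear[n, t0:tEnd] <- 1
    }
    for (id in unique(ent$id)) {
      n <- idx[[id]]
      steps <- sort(ent$t[ent$id == id])
      for (t0 in steps) {
        f <- eventHistoryFeatures(steps, t0)
        nPriorM[n, t0] <- f$nPrior
        anyPriorM[n, t0] <- f$anyPrior
        prior2yrM[n, t0] <- f$anyPrior2yr
      }
    }
  }
  str <- obsStream(obs, "strikes")
  str <- str[str$id %in% ids, , drop = FALSE]
  if (nrow(str)) for (r in seq_len(nrow(str))) {
    n <- idx[[str$id[r]]]
    if (str$t[r] < first[n] || str$t[r] > last[n]) next
    inj[n, str$t[r], match(str$injury[r], INJURY_LEVELS)] <- 1
  }
  cv <- obsStream(obs, "calvings")
  yrsOf <- stepYear(frame, seq_len(T))
  for (n in seq_len(N)) {
    by <- ind$birthYear[n]
    if (!is.na(by)) {
      tTrans <- suppressWarnings(tryCatch(stepIndex(frame, by + 1L, 1L),
                                          error = function(e) NA_integer_))
      if (!is.na(tTrans) && tTrans >= first[n] && tTrans <= last[n])
        trans[n, tTrans] <- 1
    }
    if (ind$sex[n] == "F" && nrow(cv)) {
      yc <- cv$year[cv$id == ids[n] & cv$calved == 1]
      if (length(yc)) lact[n, yrsOf %in% yc] <- 1
    }
  }

  vha <- obsStream(obs, "vha")
  vha <- vha[vha$id %in% ids, , drop = FALSE]
  vn <- idx[vha$id]
  ok <- vha$t >= first[vn] & vha$t <= last[vn]
  vha <- vha[ok, , drop = FALSE]; vn <- vn[ok]

  surv <- matrix(NA_real_, N, T)
  for (n in seq_len(N)) {
    surv[n, first[n]:last[n]] <- 1
    if (!is.na(ind$deathStep[match(ids[n], ind$id)])) surv[n, last[n]] <- 0
  }

  summer <- as.integer(quarterLabels(frame)[stepQuarter(frame, seq_len(T))] == "Jun-Aug")

  list(frame = frame, spec = spec, individuals = ind, occ = occ,
       ids = ids, N = N, T = T, first = first, last = last,
       gear = gear, sev = sev, inj = inj, trans = trans, lact = lact,
       nPrior = nPriorM, anyPrior = anyPriorM, prior2yr = prior2yrM,
       preyStd = unname(preyStd), summer = summer, surv = surv,
       vha = data.frame(n = vn, t = vha$t, variable = vha$variable,
                        score = vha$score),
       preyConstants = std$constants)
}

# ---- model construction -----------------------------------------------------

.healthSurvivalModelString <- function(hypothesis, nCat = 3L) {
  inter <- switch(hypothesis,
    gearPrey = "+ gammaGearPrey * gearPrey[n, t]",
    sevPrey = "+ gammaSevPrey[1]*sevPrey1[n,t] + gammaSevPrey[2]*sevPrey2[n,t] + gammaSevPrey[3]*sevPrey3[n,t]",
    injPrey = "+ gammaInjPrey[1]*injPrey1[n,t] + gammaInjPrey[2]*injPrey2[n,t] + gammaInjPrey[3]*injPrey3[n,t] + gammaInjPrey[4]*injPrey4[n,t]",
    nPrior = "+ gammaNPrior * nPriorEv[n, t]",
    priorAny = "+ gammaPriorAny * anyPriorEv[n, t]",
    prior2yr = "+ gammaPrior2yr * prior2yrEv[n, t]",
    "")
  interPrior <- switch(hypothesis,
    gearPrey = "gammaGearPrey ~ dnorm(0, 0.1)",
    sevPrey = "for (s in 1:3) { gammaSevPrey[s] ~ dnorm(0, 0.1) }",
    injPrey = "for (s in 1:4) { gammaInjPrey[s] ~ dnorm(0, 0.1) }",
    nPrior = "gammaNPrior ~ dnorm(0, 0.1)",
    priorAny = "gammaPriorAny ~ dnorm(0, 0.1)",
    prior2yr = "gammaPrior2yr ~ dnorm(0, 0.1)",
    "")
  paste0("
model {
  for (n in 1:N) {
    h[n, first[n]] ~ dunif(1, 100)
    for (t in (first[n] + 1):last[n]) {
      mu[n, t] <- h[n, t - 1]
        + transEff * trans[n, t] + lactEff * lact[n, t]
        + deltaSev[1] * sev1[n, t] + deltaSev[2] * sev2[n, t]
        + deltaSev[3] * sev3[n, t]
        + deltaGear * gear[n, t]
        + deltaInj[1] * inj1[n, t] + deltaInj[2] * inj2[n, t]
        + deltaInj[3] * inj3[n, t] + deltaInj[4] * inj4[n, t]
        + betaPrey * preySummer[t]
        ", inter, "
      h[n, t] ~ dnorm(mu[n, t], tauH) T(0.01, 100)
    }
    for (t in first[n]:last[n]) {
      lambda[n, t] <- exp(aC - bS * (h[n, t] - 70))
      surv[n, t] ~ dbern(exp(-lambda[n, t]))
    }
  }
  for (m in 1:M) {
    pv[m, 1] <- phi((kappa[vvar[m], 1] - h[vind[m], vt[m]]) / tauV[vvar[m]])
    ", paste(vapply(seq_len(nCat - 2L), function(c) sprintf(
      "pv[m, %d] <- phi((kappa[vvar[m], %d] - h[vind[m], vt[m]]) / tauV[vvar[m]]) - sum(pv[m, 1:%d])",
      c + 1L, c + 1L, c), character(1)), collapse = "\n    "), "
    pv[m, ", nCat, "] <- 1 - sum(pv[m, 1:", nCat - 1L, "])
    vscore[m] ~ dcat(pv[m, 1:", nCat, "])
  }
  tauH <- pow(sigmaH, -2)
  sigmaH ~ dunif(0.1, 10)
  transEff ~ dnorm(0, 0.1) T(, 0)
  lactEff ~ dnorm(0, 0.1) T(, 0)
  deltaGear ~ dnorm(0, 0.04) T(, 0)
  for (s in 1:3) { deltaSev[s] ~ dnorm(0, 0.002) T(, 0) }
  for (s in 1:4) { deltaInj[s] ~ dnorm(0, 0.002) T(, 0) }
  betaPrey ~ dnorm(0, 0.1)
  # hazard centered at health 70 to decorrelate intercept and slope
  aC ~ dnorm(-7, 0.25)
  bS ~ dunif(0, 0.5)
  aS <- aC + 70 * bS
  ", interPrior, "
}
")
}

#' Build the joint MCMC model for a dataset and specification
#'
#' Composes the latent-health random walk (with intrinsic effects, event
#' effects by severity and injury class, the prolonged gear effect, the prey
#' effect, and the active interaction term), the hazard-rate survival
#' likelihood, and the ordered-probit score likelihood into a single model,
#' together with the data list, per-chain initial values and the monitored
#' parameter set.  Occupancy enters as the plug-in class-level distribution
#' of the chosen formulation (resolved in [prepareModelData()]); observed
#' events are conditioned on.  Cutpoints and ordinal noise are fixed
#' observation constants that anchor the latent 0–100 scale.
#'
#' @param prep output of [prepareModelData()].
#' @param obsPar an [observationParameters()] list supplying cutpoints.
#' @return list `(model, data, inits, monitors, spec)`.
#' @export
buildJointModel <- function(prep, obsPar = observationParameters()) {
  spec <- prep$spec
  hyp <- spec@hypothesis
  if (hyp %in% c(LENGTH_HYPOTHESES))
    stop("length-level hypotheses are fitted with buildGrowthModel()")
  nCat <- length(obsPar$cutpoints[[1]]) + 1L
  maxT <- max(prep$last)   # JAGS sizes h by its largest used column
  prep$gear <- prep$gear[, 1:maxT, drop = FALSE]
  prep$sev <- prep$sev[, 1:maxT, , drop = FALSE]
  prep$inj <- prep$inj[, 1:maxT, , drop = FALSE]
  prep$trans <- prep$trans[, 1:maxT, drop = FALSE]
  prep$lact <- prep$lact[, 1:maxT, drop = FALSE]
  prep$nPrior <- prep$nPrior[, 1:maxT, drop = FALSE]
  prep$anyPrior <- prep$anyPrior[, 1:maxT, drop = FALSE]
  prep$prior2yr <- prep$prior2yr[, 1:maxT, drop = FALSE]
  prep$surv <- prep$surv[, 1:maxT, drop = FALSE]
  prep$preyStd <- prep$preyStd[1:maxT]
  prep$summer <- prep$summer[1:maxT]
  prep$T <- maxT
  dat <- list(
    N = prep$N, first = prep$first, last = prep$last,
    trans = prep$trans, lact = prep$lact,
    sev1 = prep$sev[, , 1], sev2 = prep$sev[, , 2], sev3 = prep$sev[, , 3],
    inj1 = prep$inj[, , 1], inj2 = prep$inj[, , 2],
    inj3 = prep$inj[, , 3], inj4 = prep$inj[, , 4],
    gear = prep$gear,
    preySummer = prep$preyStd * prep$summer,
    surv = prep$surv,
    M = nrow(prep$vha), vind = prep$vha$n, vt = prep$vha$t,
    vvar = prep$vha$variable, vscore = prep$vha$score,
    kappa = do.call(rbind, obsPar$cutpoints),
    tauV = obsPar$tauVha
  )
  if (hyp == "gearPrey") {
    dat$gearPrey <- prep$gear * matrix(prep$preyStd, prep$N, prep$T, byrow = TRUE)
  } else if (hyp == "sevPrey") {
    for (s in 1:3)
      dat[[paste0("sevPrey", s)]] <-
        prep$sev[, , s] * matrix(prep$preyStd, prep$N, prep$T, byrow = TRUE)
  } else if (hyp == "injPrey") {
    for (s in 1:4)
      dat[[paste0("injPrey", s)]] <-
        prep$inj[, , s] * matrix(prep$preyStd, prep$N, prep$T, byrow = TRUE)
  } else if (hyp == "nPrior") {
    dat$nPriorEv <- prep$nPrior * (prep$sev[, , 1] + prep$sev[, , 2] + prep$sev[, , 3])
  } else if (hyp == "priorAny") {
    dat$anyPriorEv <- prep$anyPrior * (prep$sev[, , 1] + prep$sev[, , 2] + prep$sev[, , 3])
  } else if (hyp == "prior2yr") {
    dat$prior2yrEv <- prep$prior2yr * (prep$sev[, , 1] + prep$sev[, , 2] + prep$sev[, , 3])
  }
  hInit <- matrix(NA_real_, prep$N, prep$T)
  for (n in seq_len(prep$N)) hInit[n, prep$first[n]:prep$last[n]] <- 70
  monitors <- c("sigmaH", "deltaGear", "deltaSev", "betaPrey", "aS", "bS",
                switch(hyp, gearPrey = "gammaGearPrey",
                       sevPrey = "gammaSevPrey", injPrey = "gammaInjPrey",
                       nPrior = "gammaNPrior", priorAny = "gammaPriorAny",
                       prior2yr = "gammaPrior2yr", NULL),
                spec@monitors)
  list(model = .healthSurvivalModelString(hyp, nCat), data = dat,
       inits = list(h = hInit, sigmaH = 2, bS = 0.05),
       monitors = unique(monitors), spec = spec)
}

#' Growth model for length measurements
#'
#' Hierarchical von-Bertalanffy model: measurements are Normal around the
#' individual growth curve; individual asymptotes are Normal around the
#' population mean (optionally with a birth-year trend and the active length
#' hypothesis covariates), truncated above the length at age 0.
#'
#' @param dataset as in [prepareModelData()].
#' @param covariates optional matrix of asymptote covariates (one row per
#'   individual, standardized), for length-level hypotheses.
#' @param trend include a birth-year trend on the asymptote.
#' @return list `(model, data, inits, monitors)`.
#' @export
buildGrowthModel <- function(dataset, covariates = NULL, trend = FALSE) {
  frame <- dataset$frame
  len <- obsStream(dataset$observations, "lengths")
  ind <- dataset$individuals
  ind <- ind[!is.na(ind$birthYear), ]
  len <- len[len$id %in% ind$id, ]
  if (!nrow(len)) stop("no length measurements from individuals with known birth year")
  idx <- setNames(seq_len(nrow(ind)), ind$id)
  age <- stepYear(frame, len$t) - ind$birthYear[idx[len$id]] +
    (stepQuarter(frame, len$t) - 1) / 4
  keep <- age >= 0
  len <- len[keep, ]; age <- age[keep]
  nCov <- if (is.null(covariates)) 0L else ncol(covariates)
  covTerm <- if (nCov) "+ inprod(betaA[1:nCov], X[i, 1:nCov])" else ""
  trendTerm <- if (trend) "+ trendA * byc[i]" else ""
  model <- paste0("
model {
  for (m in 1:M) {
    Lhat[m] <- A[ind[m]] - (A[ind[m]] - L0) * exp(-k * age[m])
    P[m] ~ dnorm(Lhat[m], tauP)
  }
  for (i in 1:N) {
    Amu[i] <- A0 ", trendTerm, covTerm, "
    A[i] ~ dnorm(Amu[i], tauA) T(L0, )
  }
  A0 ~ dnorm(13, 0.04)
  k ~ dunif(0.01, 2)
  L0 ~ dunif(2, 8)
  sigmaA ~ dunif(0.01, 3)
  tauA <- pow(sigmaA, -2)
  sigmaP ~ dunif(0.01, 2)
  tauP <- pow(sigmaP, -2)
  ", if (trend) "trendA ~ dnorm(0, 1)" else "", "
  ", if (nCov) "for (j in 1:nCov) { betaA[j] ~ dnorm(0, 0.25) }" else "", "
}
")
  dat <- list(M = nrow(len), N = nrow(ind), ind = unname(idx[len$id]),
              age = age, P = len$length)
  if (trend) dat$byc <- ind$birthYear - 1980
  if (nCov) { dat$X <- covariates; dat$nCov <- nCov }
  monitors <- c("A0", "k", "L0", "sigmaA", "sigmaP",
                if (trend) "trendA", if (nCov) "betaA")
  list(model = model, data = dat,
       inits = list(A0 = 13, k = 0.3, L0 = 4, sigmaA = 0.5, sigmaP = 0.3),
       monitors = monitors)
}

# ---- MCMC -------------------------------------------------------------------

#' Run MCMC on a model
#'
#' Thin wrapper around the JAGS engine: compiles the model, adapts, burns in,
#' samples, and attaches split-chain convergence diagnostics (potential scale
#' reduction factor and effective sample size).  Runs are reproducible: each
#' chain's RNG is seeded deterministically from `seed`.
#'
#' @param model JAGS model string.
#' @param data data list.
#' @param monitors character vector of monitored parameters.
#' @param inits named list of initial values shared across chains, or a list
#'   of one such list per chain (RNG seeding is added per chain either way).
#' @param chains,iterations,warmup,thin MCMC controls.
#' @param seed integer seed.
#' @param quiet suppress progress output.
#' @return list `(samples, summary, diagnostics, converged)`: `samples` is a
#'   [coda::mcmc.list], `summary` a matrix of medians and 95% credible
#'   intervals, `diagnostics` a data.frame `(parameter, rhat, ess)` and
#'   `converged` the R-hat < 1.1 flag over all monitored parameters.
#' @export
runMCMC <- function(model, data, monitors, inits = list(), chains = 2L,
                    iterations = 1000L, warmup = 500L, thin = 1L, seed = 1L,
                    quiet = TRUE) {
  perChain <- length(inits) == chains && all(vapply(inits, is.list, TRUE)) &&
    chains > 1L
  initList <- lapply(seq_len(chains), function(ch) {
    base <- if (perChain) inits[[ch]] else inits
    c(base, list(.RNG.name = "base::Mersenne-Twister",
                 .RNG.seed = as.integer(seed + 1000L * ch)))
  })
  jm <- rjags::jags.model(textConnection(model), data = data,
                          inits = initList, n.chains = chains,
                          n.adapt = max(100L, warmup %/% 2L),
                          quiet = quiet)
  update(jm, n.iter = warmup, progress.bar = "none")
  samples <- rjags::coda.samples(jm, variable.names = monitors,
                                 n.iter = iterations, thin = thin,
                                 progress.bar = "none")
  mat <- as.matrix(samples)
  summ <- t(apply(mat, 2, quantile, probs = c(0.5, 0.025, 0.975)))
  colnames(summ) <- c("median", "lower95", "upper95")
  rhat <- rep(NA_real_, ncol(mat))
  if (chains > 1L) {
    gd <- try(coda::gelman.diag(samples, autoburnin = FALSE,
                                multivariate = FALSE), silent = TRUE)
    if (!inherits(gd, "try-error")) rhat <- gd$psrf[, 1]
  }
  ess <- coda::effectiveSize(samples)
  diagnostics <- data.frame(parameter = colnames(mat), rhat = rhat,
                            ess = as.numeric(ess[colnames(mat)]))
  converged <- all(is.na(rhat) | rhat < 1.1)
  list(samples = samples, summary = summ, diagnostics = diagnostics,
       converged = converged)
}

#' Fit the health–survival joint model to a dataset
#'
#' Convenience wrapper: [prepareModelData()] then [buildJointModel()] then
#' [runMCMC()].
#'
#' @param dataset as in [prepareModelData()].
#' @param spec a [modelSpec()].
#' @param obsPar observation constants.
#' @param ... passed to [runMCMC()].
#' @return a [runMCMC()] result with the prepared data attached.
#' @export
fitHealthSurvival <- function(dataset, spec = modelSpec(),
                              obsPar = observationParameters(), ...) {
  prep <- prepareModelData(dataset, spec)
  bm <- buildJointModel(prep, obsPar)
  fit <- runMCMC(bm$model, bm$data, bm$monitors, bm$inits, ...)
  fit$prep <- prep
  fit
}

#' Summarize combined-effect parameters the way results are reported
#'
#' One row per monitored parameter: posterior median, 95% credible interval,
#' sign of the median and whether the interval overlaps zero.  The sign
#' convention follows the health/length reporting: a positive effect is an
#' improvement in health status or a larger asymptote (or, for exposure
#' effects, greater exposure risk).
#'
#' @param fit a [runMCMC()] result (or a [coda::mcmc.list]).
#' @param parameters optional subset of parameter names.
#' @return data.frame `(parameter, median, lower95, upper95, sign,
#'   overlapsZero)`.
#' @export
summarizeInteractions <- function(fit, parameters = NULL) {
  mat <- if (is.list(fit) && !is.null(fit$samples)) as.matrix(fit$samples)
         else as.matrix(fit)
  if (!is.null(parameters)) {
    miss <- setdiff(parameters, colnames(mat))
    if (length(miss)) stop("unknown parameter(s): ", paste(miss, collapse = ", "))
    mat <- mat[, parameters, drop = FALSE]
  }
  q <- t(apply(mat, 2, quantile, probs = c(0.5, 0.025, 0.975)))
  data.frame(
    parameter = rownames(q),
    median = q[, 1], lower95 = q[, 2], upper95 = q[, 3],
    sign = ifelse(q[, 1] > 0, "+", ifelse(q[, 1] < 0, "-", "0")),
    overlapsZero = q[, 2] <= 0 & q[, 3] >= 0,
    row.names = NULL
  )
}
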