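#' Parameters of the synthetic-data generator
#'
#' Bundles every generating parameter of the forward simulation: the health,
#' growth, vital-rate and observation parameter sets, the exposure
#' coefficients, the true occupancy concentrations, and event-class
#' frequencies.  Defaults describe a desk-scale study system (3 regions, 30
#' years, ~60 individuals) with a post-2010 prey regime shift and a
#' northward redistribution of whales — the features of the real system the
#' simulator emulates.
#'
#' @param health a [healthParameters()] list.
#' @param growth a [growthParameters()] list.
#' @param vital a [vitalRateParameters()] list.
#' @param obs an [observationParameters()] list.
#' @param iota1,iota2,vTrend,refYear exposure coefficients (see
#'   [entanglementProbability()] and [regionalStrikeProbability()]).
#' @param sevProbs,injProbs categorical frequencies of event classes.
#' @param gearContinueProb per-step probability that an entangled whale keeps
#'   carrying gear another step.
#' @param occAlpha optional true Dirichlet concentration array
#'   `[class, quarter, era, region]`; `NULL` builds a default northward-shift
#'   pattern at simulation time.
#' @param initialHealthMean,initialHealthSD initial adult health distribution.
#' @param pVha probability a sighting yields a score per VHA variable.
#' @param pLength per-step probability of a photogrammetric measurement given
#'   a sighting.
#' @param pBirthYearKnown probability an individual's birth year is recorded.
#' @return a `simulationParameters` list.
#' @export
simulationParameters <- function(
    health = healthParameters(),
    growth = growthParameters(),
    vital = vitalRateParameters(),
    obs = observationParameters(nRegions = 3L),
    iota1 = 0.15, iota2 = 0.02, vTrend = 0.03, refYear = 2019L,
    sevProbs = c(minor = 0.5, moderate = 0.3, severe = 0.2),
    injProbs = c(superficial = 0.4, shallow = 0.3, deep = 0.2, blunt = 0.1),
    gearContinueProb = 0.75,
    occAlpha = NULL,
    initialHealthMean = 75, initialHealthSD = 8,
    pVha = 0.8, pLength = 0.1, pBirthYearKnown = 0.9) {
  p <- list(health = health, growth = growth, vital = vital, obs = obs,
            iota1 = iota1, iota2 = iota2, vTrend = vTrend, refYear = refYear,
            sevProbs = sevProbs, injProbs = injProbs,
            gearContinueProb = gearContinueProb, occAlpha = occAlpha,
            initialHealthMean = initialHealthMean,
            initialHealthSD = initialHealthSD,
            pVha = pVha, pLength = pLength,
            pBirthYearKnown = pBirthYearKnown)
  class(p) <- "simulationParameters"
  p
}

#' Desk-scale study frame for simulations
#'
#' Three regions on a south-to-north axis, 30 years, era break 2010.
#'
#' @param years year range.
#' @return a [StudyFrame].
#' @export
simFrame <- function(years = 1990:2019) {
  StudyFrame(regions = c("SOUTH", "CENT", "NORTH"), years = years,
             eraBreakYear = 2010L)
}

#' Generate synthetic stressor and density surfaces
#'
#' Seasonal region-by-step surfaces with the structural features of the study
#' system: entanglement risk elevated in northern regions; vessel traffic
#' with a configurable exponential temporal trend; a prey field with a
#' post-era-break regime shift and inter-annual noise; whale density with a
#' seasonal migration cycle that shifts north after the era break.  All
#' fields are strictly positive and the run is reproducible from `seed`.
#'
#' @param frame a [StudyFrame].
#' @param seed integer seed.
#' @param trafficTrend exponential trend per year in the traffic field.
#' @param preyRegimeShift fractional drop of mean prey after the era break
#'   (0 = no shift).
#' @param preyNoiseSD SD of the log-scale inter-annual prey noise.
#' @param entScalarStart backcast multiplier at the first year (ramps to 1 at
#'   the 2015 anchor).
#' @return a [RegionalSurfaces].
#' @export
generateSurfaces <- function(frame, seed, trafficTrend = 0.02,
                             preyRegimeShift = 0.35, preyNoiseSD = 0.15,
                             entScalarStart = 0.4) {
  set.seed(seed)
  R <- nRegions(frame); T <- nSteps(frame)
  yrs <- stepYear(frame, seq_len(T))
  qidx <- stepQuarter(frame, seq_len(T))
  northness <- (seq_len(R) - 1) / max(R - 1, 1)   # 0 = south, 1 = north

  season <- function(peakQ, width = 1) {
    sapply(1:4, function(q) exp(-((q - peakQ) %% 4 * (4 - (q - peakQ) %% 4)) /
                                  (4 * width)))
  }
  # entanglement risk: higher north, summer-peaked, mild noise
  gSeason <- 0.5 + 0.5 * season(3)
  G <- outer(0.2 + 0.8 * northness, gSeason[qidx]) *
    matrix(exp(rnorm(R * T, 0, 0.1)), R, T)

  # backcast scalar: deterministic ramp to 1 at 2015, 1 afterwards
  ramp <- pmin(1, entScalarStart + (1 - entScalarStart) *
                 (yrs - min(yrs)) / max(2015 - min(yrs), 1))
  entScalar <- matrix(rep(ramp, each = R), R, T)

  # vessel traffic: southern bias, exponential temporal trend
  AIS <- outer(0.3 + 0.7 * (1 - northness), exp(trafficTrend * (yrs - min(yrs)))) *
    matrix(exp(rnorm(R * T, 0, 0.05)), R, T)

  # prey: summer-peaked, richer north, regime shift after the era break with
  # shared inter-annual (year-level) noise so annual means vary
  yearNoise <- exp(rnorm(length(frameYears(frame)), 0, preyNoiseSD))
  names(yearNoise) <- frameYears(frame)
  regime <- ifelse(yrs >= eraBreakYear(frame), 1 - preyRegimeShift, 1)
  pSeason <- 0.3 + 1.7 * season(3)
  prey <- outer(1 + 1.5 * northness, pSeason[qidx] * regime *
                  yearNoise[as.character(yrs)]) *
    matrix(exp(rnorm(R * T, 0, 0.05)), R, T)

  # whale density: migrate north in summer; post-break extra northward mass
  DSM <- matrix(NA_real_, R, T)
  for (t in seq_len(T)) {
    pull <- (qidx[t] %in% c(3, 4)) * 0.6 + 0.2
    if (yrs[t] >= eraBreakYear(frame)) pull <- pull + 0.25
    w <- exp(2 * pull * northness)
    DSM[, t] <- w / sum(w)
  }
  RegionalSurfaces(frame, G = G, entScalar = entScalar, AIS = AIS,
                   prey = prey, DSM = DSM, fillPolicy = "synthetic")
}

.defaultOccAlpha <- function(frame) {
  R <- nRegions(frame)
  classes <- DEMOGRAPHIC_CLASSES
  alpha <- array(NA_real_, c(length(classes), 4L, 2L, R),
                 dimnames = list(classes, quarterLabels(frame),
                                 c("pre", "post"), regionLabels(frame)))
  northness <- (seq_len(R) - 1) / max(R - 1, 1)
  for (ci in seq_along(classes)) for (q in 1:4) for (ei in 1:2) {
    # whales sit south in winter, north in summer; post era pulls north
    pull <- c(-0.8, 0, 1.0, 0.4)[q] + (ei == 2) * 0.8
    w <- exp(pull * (2 * northness - 1))
    alpha[ci, q, ei, ] <- 6 * w / sum(w)   # concentration 6: moderate spread
  }
  alpha
}

.rcat <- function(p) sample(names(p), 1L, prob = p)

#' Forward-simulate a whale population
#'
#' Individuals are initialized with staggered ages, move according to the
#' true Dirichlet occupancy, acquire entanglement and strike events according
#' to the exposure equations, accumulate health effects through the latent
#' health random walk, grow toward individual asymptotes, die through the
#' health-dependent hazard, and calve through the health- and
#' length-dependent calving model.  Pedigree is tracked so mother-calf
#' covariates are computable.
#'
#' @param frame a [StudyFrame].
#' @param surfaces a [RegionalSurfaces] from [generateSurfaces()].
#' @param params a [simulationParameters()] list.
#' @param nInitial initial population size.
#' @param seed integer seed.
#' @return list with `individuals` (truth data.frame: id, sex, birthYear,
#'   motherId, deathStep), `trajectories` (list per id of data.frame
#'   `(t, h, L, age, gear, z...)`), `entanglements`, `strikes`, `calvings`
#'   (truth event tables), `annualPreyStd` (data.frame id, year, preyStd),
#'   `preyConstants`.
#' @export
generatePopulation <- function(frame, surfaces, params, nInitial = 60L, seed = 1L) {
  set.seed(seed)
  R <- nRegions(frame); T <- nSteps(frame)
  yrs0 <- frameYears(frame)
  G <- rescaleSurface(assay(surfaces, "G"))
  AIS <- rescaleSurface(assay(surfaces, "AIS"))
  eS <- assay(surfaces, "entScalar")
  preyM <- assay(surfaces, "prey")
  DSM <- assay(surfaces, "DSM")
  alpha <- if (is.null(params$occAlpha)) .defaultOccAlpha(frame) else params$occAlpha

  # population-level prey standardization constants from the density-weighted
  # regional mean (fixed before individuals are simulated)
  popPrey <- colSums(DSM * preyM) / colSums(DSM)
  ann <- tapply(popPrey, stepYear(frame, seq_len(T)), mean)
  preyConstants <- list(mean = mean(ann), sd = sd(ann))

  vital <- params$vital; health <- params$health; growth <- params$growth

  newId <- local({ counter <- 0L; function() {
    counter <<- counter + 1L; sprintf("W%03d", counter) } })

  makeWhale <- function(birthYear, sex, motherId = NA_character_,
                        motherCovs = numeric(0)) {
    covs <- setNames(rep(0, length(growth$betaA)), names(growth$betaA))
    known <- intersect(names(motherCovs), names(covs))
    covs[known] <- motherCovs[known]
    A <- drawAsymptote(growth, birthYear, covs)
    list(id = newId(), sex = sex, birthYear = birthYear, motherId = motherId,
         motherEnt = if ("motherEnt" %in% names(motherCovs))
           motherCovs[["motherEnt"]] else NA_real_,
         alive = TRUE, deathStep = NA_integer_,
         h = NA_real_, A = A, gearLeft = 0L, entSteps = integer(0),
         lastCalving = NA_integer_, traj = list())
  }

  pop <- vector("list", 0L)
  for (i in seq_len(nInitial)) {
    age0 <- sample(0:25, 1L)
    w <- makeWhale(birthYear = yrs0[1] - age0,
                   sex = sample(c("F", "M"), 1L))
    w$h <- min(max(rnorm(1, params$initialHealthMean, params$initialHealthSD),
                   health$floor + 1), health$ceiling)
    pop[[w$id]] <- w
  }

  ents <- list(); strikes <- list(); calvs <- list(); preyRows <- list()
  zYear <- list()  # per id: R x 4 matrix of this year's occupancy draws

  for (t in seq_len(T)) {
    y <- stepYear(frame, t); q <- stepQuarter(frame, t)
    era <- if (y >= eraBreakYear(frame)) 2L else 1L
    pr <- regionalStrikeProbability(AIS[, t], params$iota2, params$vTrend, y,
                                    params$refYear)
    if (q == 1L) {
      # draw the year's occupancy for everyone alive; calve available females
      zYear <- list()
      for (id in names(pop)) {
        w <- pop[[id]]
        if (!w$alive) next
        age <- y - w$birthYear
        cls <- demographicClass(w$sex, w$birthYear, y, vital$maturityAge)
        ci <- match(cls, DEMOGRAPHIC_CLASSES)
        zm <- sapply(1:4, function(qq) drop(rDirichlet(1L, alpha[ci, qq, era, ])))
        zYear[[id]] <- zm  # R x 4
        if (w$sex == "F" && !is.na(w$h)) {
          avail <- calvingAvailability(age, w$lastCalving, y, vital)
          hBar <- w$h  # health entering the year
          L <- expectedLength(age, w$A, growth$k, growth$L0)
          phi <- calvingProbability(hBar, L, avail, vital)
          if (avail) {
            calved <- rbinom(1, 1, phi)
            calvs[[length(calvs) + 1L]] <-
              data.frame(id = id, year = y, calved = calved)
            if (calved == 1L) {
              momEnt <- as.integer(w$gearLeft > 0L ||
                                     any((t - w$entSteps) <= 4L & w$entSteps < t))
              covs <- c(motherEnt = momEnt,
                        motherHealthStart = (w$h - 70) / 10)
              calf <- makeWhale(y, sample(c("F", "M"), 1L), motherId = id,
                                motherCovs = covs)
              calf$h <- min(max(w$h + rnorm(1, 0, 5), health$floor + 1),
                            health$ceiling)
              pop[[calf$id]] <- calf
              pop[[id]]$lastCalving <- y
              cim <- match("calf", DEMOGRAPHIC_CLASSES)
              zYear[[calf$id]] <-
                sapply(1:4, function(qq) drop(rDirichlet(1L, alpha[cim, qq, era, ])))
            }
          }
        }
      }
    }
    for (id in names(pop)) {
      w <- pop[[id]]
      if (!w$alive || w$birthYear > y) next
      if (is.null(zYear[[id]])) {  # born mid-frame bookkeeping safety
        cls <- demographicClass(w$sex, w$birthYear, y, vital$maturityAge)
        ci <- match(cls, DEMOGRAPHIC_CLASSES)
        zYear[[id]] <- sapply(1:4, function(qq)
          drop(rDirichlet(1L, alpha[ci, qq, era, ])))
      }
      z <- zYear[[id]][, q]
      age <- y - w$birthYear + (q - 1) / 4
      pEnt <- entanglementProbability(z, G[, t], eS[, t], params$iota1)
      pStr <- individualStrikeProbability(z, pr)
      preyW <- individualPreyIndex(z, preyM[, t])
      preyRows[[length(preyRows) + 1L]] <- list(id, t, y, preyW)

      # annual prey covariate: density-weighted population value for the year
      preyStd <- (ann[as.character(y)] - preyConstants$mean) / preyConstants$sd

      newEnt <- NULL
      if (rbinom(1, 1, pEnt) == 1L) {
        sev <- .rcat(params$sevProbs)
        dur <- 1L + rgeom(1, 1 - params$gearContinueProb)
        ents[[length(ents) + 1L]] <-
          data.frame(id = id, t = t, severity = sev, gearSteps = dur)
        newEnt <- sev
        w$gearLeft <- dur - 1L   # remaining steps after the event step
        w$entSteps <- c(w$entSteps, t)
      }
      carrying <- is.null(newEnt) && w$gearLeft > 0L
      strike <- NULL
      if (rbinom(1, 1, pStr) == 1L) {
        strike <- .rcat(params$injProbs)
        strikes[[length(strikes) + 1L]] <-
          data.frame(id = id, t = t, injury = strike)
      }
      covs <- list(
        transition = (y - w$birthYear == 1L) && q == 1L,
        lactating = w$sex == "F" && !is.na(w$lastCalving) && w$lastCalving == y,
        summer = quarterLabels(frame)[q] == "Jun-Aug"
      )
      evs <- list(newEntanglement = newEnt, carryingGear = carrying,
                  strike = strike,
                  history = eventHistoryFeatures(head(w$entSteps, -1L), t))
      if (!is.null(newEnt)) evs$history <- eventHistoryFeatures(
        w$entSteps[w$entSteps < t], t)
      w$h <- healthStep(w$h, covs, evs, preyStd, health,
                        noise = rnorm(1, 0, health$sigmaH))
      if (carrying || !is.null(newEnt)) {
        if (is.null(newEnt)) w$gearLeft <- w$gearLeft - 1L
      }
      L <- expectedLength(max(age, 0), w$A, growth$k, growth$L0)
      theta <- survivalProbability(w$h, vital)
      if (rbinom(1, 1, 1 - theta) == 1L) {
        w$alive <- FALSE
        w$deathStep <- t
      }
      w$traj[[length(w$traj) + 1L]] <-
        c(t = t, h = w$h, L = L, age = age,
          gear = as.integer(carrying || !is.null(newEnt)), preyStd = preyStd)
      pop[[id]] <- w
    }
  }

  individuals <- do.call(rbind, lapply(pop, function(w) data.frame(
    id = w$id, sex = w$sex, birthYear = w$birthYear,
    motherId = if (is.na(w$motherId)) NA_character_ else w$motherId,
    motherEnt = w$motherEnt, deathStep = w$deathStep, A = w$A)))
  rownames(individuals) <- NULL
  preyDf <- data.frame(
    id = vapply(preyRows, `[[`, "", 1L),
    t = vapply(preyRows, `[[`, 0L, 2L),
    year = vapply(preyRows, `[[`, 0L, 3L),
    preyW = vapply(preyRows, `[[`, 0, 4L))
  annualPreyStd <- data.frame(
    year = as.integer(names(ann)),
    preyStd = as.numeric((ann - preyConstants$mean) / preyConstants$sd))
  list(
    individuals = individuals,
    trajectories = lapply(pop, function(w) {
      if (!length(w$traj)) return(NULL)
      as.data.frame(do.call(rbind, w$traj))
    }),
    entanglements = if (length(ents)) do.call(rbind, ents) else
      ObservationSet()@entanglements,
    strikes = if (length(strikes)) do.call(rbind, strikes) else
      ObservationSet()@strikes,
    calvings = if (length(calvs)) do.call(rbind, calvs) else
      ObservationSet()@calvings,
    stepPrey = preyDf,
    annualPreyStd = annualPreyStd,
    preyConstants = preyConstants,
    occAlpha = alpha
  )
}

#' Mask simulated truth through the observation models
#'
#' Applies detection, ordinal scoring, photogrammetric noise, event
#' detection, and carcass recovery to a [generatePopulation()] result,
#' emitting the observed dataset in the same containers [readIndividuals()]
#' produces.  For sighted steps the sighting region is drawn from the
#' occupancy-weighted detection distribution.
#'
#' @param frame a [StudyFrame].
#' @param truth output of [generatePopulation()].
#' @param params a [simulationParameters()] list (its `obs` component drives
#'   the masking).
#' @param seed integer seed.
#' @return list `(individuals, observations)` where `individuals` carries
#'   `NA` death steps unless the carcass was recovered.
#' @export
generateObservations <- function(frame, truth, params, seed = 1L) {
  set.seed(seed)
  obsP <- params$obs
  regs <- regionLabels(frame)
  sight <- list(); vha <- list(); lens <- list(); deaths <- list()
  nVar <- length(obsP$cutpoints)
  for (i in seq_len(nrow(truth$individuals))) {
    id <- truth$individuals$id[i]
    tr <- truth$trajectories[[id]]
    if (is.null(tr) || !nrow(tr)) next
    for (r in seq_len(nrow(tr))) {
      t <- tr$t[r]
      q <- stepQuarter(frame, t)
      pdet <- obsP$pDetect[, q]
      # region assignment for a sighting uses the detection field itself:
      # true per-step z draws are not re-stored by the population simulator
      pSee <- mean(pdet)
      if (runif(1) < pSee) {
        reg <- sample(regs, 1L, prob = pdet / sum(pdet))
        sight[[length(sight) + 1L]] <- list(id, t, reg)
        for (v in seq_len(nVar)) {
          if (runif(1) < params$pVha) {
            pc <- vhaCategoryProbs(tr$h[r], v, obsP)
            vha[[length(vha) + 1L]] <-
              list(id, t, v, sample.int(length(pc), 1L, prob = pc))
          }
        }
        if (runif(1) < params$pLength) {
          plat <- sample(names(obsP$sigmaP), 1L)
          lens[[length(lens) + 1L]] <-
            list(id, t, rnorm(1, tr$L[r], obsP$sigmaP[[plat]]), plat)
        }
      }
    }
    ds <- truth$individuals$deathStep[i]
    if (!is.na(ds) && runif(1) < obsP$pRecover) {
      deaths[[length(deaths) + 1L]] <- data.frame(
        id = id, t = ds, causeKnown = runif(1) < 0.7, cause = "unknown")
    }
  }
  proto <- ObservationSet()
  col <- function(rows, j, proto) {
    v <- lapply(rows, `[[`, j)
    if (is.character(proto)) as.character(unlist(v))
    else if (is.integer(proto)) as.integer(unlist(v))
    else as.numeric(unlist(v))
  }
  entObs <- truth$entanglements
  if (nrow(entObs))
    entObs <- entObs[runif(nrow(entObs)) < obsP$pDetectEnt, , drop = FALSE]
  strObs <- truth$strikes
  if (nrow(strObs))
    strObs <- strObs[runif(nrow(strObs)) < obsP$pDetectStrike, , drop = FALSE]
  deathsDf <- if (length(deaths)) do.call(rbind, deaths) else proto@deaths
  recoveredIds <- deathsDf$id

  ind <- truth$individuals[, c("id", "sex", "birthYear")]
  ind$birthYear[runif(nrow(ind)) > params$pBirthYearKnown] <- NA_integer_
  ind$deathStep <- NA_integer_
  ind$deathStep[match(recoveredIds, ind$id)] <-
    deathsDf$t[match(recoveredIds, deathsDf$id)]

  sightDf <- if (length(sight)) data.frame(
    id = col(sight, 1, ""), t = col(sight, 2, 1L),
    region = col(sight, 3, "")) else proto@sightings
  obs <- ObservationSet(
    sightings = sightDf,
    vha = if (length(vha)) data.frame(
      id = col(vha, 1, ""), t = col(vha, 2, 1L),
      variable = col(vha, 3, 1L), score = col(vha, 4, 1L)) else proto@vha,
    lengths = if (length(lens)) data.frame(
      id = col(lens, 1, ""), t = col(lens, 2, 1L),
      length = col(lens, 3, 1.0), platform = col(lens, 4, "")) else proto@lengths,
    entanglements = entObs[, c("id", "t", "severity", "gearSteps")],
    strikes = strObs,
    calvings = truth$calvings,   # calvings of known mothers are well recorded
    deaths = deathsDf
  )
  rownames(ind) <- NULL
  list(individuals = ind, observations = obs)
}

#' Generate a complete synthetic dataset
#'
#' Runs [generateSurfaces()], [generatePopulation()] and
#' [generateObservations()] under one seed and returns truth and observed
#' data together.
#'
#' @param frame a [StudyFrame] (default [simFrame()]).
#' @param params a [simulationParameters()] list.
#' @param nInitial initial population size.
#' @param seed integer seed; sub-seeds for the three stages are derived from
#'   it.
#' @return list `(frame, surfaces, truth, individuals, observations, seed)`.
#' @export
simulateDataset <- function(frame = simFrame(),
                            params = simulationParameters(),
                            nInitial = 60L, seed = 1L) {
  surfaces <- generateSurfaces(frame, seed = seed)
  truth <- generatePopulation(frame, surfaces, params, nInitial = nInitial,
                              seed = seed + 1000L)
  masked <- generateObservations(frame, truth, params, seed = seed + 2000L)
  list(frame = frame, surfaces = surfaces, truth = truth,
       individuals = masked$individuals, observations = masked$observations,
       seed = seed)
}
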