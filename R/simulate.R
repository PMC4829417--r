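#' @importFrom stats rnorm runif rpois rlnorm plogis qlnorm pnorm rbinom dist
NULL

#' Define a simulation scenario with known ground truth
#'
#' Bundles every generative parameter of the synthetic study: two troops of
#' 46 and 48 individuals, 25 diffusion experiments per troop, 24 proximity
#' scans per individual per rule, a designated true transmission network and
#' a true bounded social-transmission parameter, ILV effects on acquisition,
#' and Poisson coefficients for the downstream count responses. The spatial
#' association model places each individual at a latent 2-D home position
#' (scatter `homeSd` metres) and jitters positions by `jitterSd` at every
#' sampling occasion; the 10 m radius, 5 m chain and 5 m nearest-neighbour
#' rules are applied to the same positions, so the three proximity networks
#' are correlated as in field data.
#'
#' @param seed integer seed; every generator stage derives its RNG state
#'   from it, so a scenario is bit-reproducible.
#' @param troopSizes named integer vector of troop sizes.
#' @param nDiffusionsPerTroop diffusion experiments per troop.
#' @param scansPerIndividualPerRule sampling occasions per proximity rule.
#' @param trueRule the network information actually spreads on.
#' @param sBoundedTrue true social transmission on the bounded [0,1) scale.
#' @param ilvBetasTrue named ILV effects on the (asocial) acquisition rate.
#' @param countBetasTrue list of named coefficient vectors (log-link) for
#'   the acquired / applied / exploited count responses.
#' @param homeSd,jitterSd spatial scatter parameters (metres).
#' @param groomTotal,domTotal expected interaction totals per troop.
#' @param nUnknownAcquirers expected number of unidentifiable acquirers
#'   injected across the whole study.
#' @param stopMedian,stopSdLog median and log-sd of the per-experiment
#'   informed-count truncation (patch depletion), clamped to [2, 27].
#' @return A list of class `"SimScenario"`.
#' @export
simScenario <- function(seed = 1L,
                        troopSizes = c(J = 46L, L = 48L),
                        nDiffusionsPerTroop = 25L,
                        scansPerIndividualPerRule = 24L,
                        trueRule = "ten_m",
                        sBoundedTrue = 0.9,
                        ilvBetasTrue = c(rank = 0.26, sex = 0.15,
                                         age = -0.01, boldness = 0),
                        countBetasTrue = list(
                          acquired  = c(intercept = 0.23,
                                        proximity_strength = 0.66),
                          applied   = c(intercept = -1.30,
                                        proximity_strength = 0.65,
                                        grooming_strength = 0.01, sex = 0.84),
                          exploited = c(intercept = -2.43,
                                        grooming_strength = 0.02, sex = 0.73,
                                        boldness = 0.01, rank = 1.39)),
                        homeSd = 10, jitterSd = 8,
                        groomTotal = 1384, domTotal = 737,
                        nUnknownAcquirers = 2,
                        stopMedian = 10, stopSdLog = 0.5) {
  stopifnot(sBoundedTrue >= 0, sBoundedTrue < 1,
            trueRule %in% networkRules())
  structure(list(seed = as.integer(seed), troopSizes = troopSizes,
                 nDiffusionsPerTroop = nDiffusionsPerTroop,
                 scansPerIndividualPerRule = scansPerIndividualPerRule,
                 trueRule = trueRule, sBoundedTrue = sBoundedTrue,
                 ilvBetasTrue = ilvBetasTrue, countBetasTrue = countBetasTrue,
                 homeSd = homeSd, jitterSd = jitterSd,
                 groomTotal = groomTotal, domTotal = domTotal,
                 nUnknownAcquirers = nUnknownAcquirers,
                 stopMedian = stopMedian, stopSdLog = stopSdLog),
            class = "SimScenario")
}

.stageSeed <- function(scenario, stage) {
  set.seed((scenario$seed %% 1000003L) * 1000L + stage)
}

## Reference age-sex composition (adult female / adult male / juvenile
## female / juvenile male) for the two troops; rescaled for other sizes.
.COMPOSITION <- list(J = c(af = 18, am = 8, jf = 6, jm = 14),
                     L = c(af = 19, am = 10, jf = 2, jm = 17))

#' Generate a synthetic study population
#'
#' Per troop: an age-sex composition matching the field demography, ages
#' uniform within class (juveniles 2-6 y, adults 6-25 y), absolute ranks a
#' uniform random permutation of 1..n, and boldness (seconds investigating
#' a novel food) lognormal and negatively age-correlated through a Gaussian
#' copula (rho = -0.3).
#'
#' @param scenario a [simScenario()].
#' @return Phenotype data.frame (see [readRecords()] `phenotypes` schema,
#'   plus `age_class`).
#' @export
genPopulation <- function(scenario) {
  .stageSeed(scenario, 1L)
  out <- list()
  for (tr in names(scenario$troopSizes)) {
    n <- scenario$troopSizes[[tr]]
    ref <- .COMPOSITION[[tr]] %||% .COMPOSITION[["J"]]
    cls <- sample(names(ref), n, replace = TRUE, prob = ref / sum(ref))
    # keep exact reference composition when the size matches the field troop
    if (n == sum(ref)) cls <- sample(rep(names(ref), ref))
    adult <- cls %in% c("af", "am")
    age <- ifelse(adult, runif(n, 6, 25), runif(n, 2, 6))
    zAge <- stats::qnorm(rank(age, ties.method = "random") / (n + 1))
    rho <- -0.3
    zB <- rho * zAge + sqrt(1 - rho^2) * rnorm(n)
    boldness <- round(qlnorm(pnorm(zB), meanlog = log(20), sdlog = 0.9), 1)
    out[[tr]] <- data.frame(
      individual_id = sprintf("%s%02d", tr, seq_len(n)),
      troop_id = tr,
      sex = ifelse(cls %in% c("af", "jf"), "female", "male"),
      age = round(age, 1),
      absolute_rank = sample(n),
      boldness = boldness,
      age_class = ifelse(adult, "adult", "juvenile"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

.homePositions <- function(scenario, phen) {
  lapply(split(phen$individual_id, phen$troop_id), function(ids)
    matrix(rnorm(2 * length(ids), 0, scenario$homeSd), ncol = 2,
           dimnames = list(ids, NULL)))
}

#' Generate proximity scans and interaction records
#'
#' Draws, for every sampling occasion, jittered positions around latent
#' home positions and records group memberships under the three proximity
#' rules (10 m radius around the focal; connected components of 5 m links;
#' nearest neighbour within 5 m). Grooming and dominance events are drawn
#' per directed dyad as Poisson counts proportional to spatial affinity
#' (dominance additionally down-weighted against rank), with expected
#' totals of the observed field magnitude.
#'
#' @param scenario a [simScenario()].
#' @param population phenotype table from [genPopulation()].
#' @return List with `scans`, `interactions` (record data.frames) and the
#'   generative truth: `affinity` (per troop, `exp(-homeDistance/10)`) and
#'   `homes`.
#' @export
genScansAndInteractions <- function(scenario, population) {
  .stageSeed(scenario, 2L)
  homes <- .homePositions(scenario, population)
  scanRows <- list(); intRows <- list()
  rules <- c(ten_m = 10, five_m_chain = 5, nearest_neighbour = 5)
  affinity <- list()
  for (tr in names(homes)) {
    H <- homes[[tr]]; ids <- rownames(H); n <- length(ids)
    dh <- as.matrix(dist(H))
    affinity[[tr]] <- exp(-dh / 10); diag(affinity[[tr]]) <- 0
    for (ri in seq_along(rules)) {
      rule <- names(rules)[ri]; radius <- rules[[ri]]
      for (t in seq_len(scenario$scansPerIndividualPerRule)) {
        P <- H + matrix(rnorm(2 * n, 0, scenario$jitterSd), ncol = 2)
        D <- as.matrix(dist(P))
        ts <- (ri - 1L) * 1000L + t
        assoc <- switch(rule,
          ten_m = lapply(seq_len(n), function(i)
            ids[D[i, ] <= radius & seq_len(n) != i]),
          five_m_chain = {
            g <- igraph::graph_from_adjacency_matrix(D <= radius,
                                                     mode = "undirected",
                                                     diag = FALSE)
            comp <- igraph::components(g)$membership
            lapply(seq_len(n), function(i)
              ids[comp == comp[i] & seq_len(n) != i])
          },
          nearest_neighbour = lapply(seq_len(n), function(i) {
            d <- D[i, ]; d[i] <- Inf
            j <- which.min(d)
            if (d[j] <= radius) ids[j] else character(0)
          }))
        scanRows[[length(scanRows) + 1L]] <- data.frame(
          scan_id = sprintf("%s_%s_%03d_%s", tr, rule, t, ids),
          troop_id = tr, timestamp = ts, rule = rule, focal_id = ids,
          associates = vapply(assoc, paste, character(1), collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
    for (ty in c("groom", "dominance")) {
      a <- affinity[[tr]]
      if (ty == "dominance") {
        rr <- relativeRank(population$absolute_rank[population$troop_id == tr], n)
        names(rr) <- population$individual_id[population$troop_id == tr]
        rr <- rr[ids]
        a <- a * ifelse(outer(rr, rr, ">"), 1, 0.15)
      }
      total <- if (ty == "groom") scenario$groomTotal else scenario$domTotal
      lam <- total * a / sum(a)
      cnt <- matrix(rpois(n * n, lam), n, dimnames = list(ids, ids))
      idx <- which(cnt > 0, arr.ind = TRUE)
      if (nrow(idx)) {
        from <- rep(ids[idx[, 1]], cnt[idx])
        to <- rep(ids[idx[, 2]], cnt[idx])
        intRows[[length(intRows) + 1L]] <- data.frame(
          event_id = sprintf("%s_%s_%05d", tr, ty, seq_along(from)),
          troop_id = tr, timestamp = seq_along(from), type = ty,
          actor_id = from, recipient_id = to, stringsAsFactors = FALSE)
      }
    }
  }
  list(scans = do.call(rbind, c(scanRows, list(make.row.names = FALSE))),
       interactions = do.call(rbind, c(intRows, list(make.row.names = FALSE))),
       affinity = affinity, homes = homes)
}

#' Simulate one information-diffusion experiment
#'
#' Generative use of the acquisition-rate model itself: a discoverer is
#' sampled with probability increasing in dominance rank and maleness and
#' decreasing in age; thereafter the next acquirer among the naive troop
#' members is drawn with probability proportional to their modelled rate on
#' the true network under the scenario's (s, ILV betas). The diffusion is
#' truncated at a random informed count (lognormal, median `stopMedian`,
#' clamped to [2, 27]) standing in for patch depletion. Patch entries and
#' feeding/co-feeding/protest flags are then drawn with rank- and
#' sex-dependent probabilities (dominants enter first).
#'
#' Uses the current RNG state; seed the stream yourself or use
#' [simulateExperiments()].
#'
#' @param scenario a [simScenario()].
#' @param population phenotype table.
#' @param network the true [AssociationMatrix-class] for this troop.
#' @param task experiment identifier.
#' @param form acquisition-rate form used generatively.
#' @return A [DiffusionLog-class].
#' @export
simulateDiffusion <- function(scenario, population, network, task = "t1",
                              form = "multiplicative") {
  tr <- network@troop
  phen <- population[population$troop_id == tr, , drop = FALSE]
  ids <- network@ids
  X <- .ilvMatrix(phen)[ids, , drop = FALSE]
  rr <- X[, "rank"]; male <- X[, "sex"]; age <- X[, "age"]
  n <- length(ids)
  s <- scenario$sBoundedTrue / (1 - scenario$sBoundedTrue)
  b <- scenario$ilvBetasTrue
  expG <- exp(as.numeric(X[, names(b), drop = FALSE] %*% b))
  wDisc <- exp(0.8 * rr + 0.6 * male - 0.06 * age)
  disc <- sample(n, 1, prob = wDisc)
  pos <- sample(c("leading_edge", "side", "middle_back"), 1,
                prob = c(0.56, 0.22, 0.22))
  nStop <- max(2, min(27, n, round(rlnorm(1, log(scenario$stopMedian),
                                          scenario$stopSdLog))))
  Wor <- network@weights
  naive <- setdiff(seq_len(n), disc)
  Tt <- Wor[, disc]
  order_ <- integer(0)
  while (length(order_) + 1L < nStop && length(naive)) {
    R <- .rates(form, s, Tt[naive], expG[naive])
    if (sum(R) <= 0) break
    j <- naive[sample.int(length(naive), 1, prob = R)]
    order_ <- c(order_, j)
    Tt <- Tt + Wor[, j]
    naive <- setdiff(naive, j)
  }
  informed <- order_
  pApply <- plogis(-0.2 + 0.8 * rr[informed] + 0.5 * male[informed])
  applies <- informed[runif(length(informed)) < pApply]
  applies <- applies[order(-rr[applies])]  # dominants queue-jump
  fed <- runif(length(applies)) < plogis(-0.8 + 1.5 * rr[applies] +
                                           0.4 * male[applies])
  if (length(fed)) fed[1] <- TRUE
  cofeed <- fed & c(FALSE, runif(max(0, length(applies) - 1)) < 0.05)
  protest <- cofeed & runif(length(applies)) < 0.3
  diffusionLog(task = task, troop = tr, discoverer = ids[disc],
               acquisitions = as.list(ids[order_]),
               applications = data.frame(individual_id = ids[applies],
                                         fed = fed, cofeed = cofeed,
                                         protest = protest),
               discoveryPosition = pos)
}

#' Simulate the full set of diffusion experiments
#'
#' Runs [simulateDiffusion()] `nDiffusionsPerTroop` times per troop on the
#' scenario's true network and injects the scenario's expected number of
#' unidentifiable (`UNKNOWN`) acquirers at random, mirroring the occasional
#' field failure to identify an acquirer.
#'
#' @param scenario a [simScenario()].
#' @param population phenotype table.
#' @param networks list `troop -> rule -> AssociationMatrix`.
#' @return List of [DiffusionLog-class], length `2 * nDiffusionsPerTroop`.
#' @export
simulateExperiments <- function(scenario, population, networks) {
  .stageSeed(scenario, 3L)
  logs <- list()
  for (tr in names(networks)) {
    net <- networks[[tr]][[scenario$trueRule]]
    for (i in seq_len(scenario$nDiffusionsPerTroop))
      logs[[length(logs) + 1L]] <- simulateDiffusion(
        scenario, population, net, task = sprintf("%s_%02d", tr, i))
  }
  nTot <- length(logs)
  pUnk <- scenario$nUnknownAcquirers / max(1, nTot)
  for (i in seq_along(logs)) {
    lg <- logs[[i]]
    if (length(lg@acquisitions) && runif(1) < pUnk) {
      j <- sample(length(lg@acquisitions), 1)
      victim <- lg@acquisitions[[j]][1]
      lg@acquisitions[[j]][1] <- UNKNOWN_ID
      app <- lg@applications
      lg@applications <- app[app$individual_id != victim, , drop = FALSE]
      logs[[i]] <- lg
    }
  }
  logs
}

#' Generate Poisson count responses with known coefficients
#'
#' Draws per-individual acquired / applied / exploited counts from log-link
#' Poisson models with the scenario's true coefficients over the six
#' phenotypic predictors, emulating exposure to 25 trials per troop.
#'
#' @param population phenotype table.
#' @param predictors data.frame from [constraintPredictors()].
#' @param countBetasTrue list of named coefficient vectors (a subset of
#'   `intercept` plus predictor names), as in [simScenario()].
#' @return data.frame in the [tallyCounts()] layout (with `n_discovered`
#'   zero).
#' @export
genCountResponses <- function(population, predictors, countBetasTrue) {
  df <- predictors
  out <- data.frame(individual_id = df$individual_id,
                    stringsAsFactors = FALSE)
  for (resp in c("acquired", "applied", "exploited")) {
    b <- countBetasTrue[[resp]]
    eta <- rep(b[["intercept"]], nrow(df))
    for (nm in setdiff(names(b), "intercept")) eta <- eta + b[[nm]] * df[[nm]]
    out[[paste0("n_", resp)]] <- rpois(nrow(df), exp(eta))
  }
  out$n_discovered <- 0L
  out
}

#' Run the whole generative study
#'
#' Convenience wrapper: population, scans and interactions, the eight
#' networks per troop, the 50 diffusion experiments on the true network,
#' and the per-individual tallies — everything the analysis pipeline
#' consumes, plus the generative truth.
#'
#' @param scenario a [simScenario()].
#' @return List with `population`, `scans`, `interactions`, `networks`
#'   (troop -> rule -> matrix), `logs`, `counts`, `predictors`, `affinity`
#'   and the `scenario` itself.
#' @export
simulateStudy <- function(scenario) {
  pop <- genPopulation(scenario)
  rec <- genScansAndInteractions(scenario, pop)
  troops <- unique(pop$troop_id)
  networks <- lapply(setNames(troops, troops), function(tr)
    buildNetworks(rec$scans[rec$scans$troop_id == tr, ],
                  rec$interactions[rec$interactions$troop_id == tr, ],
                  ids = pop$individual_id[pop$troop_id == tr]))
  logs <- simulateExperiments(scenario, pop, networks)
  counts <- suppressWarnings(
    tallyCounts(logs, ids = pop$individual_id))
  preds <- constraintPredictors(pop, networks)
  list(population = pop, scans = rec$scans, interactions = rec$interactions,
       networks = networks, logs = logs, counts = counts,
       predictors = preds, affinity = rec$affinity, scenario = scenario)
}
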