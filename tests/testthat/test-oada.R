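mkNet <- function(w, troop = "J") toyNetwork(w, troop = troop)

test_that("the transmission term sums connections to informed individuals", {
  w <- matrix(0, 4, 4,
              dimnames = list(paste0("J", 1:4), paste0("J", 1:4)))
  w["J1", "J2"] <- w["J2", "J1"] <- 0.5
  w["J1", "J3"] <- w["J3", "J1"] <- 0.25
  m <- mkNet(w)
  expect_equal(transmissionTerm("J1", c("J2", "J3"), m), 0.75)
  expect_equal(transmissionTerm("J4", c("J2", "J3"), m), 0)

  full <- matrix(1, 5, 5); diag(full) <- 0
  dimnames(full) <- list(paste0("J", 1:5), paste0("J", 1:5))
  expect_equal(transmissionTerm("J1", paste0("J", 2:5), mkNet(full)), 4)

  wd <- matrix(0, 2, 2, dimnames = list(c("J1", "J2"), c("J1", "J2")))
  wd["J1", "J2"] <- 3
  md <- toyNetwork(wd, rule = "groom_directed")
  expect_equal(transmissionTerm("J1", "J2", md, "outgoing"), 3)
  expect_equal(transmissionTerm("J1", "J2", md, "incoming"), 0)
})

test_that("event rates follow the additive and multiplicative forms", {
  phen <- toyPhenotypes(3, seed = 5)
  w <- matrix(0.5, 3, 3); diag(w) <- 0
  dimnames(w) <- list(phen$individual_id, phen$individual_id)
  m <- mkNet(w)
  addSpec <- oadaSpec("ten_m", "additive")
  # s = 0, no ILVs: reduces to the asocial baseline of 1
  expect_equal(eventRate("J1", "J2", m, addSpec, phen, s = 0), 1)
  # additive, s = 2, T = 0.5 -> 2*0.5 + 1 = 2
  expect_equal(eventRate("J1", "J2", m, addSpec, phen, s = 2), 2)
  # multiplicative == additive whenever there are no ILVs
  mulSpec <- oadaSpec("ten_m", "multiplicative")
  for (s in c(0, 0.3, 2, 10))
    expect_equal(eventRate("J1", c("J2", "J3"), m, mulSpec, phen, s = s),
                 eventRate("J1", c("J2", "J3"), m, addSpec, phen, s = s))
  # a missing ILV coefficient is a named error
  rSpec <- oadaSpec("ten_m", "additive", ilvs = "rank")
  expect_error(eventRate("J1", "J2", m, rSpec, phen, s = 1), "rank")
})

test_that("the asocial no-ILV order probability is uniform over orders", {
  phen <- toyPhenotypes(4)
  spec <- oadaSpec("none")
  lg <- diffusionLog("t", "J", "J4", list("J2", "J1", "J3"))
  ll <- diffusionLoglik(lg, NULL, spec, phen)
  expect_equal(ll, log(1 / 6))
})

test_that("order probabilities sum to one over all complete orders", {
  set.seed(77)
  for (rep in 1:6) {
    n <- sample(3:5, 1)
    phen <- toyPhenotypes(n)
    w <- randomUndirectedWeights(n, density = 0.8)
    m <- mkNet(w)
    form <- sample(c("additive", "multiplicative"), 1)
    ilvs <- if (runif(1) < 0.5) c("rank", "sex") else character()
    spec <- oadaSpec("ten_m", form, ilvs)
    betas <- setNames(runif(length(ilvs), -0.5, 0.5), ilvs)
    s <- runif(1, 0, 4)
    disc <- sample(phen$individual_id, 1)
    expect_equal(orderProbabilityMass(m, spec, phen, s, betas, disc), 1,
                 tolerance = 1e-10)
  }
  # asocial variant
  phen <- toyPhenotypes(4)
  spec <- oadaSpec("none", ilvs = "age")
  expect_equal(orderProbabilityMass(NULL, spec, phen, 0,
                                    c(age = 0.1), "J2"), 1,
               tolerance = 1e-10)
})

test_that("breslow and exact tie handling coincide without ties and the exact method averages orderings", {
  phen <- toyPhenotypes(5, seed = 3)
  w <- randomUndirectedWeights(5, troop = "J")
  m <- mkNet(w)
  lg <- diffusionLog("t", "J", "J1", list("J3", "J2", "J5"))
  for (form in c("additive", "multiplicative")) {
    sB <- oadaSpec("ten_m", form, "rank")
    sE <- oadaSpec("ten_m", form, "rank", tieMethod = "exact")
    expect_equal(diffusionLoglik(lg, m, sB, phen, 1.5, c(rank = 0.3)),
                 diffusionLoglik(lg, m, sE, phen, 1.5, c(rank = 0.3)))
  }
  # tied pair: exact equals the hand-averaged two-order probability
  tie <- diffusionLog("t", "J", "J1", list(c("J2", "J3")))
  spec <- oadaSpec("ten_m", "additive", tieMethod = "exact")
  s <- 2
  pOrder <- function(first, second) {
    r1 <- vapply(c("J2", "J3", "J4", "J5"), function(i)
      eventRate(i, "J1", m, spec, phen, s), numeric(1))
    p1 <- r1[[first]] / sum(r1)
    rest <- setdiff(c("J2", "J3", "J4", "J5"), first)
    r2 <- vapply(rest, function(i)
      eventRate(i, c("J1", first), m, spec, phen, s), numeric(1))
    p1 * r2[[second]] / sum(r2)
  }
  expect_equal(diffusionLoglik(tie, m, spec, phen, s),
               log(mean(c(pOrder("J2", "J3"), pOrder("J3", "J2")))))
})

test_that("social models nest the asocial model at s = 0", {
  phen <- toyPhenotypes(5, seed = 13)
  m <- mkNet(randomUndirectedWeights(5))
  lg <- diffusionLog("t", "J", "J2", list("J4", "J1", "J5", "J3"))
  asoc <- diffusionLoglik(lg, NULL, oadaSpec("none", ilvs = "rank"), phen,
                          betas = c(rank = 0.4))
  for (form in c("additive", "multiplicative"))
    expect_identical(
      diffusionLoglik(lg, m, oadaSpec("ten_m", form, "rank"), phen, s = 0,
                      betas = c(rank = 0.4)),
      asoc)
  # additive and multiplicative are identical whenever no ILVs enter
  for (s in c(0.2, 1, 7))
    expect_equal(
      diffusionLoglik(lg, m, oadaSpec("ten_m", "additive"), phen, s = s),
      diffusionLoglik(lg, m, oadaSpec("ten_m", "multiplicative"), phen,
                      s = s))
})

test_that("the pooled fitter reproduces the per-diffusion likelihood", {
  sc <- smallScenario(seed = 8)
  st <- suppressWarnings(simulateStudy(sc))
  spec <- oadaSpec("ten_m", "multiplicative", c("rank", "sex"))
  fit <- suppressWarnings(fitOada(st$logs, st$networks, spec,
                                  st$population))
  byHand <- sum(vapply(st$logs, function(lg)
    suppressWarnings(diffusionLoglik(
      lg, st$networks[[lg@troop]]$ten_m, spec, st$population,
      s = fit@sUnbounded, betas = fit@betas)), numeric(1)))
  expect_equal(fit@loglik, byHand, tolerance = 1e-8)
})

test_that("fitting asocially generated data drives s to the boundary", {
  sc <- smallScenario(seed = 21, sBoundedTrue = 0,
                      ilvBetasTrue = c(rank = 0, sex = 0, age = 0,
                                       boldness = 0))
  st <- suppressWarnings(simulateStudy(sc))
  fit <- suppressWarnings(fitOada(st$logs, st$networks, oadaSpec("ten_m"),
                                  st$population))
  asoc <- suppressWarnings(fitOada(st$logs, NULL, oadaSpec("none"),
                                   st$population))
  expect_lt(fit@sBounded, 0.15)
  # nesting: the social model can only match or improve the asocial
  # likelihood, and without a transmission signal the gain stays negligible
  expect_gte(fit@loglik + 1e-8, asoc@loglik)
  expect_lt(fit@loglik - asoc@loglik, 2)
  # evaluated at the s = 0 boundary the social model IS the asocial model
  atZero <- sum(vapply(st$logs, function(lg)
    suppressWarnings(diffusionLoglik(lg, st$networks[[lg@troop]]$ten_m,
                                     oadaSpec("ten_m"), st$population,
                                     s = 0)), numeric(1)))
  expect_equal(atZero, asoc@loglik, tolerance = 1e-10)
  expect_true(fit@converged)
})

test_that("the AICc identity and the s parameterization hold for every fit", {
  sc <- smallScenario(seed = 5)
  st <- suppressWarnings(simulateStudy(sc))
  tab <- suppressWarnings(compareNetworks(
    st$logs, st$networks, st$population, rules = c("ten_m", "dom_directed"),
    forms = "additive", ilvs = "rank"))
  fits <- attr(tab, "fits")
  for (f in fits) {
    expect_equal(f@aicc,
                 -2 * f@loglik + 2 * f@k +
                   2 * f@k * (f@k + 1) / (f@nEvents - f@k - 1))
    expect_equal(f@sBounded, f@sUnbounded / (1 + f@sUnbounded))
  }
  # the bounded scale is a monotone bijection of the unbounded scale
  s <- c(0, 0.01, 0.5, 1, 10, 1e4)
  expect_true(all(diff(s / (1 + s)) > 0))
})

test_that("model tables rank by AICc with weights summing to one", {
  sc <- smallScenario(seed = 5)
  st <- suppressWarnings(simulateStudy(sc))
  tab <- suppressWarnings(compareNetworks(
    st$logs, st$networks, st$population,
    rules = c("ten_m", "five_m_chain", "groom_directed"),
    forms = "additive", ilvs = character()))
  expect_equal(nrow(tab), 4L)  # 3 networks + asocial
  expect_equal(min(tab$delta_aicc), 0)
  expect_equal(sum(tab$delta_aicc == 0), 1L)
  expect_equal(sum(tab$akaike_weight), 1)
  expect_true(all(diff(tab$aicc) >= 0))

  # duplicate candidate matrices yield identical rows
  nets <- st$networks
  for (tr in names(nets)) {
    dup <- nets[[tr]]$ten_m
    dup@rule <- "five_m_chain"
    nets[[tr]]$five_m_chain <- dup
  }
  tab2 <- suppressWarnings(compareNetworks(
    st$logs, nets, st$population, rules = c("ten_m", "five_m_chain"),
    forms = "additive", ilvs = character()))
  expect_equal(tab2$loglik[tab2$network == "ten_m"],
               tab2$loglik[tab2$network == "five_m_chain"])
})

test_that("richer ILV subsets never lose likelihood within a form", {
  sc <- smallScenario(seed = 9, nDiff = 6, sBoundedTrue = 0.6)
  st <- suppressWarnings(simulateStudy(sc))
  subsets <- list(character(0), "rank", "sex", c("rank", "sex"))
  tab <- suppressWarnings(ilvSubsetSearch(
    st$logs, st$networks, st$population, rule = "ten_m",
    forms = "additive", candidates = subsets))
  ll <- setNames(tab$loglik, tab$ilvs)
  ll0 <- tab$loglik[tab$ilvs == ""]
  expect_gte(ll[["rank"]] + 1e-6, ll0)
  expect_gte(ll[["sex"]] + 1e-6, ll0)
  expect_gte(ll[["rank+sex"]] + 1e-6, max(ll[["rank"]], ll[["sex"]]))
  expect_equal(sum(tab$akaike_weight), 1)
})

test_that("model averaging renormalises weights and substitutes zero betas", {
  mkFit <- function(ll, ilvs, betas, k) {
    new("OADAFit", spec = oadaSpec("ten_m", "additive", ilvs),
        sUnbounded = 1, sBounded = 0.5,
        betas = setNames(betas, ilvs), loglik = ll, k = k,
        nEvents = 100L, aicc = -2 * ll + 2 * k + 2 * k * (k + 1) / (100 - k - 1),
        converged = TRUE)
  }
  f1 <- mkFit(-50, "rank", 0.4, 2L)
  single <- SocialDiffusion:::.modelSet(list(f1), "only")
  avg <- modelAverage(single)
  expect_equal(avg[["rank"]], 0.4)
  expect_equal(avg[["sex"]], 0)

  # two retained models with equal AICc: beta 0.4 averages to 0.2 when the
  # other model omits the ILV
  f2 <- mkFit(f1@loglik, character(0), numeric(0), 2L)
  f2@aicc <- f1@aicc
  both <- SocialDiffusion:::.modelSet(list(f1, f2), c("with", "without"))
  avg <- modelAverage(both, threshold = 2)
  expect_equal(avg[["rank"]], 0.2)
  expect_equal(sum(attr(avg, "weights")), 1)
})
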