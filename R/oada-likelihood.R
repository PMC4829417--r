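#' @importFrom stats setNames
NULL

#' Social-transmission term for a naive individual
#'
#' The network exposure of naive individual `i`: the sum of its connections
#' to all currently informed individuals. On a directed network the default
#' convention sums i's outgoing edges toward informed individuals (i attends
#' to those it directs associations at); `direction = "incoming"` uses the
#' edges informed individuals direct at i.
#'
#' @param i naive individual id.
#' @param informed character vector of informed ids.
#' @param m an [AssociationMatrix-class].
#' @param direction `"outgoing"` or `"incoming"` (directed networks only).
#' @return Nonnegative scalar exposure.
#' @export
transmissionTerm <- function(i, informed, m, direction = "outgoing") {
  if (i %in% informed) stop("individual ", i, " is already informed")
  informed <- intersect(informed, m@ids)
  if (!length(informed)) return(0)
  w <- m@weights
  if (m@directed && direction == "incoming") sum(w[informed, i])
  else sum(w[i, informed])
}

## ILV design matrix over phenotype rows: rank is the relative dominance
## rank within troop, sex is coded female = 0 / male = 1, age in years,
## boldness in seconds (all unstandardized).
.ilvMatrix <- function(phenotypes, ilvs = ilvNames()) {
  n <- stats::ave(phenotypes$absolute_rank, phenotypes$troop_id,
                  FUN = length)
  X <- cbind(rank = relativeRank(phenotypes$absolute_rank, n),
             sex = as.numeric(phenotypes$sex == "male"),
             age = phenotypes$age,
             boldness = phenotypes$boldness)
  rownames(X) <- phenotypes$individual_id
  X[, ilvs, drop = FALSE]
}

.rates <- function(form, s, Tt, expG) {
  switch(form,
         additive = s * Tt + expG,
         multiplicative = expG * (s * Tt + 1),
         asocial = expG + 0 * Tt)
}

#' Acquisition rate of a naive individual
#'
#' The modelled relative rate at which a naive individual acquires the
#' information. With linear predictor `G = sum_m beta_m x_im` over the ILVs:
#' additive form `s*T + exp(G)`, multiplicative form `exp(G) * (s*T + 1)`,
#' asocial form `exp(G)`, where `T` is the [transmissionTerm()].
#'
#' @inheritParams transmissionTerm
#' @param spec an [OADASpec-class].
#' @param phenotypes phenotype table containing `i`.
#' @param s social transmission parameter on the unbounded scale.
#' @param betas named ILV coefficients (missing ILVs are an error).
#' @return Positive scalar rate.
#' @export
eventRate <- function(i, informed, m, spec, phenotypes, s = 0,
                      betas = numeric()) {
  X <- .ilvMatrix(phenotypes, spec@ilvs)
  if (!i %in% rownames(X)) stop("no phenotype row for individual ", i)
  if (length(spec@ilvs)) {
    if (!all(spec@ilvs %in% names(betas)))
      stop("missing coefficient for ILV '",
           paste(setdiff(spec@ilvs, names(betas)), collapse = "', '"),
           "' (individual ", i, ")")
    G <- sum(X[i, spec@ilvs] * betas[spec@ilvs])
  } else G <- 0
  Tt <- if (spec@form == "asocial") 0
        else transmissionTerm(i, informed, m, spec@direction)
  as.numeric(.rates(spec@form, s, Tt, exp(G)))
}

## Precompute the per-diffusion structures the likelihood loops over:
## the transmission-oriented weight matrix (column j added to the exposure
## vector when j becomes informed), discoverer index, integer tie groups.
.prepDiffusion <- function(log, m, spec, ids) {
  groups <- lapply(log@acquisitions, function(g) g[g != UNKNOWN_ID])
  nUnknown <- sum(lengths(log@acquisitions)) - sum(lengths(groups))
  if (nUnknown > 0)
    warning(sprintf("%d unidentified acquirer(s) dropped from likelihood of task %s",
                    nUnknown, log@task), call. = FALSE)
  groups <- groups[lengths(groups) > 0]
  bad <- setdiff(c(log@discoverer, unlist(groups)), ids)
  if (length(bad))
    stop("diffusion ", log@task, " references id(s) outside the troop roster: ",
         paste(bad, collapse = ", "))
  Wor <- NULL
  if (!is.null(m)) {
    w <- m@weights[ids, ids]
    Wor <- if (m@directed && spec@direction == "incoming") t(w) else w
  }
  prep <- list(task = log@task, n = length(ids),
               disc = match(log@discoverer, ids),
               groups = lapply(groups, function(g) match(g, ids)),
       Wor = Wor)
  c(prep, .flattenPrep(prep))
}

## Risk sets and network exposures at each event depend only on the observed
## order, never on the parameters: flatten them once so a likelihood
## evaluation is a single vectorized expression (valid for the Breslow tie
## method; the exact method iterates the sequential form instead).
.flattenPrep <- function(prep) {
  n <- prep$n
  naive <- rep(TRUE, n); naive[prep$disc] <- FALSE
  Tt <- if (is.null(prep$Wor)) numeric(n) else prep$Wor[, prep$disc]
  flatIdx <- integer(0); flatT <- numeric(0); flatEvent <- integer(0)
  numSel <- logical(0); gs <- integer(0)
  for (k in seq_along(prep$groups)) {
    G <- prep$groups[[k]]
    nv <- which(naive)
    if (!length(nv))
      stop("empty risk set with acquisition events remaining (task ",
           prep$task, ")", call. = FALSE)
    flatIdx <- c(flatIdx, nv)
    flatT <- c(flatT, Tt[nv])
    flatEvent <- c(flatEvent, rep.int(k, length(nv)))
    numSel <- c(numSel, nv %in% G)
    gs <- c(gs, length(G))
    if (!is.null(prep$Wor))
      Tt <- Tt + rowSums(prep$Wor[, G, drop = FALSE])
    naive[G] <- FALSE
  }
  list(flatIdx = flatIdx, flatT = flatT, flatEvent = flatEvent,
       numSel = numSel, groupSizes = gs,
       maxTie = if (length(gs)) max(gs) else 0L)
}

.oadaLoglikFast <- function(prep, form, s, expG) {
  R <- .rates(form, s, prep$flatT, expG[prep$flatIdx])
  denom <- rowsum(R, prep$flatEvent)
  sum(log(R[prep$numSel])) - sum(prep$groupSizes * log(denom))
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (k in seq_along(v))
    out <- c(out, lapply(.permutations(v[-k]), function(p) c(v[k], p)))
  out
}

## Core partial log-likelihood for one prepared diffusion.
## expG: length-n vector exp(linear predictor); s on the unbounded scale.
.oadaLoglik <- function(prep, form, tieMethod, s, expG) {
  n <- prep$n
  naive <- setdiff(seq_len(n), prep$disc)
  Tt <- if (is.null(prep$Wor)) numeric(n) else prep$Wor[, prep$disc]
  ll <- 0
  for (G in prep$groups) {
    if (!length(naive))
      stop("empty risk set with acquisition events remaining (task ",
           prep$task, ")", call. = FALSE)
    if (tieMethod == "breslow" || length(G) == 1L) {
      R <- .rates(form, s, Tt[naive], expG[naive])
      denom <- sum(R)
      ll <- ll + sum(log(.rates(form, s, Tt[G], expG[G]))) -
        length(G) * log(denom)
    } else {
      if (length(G) > 6L)
        stop("exact tie handling supports tie groups up to size 6")
      probs <- vapply(.permutations(G), function(ord) {
        p <- 1; nv <- naive; Tl <- Tt
        for (j in ord) {
          R <- .rates(form, s, Tl[nv], expG[nv])
          p <- p * R[match(j, nv)] / sum(R)
          Tl <- Tl + if (is.null(prep$Wor)) 0 else prep$Wor[, j]
          nv <- setdiff(nv, j)
        }
        p
      }, numeric(1))
      ll <- ll + log(mean(probs))
    }
    if (!is.null(prep$Wor))
      Tt <- Tt + rowSums(prep$Wor[, G, drop = FALSE])
    naive <- setdiff(naive, G)
  }
  ll
}

#' Partial log-likelihood of one diffusion experiment
#'
#' The order-of-acquisition partial likelihood: the discoverer is seeded as
#' informed before the first event; at each acquisition event the
#' contribution is the acquirer's rate over the summed rates of all naive
#' troop members (the risk set). Simultaneous acquisitions are handled per
#' the spec's tie method: `"breslow"` puts each tied acquirer's rate over
#' the common pre-event denominator; `"exact"` averages the full sequential
#' probability over all orderings of the tie group (groups up to size 6).
#' The two methods coincide when no ties exist.
#'
#' @param log a [DiffusionLog-class].
#' @param m the troop's [AssociationMatrix-class] for the spec's rule
#'   (ignored, may be `NULL`, for asocial specs).
#' @param spec an [OADASpec-class].
#' @param phenotypes phenotype table for the troop (defines the risk set).
#' @param s social transmission parameter, unbounded scale.
#' @param betas named ILV coefficients.
#' @return The summed log contributions (a nonpositive number).
#' @export
diffusionLoglik <- function(log, m, spec, phenotypes, s = 0,
                            betas = numeric()) {
  phen <- phenotypes[phenotypes$troop_id == log@troop, , drop = FALSE]
  if (!nrow(phen)) stop("no phenotypes for troop ", log@troop)
  ids <- if (!is.null(m)) m@ids else phen$individual_id
  if (length(miss <- setdiff(phen$individual_id, ids)))
    stop("network lacks troop member(s): ", paste(miss, collapse = ", "))
  prep <- .prepDiffusion(log, m, spec, ids)
  expG <- .expG(phen, ids, spec@ilvs, betas)
  .oadaLoglik(prep, spec@form, spec@tieMethod, s, expG)
}

.expG <- function(phen, ids, ilvs, betas) {
  if (!length(ilvs)) return(rep(1, length(ids)))
  if (!all(ilvs %in% names(betas)))
    stop("missing coefficient for ILV '",
         paste(setdiff(ilvs, names(betas)), collapse = "', '"), "'")
  X <- .ilvMatrix(phen, ilvs)
  G <- as.numeric(X %*% betas[ilvs])
  expG <- setNames(rep(1, length(ids)), ids)
  expG[rownames(X)] <- exp(G)
  unname(expG[ids])
}
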