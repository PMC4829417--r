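#' @importFrom stats optim
NULL

.aicc <- function(loglik, k, n) {
  corr <- if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
  -2 * loglik + 2 * k + corr
}

## Fixed multi-start schedule on log(s); deterministic by construction.
.LS_GRID <- c(-8, -2, 0, 2, 5)
.LS_BOUNDS <- c(-15, 15)

.networksForRule <- function(networks, rule) {
  if (is.null(networks)) return(NULL)
  if (is(networks, "AssociationMatrix"))
    return(setNames(list(networks), networks@troop))
  if (all(vapply(networks, is, logical(1), "AssociationMatrix"))) {
    nm <- vapply(networks, troopId, character(1))
    return(setNames(networks, nm))
  }
  # troop -> rule -> matrix
  setNames(lapply(networks, function(byRule) byRule[[rule]]), names(networks))
}

#' Fit an order-of-acquisition diffusion model
#'
#' Maximises the joint partial likelihood over all diffusion experiments
#' (each experiment is an independent likelihood factor — its own task —
#' and its troop selects the association matrix) with respect to the social
#' transmission parameter s and the ILV coefficients. s is optimised on the
#' log scale over a fixed deterministic multi-start schedule; both the
#' unbounded estimate and the bounded reporting scale s/(1+s) are returned,
#' together with the AICc computed from the total number of individual
#' acquisition events.
#'
#' @param logs list of [DiffusionLog-class].
#' @param networks the association matrices for the spec's rule: a single
#'   [AssociationMatrix-class], a list of per-troop matrices, or a list
#'   `troop -> rule -> matrix` (as from [buildNetworks()]); `NULL` for
#'   asocial specs.
#' @param spec an [OADASpec-class].
#' @param phenotypes phenotype table covering every troop in `logs`.
#' @param control optional list: `factr` (L-BFGS-B tolerance, default 1e6,
#'   i.e. ~1e-10 relative on the log-likelihood), `maxit` (default 500).
#' @return An [OADAFit-class]; a fit whose multi-start schedule never
#'   converged is returned with `converged = FALSE`, never silently.
#' @export
fitOada <- function(logs, networks, spec, phenotypes, control = list()) {
  social <- spec@form != "asocial"
  nets <- if (social) .networksForRule(networks, spec@rule) else NULL
  troops <- unique(vapply(logs, function(l) l@troop, character(1)))
  phenByTroop <- lapply(setNames(troops, troops), function(tr)
    phenotypes[phenotypes$troop_id == tr, , drop = FALSE])
  idsByTroop <- lapply(setNames(troops, troops), function(tr) {
    if (social) {
      m <- nets[[tr]]
      if (is.null(m)) stop("no network supplied for troop ", tr)
      m@ids
    } else phenByTroop[[tr]]$individual_id
  })
  preps <- lapply(logs, function(lg)
    .prepDiffusion(lg, if (social) nets[[lg@troop]] else NULL, spec,
                   idsByTroop[[lg@troop]]))
  troopOf <- vapply(logs, function(l) l@troop, character(1))
  ilvs <- spec@ilvs
  Xs <- lapply(setNames(troops, troops), function(tr) {
    if (!length(ilvs)) return(NULL)
    X <- .ilvMatrix(phenByTroop[[tr]], ilvs)
    X[idsByTroop[[tr]], , drop = FALSE]
  })
  nEvents <- sum(vapply(preps, function(p) sum(lengths(p$groups)), numeric(1)))
  fast <- vapply(preps, function(p)
    spec@tieMethod == "breslow" || p$maxTie <= 1L, logical(1))
  # pool the flattened per-event structures troop-wise: each diffusion is an
  # independent likelihood factor, so one rowsum over pooled event ids gives
  # the whole troop's contribution in a single vectorized pass
  pooled <- lapply(setNames(troops, troops), function(tr) {
    ps <- preps[troopOf == tr & fast]
    if (!length(ps)) return(NULL)
    off <- 0L; fe <- list()
    for (i in seq_along(ps)) {
      fe[[i]] <- ps[[i]]$flatEvent + off
      off <- off + length(ps[[i]]$groupSizes)
    }
    list(flatIdx = unlist(lapply(ps, `[[`, "flatIdx")),
         flatT = unlist(lapply(ps, `[[`, "flatT")),
         flatEvent = unlist(fe),
         numSel = unlist(lapply(ps, `[[`, "numSel")),
         groupSizes = unlist(lapply(ps, `[[`, "groupSizes")))
  })
  slowIdx <- which(!fast)

  totalLL <- function(s, betas) {
    ll <- 0
    for (tr in troops) {
      expG <- if (!length(ilvs)) rep(1, length(idsByTroop[[tr]]))
              else exp(as.numeric(Xs[[tr]] %*% betas))
      if (!is.null(pooled[[tr]]))
        ll <- ll + .oadaLoglikFast(pooled[[tr]], spec@form, s, expG)
      for (i in slowIdx[troopOf[slowIdx] == tr])
        ll <- ll + .oadaLoglik(preps[[i]], spec@form, spec@tieMethod, s, expG)
    }
    ll
  }

  factr <- control$factr %||% 1e6
  maxit <- control$maxit %||% 500
  nb <- length(ilvs)
  if (!social && nb == 0) {
    ll <- totalLL(0, numeric())
    s <- 0; betas <- setNames(numeric(0), character(0)); conv <- TRUE
  } else if (social && nb == 0) {
    negll <- function(ls) -totalLL(exp(ls), numeric())
    o <- optim(0, negll, method = "Brent", lower = .LS_BOUNDS[1],
               upper = .LS_BOUNDS[2], control = list(maxit = maxit))
    s <- exp(o$par); betas <- setNames(numeric(0), character(0))
    ll <- -o$value; conv <- o$convergence == 0
  } else {
    negll <- function(th) {
      v <- if (social) -totalLL(exp(th[1]), setNames(th[-1], ilvs))
           else -totalLL(0, setNames(th, ilvs))
      if (!is.finite(v)) 1e10 else v  # overflow guard far from the optimum
    }
    starts <- if (social) lapply(.LS_GRID, function(g) c(g, rep(0, nb)))
              else list(rep(0, nb))
    lower <- c(if (social) .LS_BOUNDS[1], rep(-20, nb))
    upper <- c(if (social) .LS_BOUNDS[2], rep(20, nb))
    best <- NULL
    for (st in starts) {
      o <- tryCatch(optim(st, negll, method = "L-BFGS-B", lower = lower,
                          upper = upper,
                          control = list(factr = factr, maxit = maxit)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("OADA optimisation failed for every start")
    conv <- best$convergence == 0
    polish <- tryCatch(optim(best$par, negll, method = "L-BFGS-B",
                             lower = lower, upper = upper,
                             control = list(factr = 1e3, maxit = maxit)),
                       error = function(e) NULL)
    # the polishing pass may end in a line-search failure at machine
    # precision; it still tightens the optimum, so keep the better value
    # and let convergence reflect the schedule as a whole
    if (!is.null(polish) && polish$value <= best$value) {
      best <- polish
      conv <- conv || polish$convergence == 0
    }
    s <- if (social) exp(best$par[1]) else 0
    betas <- setNames(if (social) best$par[-1] else best$par, ilvs)
    ll <- -best$value
  }
  k <- as.integer(nb + social)
  new("OADAFit", spec = spec, sUnbounded = s, sBounded = s / (1 + s),
      betas = betas, loglik = ll, k = k, nEvents = as.integer(nEvents),
      aicc = .aicc(ll, k, nEvents), converged = conv)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.modelSet <- function(fits, labels) {
  ok <- !vapply(fits, is.null, logical(1))
  aicc <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f@aicc,
                 numeric(1))
  delta <- aicc - min(aicc, na.rm = TRUE)
  w <- exp(-delta / 2); w <- w / sum(w, na.rm = TRUE)
  tab <- data.frame(
    model = labels,
    network = vapply(fits, function(f) if (is.null(f)) NA_character_ else f@spec@rule, character(1)),
    form = vapply(fits, function(f) if (is.null(f)) NA_character_ else f@spec@form, character(1)),
    ilvs = vapply(fits, function(f) if (is.null(f)) NA_character_ else paste(f@spec@ilvs, collapse = "+"), character(1)),
    k = vapply(fits, function(f) if (is.null(f)) NA_integer_ else f@k, integer(1)),
    loglik = vapply(fits, function(f) if (is.null(f)) NA_real_ else f@loglik, numeric(1)),
    aicc = aicc, delta_aicc = delta, akaike_weight = w,
    s_bounded = vapply(fits, function(f) if (is.null(f)) NA_real_ else f@sBounded, numeric(1)),
    converged = vapply(fits, function(f) if (is.null(f)) FALSE else f@converged, logical(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aicc), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- setNames(fits, labels)
  class(tab) <- c("ModelTable", class(tab))
  tab
}

#' @exportS3Method base::print
print.ModelTable <- function(x, ...) {
  cat(sprintf("OADA model table: %d candidate(s)\n", nrow(x)))
  print.data.frame(cbind(x[, c("model", "k")],
                         round(x[, c("loglik", "aicc", "delta_aicc",
                                     "akaike_weight", "s_bounded")], 3)), ...)
  invisible(x)
}

#' Compare candidate transmission networks by AICc
#'
#' Fits one OADA model per candidate network and form (default the eight
#' network rules under both additive and multiplicative ILV forms) plus one
#' asocial model without social transmission — all with the same diffusions
#' and the same ILVs — and ranks them by AICc with Akaike weights.
#'
#' @param logs list of [DiffusionLog-class] (all troops pooled; troop
#'   membership selects each experiment's matrix).
#' @param networks list `troop -> rule -> AssociationMatrix`, e.g. one
#'   [buildNetworks()] result per troop.
#' @param phenotypes phenotype table.
#' @param rules candidate rules (default every rule present for all troops).
#' @param forms ILV forms to cross with the networks.
#' @param ilvs ILVs included in every candidate (default all four).
#' @param tieMethod,direction passed to [oadaSpec()].
#' @param control passed to [fitOada()].
#' @return A `ModelTable` data.frame (ranked, with `delta_aicc` and Akaike
#'   weights summing to one) carrying the fits as an attribute. A candidate
#'   whose fit fails is kept as a row of `NA`s with `converged = FALSE`.
#' @export
compareNetworks <- function(logs, networks, phenotypes,
                            rules = Reduce(intersect, lapply(networks, names)),
                            forms = c("additive", "multiplicative"),
                            ilvs = ilvNames(), tieMethod = "breslow",
                            direction = "outgoing", control = list()) {
  fits <- list(); labels <- character()
  for (rule in rules) for (form in forms) {
    spec <- oadaSpec(rule, form, ilvs, tieMethod, direction)
    fits[[length(fits) + 1L]] <- tryCatch(
      fitOada(logs, networks, spec, phenotypes, control),
      error = function(e) NULL)
    labels <- c(labels, paste(rule, form, sep = "/"))
  }
  fits[[length(fits) + 1L]] <- fitOada(
    logs, NULL, oadaSpec("none", "asocial", ilvs, tieMethod, direction),
    phenotypes, control)
  labels <- c(labels, "asocial")
  .modelSet(fits, labels)
}

#' All-subsets ILV search on one network
#'
#' Fits OADA models with every combination of the individual-level
#' variables (2^4 subsets by default) under the requested forms on a single
#' candidate network, returning the ranked model table with Akaike weights.
#'
#' @param logs list of [DiffusionLog-class].
#' @param networks per-troop matrices for `rule` (formats as in
#'   [fitOada()]).
#' @param phenotypes phenotype table.
#' @param rule the network rule searched over (typically the AICc-best rule
#'   from [compareNetworks()]).
#' @param forms forms crossed with the subsets.
#' @param candidates list of ILV subsets (default the full power set).
#' @param tieMethod,direction,control as in [compareNetworks()].
#' @return A `ModelTable` (see [compareNetworks()]).
#' @export
ilvSubsetSearch <- function(logs, networks, phenotypes, rule = "ten_m",
                            forms = c("additive", "multiplicative"),
                            candidates = NULL, tieMethod = "breslow",
                            direction = "outgoing", control = list()) {
  if (is.null(candidates)) {
    candidates <- list(character(0))
    for (v in ilvNames())
      candidates <- c(candidates, lapply(candidates, c, v))
  }
  fits <- list(); labels <- character()
  for (form in forms) for (sub in candidates) {
    spec <- oadaSpec(rule, form, sub, tieMethod, direction)
    fits[[length(fits) + 1L]] <- tryCatch(
      fitOada(logs, networks, spec, phenotypes, control),
      error = function(e) NULL)
    labels <- c(labels, paste0(form, "{", paste(sub, collapse = "+"), "}"))
  }
  .modelSet(fits, labels)
}

#' Model-averaged ILV effect sizes
#'
#' Averages the ILV coefficients over the models within `threshold` AICc of
#' the best model, weighting by their renormalised Akaike weights and
#' substituting beta = 0 where an ILV is absent from a retained model
#' (full-model averaging).
#'
#' @param table a `ModelTable` from [compareNetworks()] or
#'   [ilvSubsetSearch()].
#' @param threshold retain models with `delta_aicc <= threshold` (default 2).
#' @return Named numeric vector of averaged coefficients over
#'   [ilvNames()], with attributes `retained` (model labels) and `weights`
#'   (renormalised Akaike weights).
#' @export
modelAverage <- function(table, threshold = 2) {
  if (!nrow(table)) stop("empty model table")
  keep <- which(!is.na(table$delta_aicc) & table$delta_aicc <= threshold)
  fits <- attr(table, "fits")[table$model[keep]]
  w <- table$akaike_weight[keep]
  w <- w / sum(w)
  avg <- setNames(numeric(length(ilvNames())), ilvNames())
  for (i in seq_along(fits)) {
    b <- fits[[i]]@betas
    full <- setNames(numeric(length(ilvNames())), ilvNames())
    full[names(b)] <- b
    avg <- avg + w[i] * full
  }
  structure(avg, retained = table$model[keep], weights = w)
}
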