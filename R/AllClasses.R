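#' @import methods
NULL

#' Recognised association-network rules
#'
#' The five field association rules yield eight candidate matrices per troop:
#' two undirected proximity indices (10 m radius and 5 m chain, both
#' simple-ratio indices), and three directed count matrices (nearest
#' neighbour, grooming, dominance) that are each also analysed after
#' symmetrization.
#'
#' @return Character vector of the eight matrix rule labels.
#' @export
networkRules <- function() {
  c("ten_m", "five_m_chain", "nn_directed", "nn_undirected",
    "groom_directed", "groom_undirected", "dom_directed", "dom_undirected")
}

#' Individual-level variables usable in acquisition-rate models
#' @return Character vector of covariate names.
#' @export
ilvNames <- function() c("rank", "sex", "age", "boldness")

#' Weighted association matrix for one troop under one rule
#'
#' Holds a square nonnegative weight matrix over the troop's individuals.
#' Simple-ratio rules are undirected with weights in [0, 1]; interaction and
#' nearest-neighbour rules are directed event counts until symmetrized.
#'
#' @slot troop single troop identifier.
#' @slot rule one of [networkRules()].
#' @slot ids individual identifiers, in matrix row/column order.
#' @slot weights numeric n x n matrix, zero diagonal, nonnegative.
#' @slot directed logical; FALSE implies a symmetric matrix.
#' @export
setClass("AssociationMatrix",
  representation(troop = "character", rule = "character",
                 ids = "character", weights = "matrix",
                 directed = "logical"))

setValidity("AssociationMatrix", function(object) {
  w <- object@weights
  n <- length(object@ids)
  msgs <- character()
  if (!is.numeric(w)) msgs <- c(msgs, "weights must be numeric")
  if (nrow(w) != n || ncol(w) != n)
    msgs <- c(msgs, "weights must be square with one row per id")
  if (anyDuplicated(object@ids)) msgs <- c(msgs, "duplicated ids")
  if (length(object@troop) != 1L) msgs <- c(msgs, "troop must be length 1")
  if (length(object@directed) != 1L) msgs <- c(msgs, "directed must be length 1")
  if (n > 0 && is.numeric(w) && nrow(w) == n && ncol(w) == n) {
    if (any(!is.finite(w))) msgs <- c(msgs, "non-finite weights")
    else {
      if (any(diag(w) != 0)) msgs <- c(msgs, "diagonal must be zero")
      if (any(w < 0)) msgs <- c(msgs, "weights must be nonnegative")
      if (!object@directed && !isTRUE(all.equal(w, t(w), tolerance = 1e-12)))
        msgs <- c(msgs, "undirected matrix must be symmetric")
      if (object@rule %in% c("ten_m", "five_m_chain") && any(w > 1))
        msgs <- c(msgs, "simple-ratio weights must lie in [0, 1]")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an AssociationMatrix
#'
#' @param weights square numeric matrix (row/col names used as ids when
#'   `ids` is missing).
#' @param rule matrix rule label, one of [networkRules()].
#' @param troop troop identifier.
#' @param ids individual ids in matrix order.
#' @param directed logical; defaults to the convention of `rule`
#'   (`*_directed` rules are directed, others undirected).
#' @return An [AssociationMatrix-class] object.
#' @examples
#' w <- matrix(c(0, .5, .5, 0), 2, 2, dimnames = list(c("a","b"), c("a","b")))
#' associationMatrix(w, rule = "ten_m", troop = "J")
#' @export
associationMatrix <- function(weights, rule, troop, ids = rownames(weights),
                              directed = grepl("_directed$", rule)) {
  rule <- match.arg(rule, networkRules())
  if (is.null(ids)) stop("ids are required (or name the weight matrix)")
  dimnames(weights) <- list(ids, ids)
  new("AssociationMatrix", troop = as.character(troop), rule = rule,
      ids = as.character(ids), weights = weights, directed = directed)
}

setMethod("show", "AssociationMatrix", function(object) {
  cat(sprintf("AssociationMatrix: troop %s, rule %s, %d individuals, %s\n",
              object@troop, object@rule, length(object@ids),
              if (object@directed) "directed" else "undirected"))
  nz <- sum(object@weights > 0)
  cat(sprintf("  %d nonzero edges, mean positive weight %.4g\n",
              nz, if (nz) mean(object@weights[object@weights > 0]) else 0))
})

#' One information-diffusion experiment
#'
#' Records a single food-patch trial: the discovering individual, the ordered
#' acquisition events (tie groups of individuals acquiring social information
#' simultaneously), and the application events (patch entries) with feeding,
#' co-feeding and vocal-protest flags.
#'
#' @slot task experiment identifier.
#' @slot troop troop identifier.
#' @slot discoverer id of the individual that found the patch.
#' @slot discoveryPosition spatial position of the discoverer in the troop at
#'   discovery: `"leading_edge"`, `"side"`, `"middle_back"` or `NA`.
#' @slot acquisitions list of character vectors; element k is the k-th tie
#'   group of acquirers (usually singletons).
#' @slot applications data.frame with columns `individual_id`, `fed`,
#'   `cofeed`, `protest` (logical flags), one row per patch entry in order.
#' @export
setClass("DiffusionLog",
  representation(task = "character", troop = "character",
                 discoverer = "character", discoveryPosition = "character",
                 acquisitions = "list", applications = "data.frame"))

setValidity("DiffusionLog", function(object) {
  msgs <- character()
  acq <- unlist(object@acquisitions, use.names = FALSE)
  if (anyDuplicated(acq))
    msgs <- c(msgs, "an individual appears in more than one tie group")
  if (object@discoverer %in% acq)
    msgs <- c(msgs, "discoverer must not appear in an acquisition tie group")
  app <- object@applications
  need <- c("individual_id", "fed", "cofeed", "protest")
  if (!all(need %in% names(app)))
    msgs <- c(msgs, "applications must have individual_id/fed/cofeed/protest")
  else {
    informed <- c(object@discoverer, acq)
    bad <- setdiff(app$individual_id, informed)
    if (length(bad))
      msgs <- c(msgs, paste0("application by uninformed individual(s): ",
                             paste(bad, collapse = ", ")))
    if (any(app$cofeed & !app$fed))
      msgs <- c(msgs, "cofeed flag requires fed flag")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DiffusionLog
#'
#' @param task,troop,discoverer identifiers (single strings).
#' @param acquisitions list of character vectors of ids (tie groups in event
#'   order); a plain character vector is taken as singleton events.
#' @param applications data.frame of patch entries (`individual_id`, `fed`,
#'   `cofeed`, `protest`); defaults to none.
#' @param discoveryPosition optional spatial position of discovery.
#' @return A [DiffusionLog-class] object.
#' @export
diffusionLog <- function(task, troop, discoverer, acquisitions = list(),
                         applications = NULL, discoveryPosition = NA_character_) {
  if (is.character(acquisitions)) acquisitions <- as.list(acquisitions)
  if (is.null(applications))
    applications <- data.frame(individual_id = character(), fed = logical(),
                               cofeed = logical(), protest = logical())
  new("DiffusionLog", task = as.character(task), troop = as.character(troop),
      discoverer = as.character(discoverer),
      discoveryPosition = as.character(discoveryPosition),
      acquisitions = lapply(acquisitions, as.character),
      applications = applications)
}

setMethod("show", "DiffusionLog", function(object) {
  cat(sprintf("DiffusionLog %s (troop %s): discoverer %s, %d acquisition event(s) / %d acquirer(s), %d patch entries\n",
              object@task, object@troop, object@discoverer,
              length(object@acquisitions),
              length(unlist(object@acquisitions)), nrow(object@applications)))
})

#' Specification of one OADA candidate model
#'
#' @slot rule transmission network rule, or `"none"` for the asocial model.
#' @slot form `"additive"`, `"multiplicative"` or `"asocial"`.
#' @slot ilvs subset of [ilvNames()] entering the acquisition rate.
#' @slot tieMethod `"breslow"` or `"exact"` handling of simultaneous
#'   acquisitions.
#' @slot direction for directed networks, whether the naive individual's
#'   `"outgoing"` or `"incoming"` edges carry transmission.
#' @export
setClass("OADASpec",
  representation(rule = "character", form = "character", ilvs = "character",
                 tieMethod = "character", direction = "character"))

setValidity("OADASpec", function(object) {
  msgs <- character()
  if (!object@form %in% c("additive", "multiplicative", "asocial"))
    msgs <- c(msgs, "unknown form")
  if ((object@form == "asocial") != (object@rule == "none"))
    msgs <- c(msgs, "form 'asocial' if and only if rule 'none'")
  if (object@rule != "none" && !object@rule %in% networkRules())
    msgs <- c(msgs, "unknown network rule")
  if (!all(object@ilvs %in% ilvNames())) msgs <- c(msgs, "unknown ILV")
  if (!object@tieMethod %in% c("breslow", "exact"))
    msgs <- c(msgs, "tieMethod must be breslow or exact")
  if (!object@direction %in% c("outgoing", "incoming"))
    msgs <- c(msgs, "direction must be outgoing or incoming")
  if (length(msgs)) msgs else TRUE
})

#' Construct an OADASpec
#'
#' @param rule network rule (see [networkRules()]) or `"none"`.
#' @param form `"additive"`, `"multiplicative"`, or `"asocial"` (implied by
#'   `rule = "none"`).
#' @param ilvs character subset of [ilvNames()].
#' @param tieMethod `"breslow"` (common pre-event denominator) or `"exact"`
#'   (average over tie orderings, tie groups up to size 6).
#' @param direction edge direction carrying transmission on directed
#'   networks: `"outgoing"` (naive individual attends to those it directs
#'   edges toward) or `"incoming"`.
#' @return An [OADASpec-class] object.
#' @export
oadaSpec <- function(rule = "ten_m",
                     form = if (identical(rule, "none")) "asocial" else "additive",
                     ilvs = character(), tieMethod = "breslow",
                     direction = "outgoing") {
  new("OADASpec", rule = rule, form = form, ilvs = as.character(ilvs),
      tieMethod = tieMethod, direction = direction)
}

setMethod("show", "OADASpec", function(object) {
  cat(sprintf("OADASpec: network %s, form %s, ILVs {%s}, ties %s\n",
              object@rule, object@form, paste(object@ilvs, collapse = ", "),
              object@tieMethod))
})

#' A fitted order-of-acquisition diffusion model
#'
#' @slot spec the [OADASpec-class] fitted.
#' @slot sUnbounded social-transmission rate ratio s on the [0, Inf) scale
#'   (0 for asocial models).
#' @slot sBounded s/(1+s), the bounded reporting scale in [0, 1).
#' @slot betas named ILV coefficients (log-rate scale).
#' @slot loglik maximised partial log-likelihood.
#' @slot k number of estimated parameters.
#' @slot nEvents total individual acquisition events (tied acquirers each
#'   count once) entering the AICc correction.
#' @slot aicc corrected Akaike information criterion.
#' @slot converged logical; FALSE flags a fit that exhausted the multi-start
#'   schedule without convergence.
#' @export
setClass("OADAFit",
  representation(spec = "OADASpec", sUnbounded = "numeric",
                 sBounded = "numeric", betas = "numeric", loglik = "numeric",
                 k = "integer", nEvents = "integer", aicc = "numeric",
                 converged = "logical"))

setValidity("OADAFit", function(object) {
  msgs <- character()
  if (object@sUnbounded < 0) msgs <- c(msgs, "s must be nonnegative")
  sb <- object@sUnbounded / (1 + object@sUnbounded)
  if (!isTRUE(all.equal(sb, object@sBounded, tolerance = 1e-10)))
    msgs <- c(msgs, "bounded and unbounded s are inconsistent")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "OADAFit", function(object) {
  cat(sprintf("OADAFit [%s/%s]: s = %.4g (bounded %.4g), logLik = %.3f, k = %d, AICc = %.2f%s\n",
              object@spec@rule, object@spec@form, object@sUnbounded,
              object@sBounded, object@loglik, object@k, object@aicc,
              if (object@converged) "" else "  [NOT CONVERGED]"))
  if (length(object@betas)) {
    cat("  ILV coefficients:\n")
    print(round(object@betas, 4))
  }
})
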