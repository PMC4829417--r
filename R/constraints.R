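#' @importFrom stats glm poisson as.formula coef
NULL

#' Assemble the six phenotypic predictors of information use
#'
#' The predictor set for the count models: relative dominance rank, boldness,
#' age, sex (female = 0, male = 1), and the individual strengths in the 10 m
#' proximity and the directed grooming networks (the best proximity and
#' interaction predictors of diffusion; betweenness is omitted as strongly
#' correlated with strength).
#'
#' @param phenotypes phenotype table.
#' @param networks list `troop -> rule -> AssociationMatrix` containing
#'   `ten_m` and `groom_directed`.
#' @return data.frame keyed by `individual_id` with `troop_id` and the six
#'   predictor columns `rank`, `boldness`, `age`, `sex`,
#'   `proximity_strength`, `grooming_strength`.
#' @export
constraintPredictors <- function(phenotypes, networks) {
  X <- .ilvMatrix(phenotypes)
  prox <- groom <- setNames(rep(NA_real_, nrow(phenotypes)),
                            phenotypes$individual_id)
  for (tr in names(networks)) {
    sp <- strength(networks[[tr]][["ten_m"]])
    sg <- strength(networks[[tr]][["groom_directed"]])
    prox[names(sp)] <- sp
    groom[names(sg)] <- sg
  }
  data.frame(individual_id = phenotypes$individual_id,
             troop_id = phenotypes$troop_id,
             rank = X[, "rank"], boldness = X[, "boldness"],
             age = X[, "age"], sex = X[, "sex"],
             proximity_strength = unname(prox[phenotypes$individual_id]),
             grooming_strength = unname(groom[phenotypes$individual_id]),
             stringsAsFactors = FALSE)
}

.coefTable <- function(model) {
  s <- coef(summary(model))
  if (inherits(model, "merMod")) s <- s  # same 4-column layout
  data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
             statistic = s[, 3], p = s[, 4], row.names = NULL,
             stringsAsFactors = FALSE)
}

.fitCountModel <- function(df, response, terms, method) {
  nTroop <- length(unique(df$troop_id))
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  if (method == "random" && nTroop >= 2) {
    fml <- as.formula(paste(response, "~", rhs, "+ (1 | troop_id)"))
    model <- suppressWarnings(
      lme4::glmer(fml, data = df, family = poisson(link = "log")))
    sd <- sqrt(unname(lme4::VarCorr(model)$troop_id[1, 1]))
  } else {
    rhs2 <- if (method == "fixed" && nTroop >= 2)
      paste(rhs, "+ troop_id") else rhs
    model <- glm(as.formula(paste(response, "~", rhs2)), data = df,
                 family = poisson(link = "log"))
    sd <- 0
  }
  list(model = model, random_sd = sd)
}

#' Poisson count model of information use against phenotype
#'
#' Fits a log-link Poisson regression of a per-individual information-use
#' count (acquired, applied or exploited) on the six phenotypic predictors,
#' with a random intercept per troop. Two-level random intercepts are
#' boundary-prone, so a fixed troop intercept is available side-by-side via
#' `method = "fixed"`; with a single troop the grouping degenerates and the
#' model reduces to a plain GLM.
#'
#' @param counts data.frame from [tallyCounts()].
#' @param predictors data.frame from [constraintPredictors()].
#' @param response `"acquired"`, `"applied"` or `"exploited"`.
#' @param method `"random"` (troop random intercept via `lme4::glmer`) or
#'   `"fixed"` (troop fixed effect via `glm`).
#' @param terms predictor columns to include (default all six).
#' @return An object of class `"constraintFit"`: coefficient table
#'   (`terms`), `random_sd`, the fitted `model`, and the data for
#'   refitting. A constant predictor column raises an error naming it.
#' @export
fitPoissonCounts <- function(counts, predictors,
                             response = c("acquired", "applied", "exploited"),
                             method = c("random", "fixed"),
                             terms = c("rank", "boldness", "age", "sex",
                                       "proximity_strength",
                                       "grooming_strength")) {
  response <- match.arg(response)
  method <- match.arg(method)
  df <- merge(predictors, counts, by = "individual_id")
  ycol <- paste0("n_", response)
  if (!ycol %in% names(df)) stop("counts lack column ", ycol)
  y <- df[[ycol]]
  if (any(y < 0) || any(y != round(y)))
    stop("counts must be nonnegative integers")
  for (tm in terms)
    if (length(unique(df[[tm]])) < 2)
      stop("degenerate (constant) predictor column: ", tm)
  df$.y <- y
  ft <- .fitCountModel(df, ".y", terms, method)
  structure(list(response = response, method = method,
                 terms = .coefTable(ft$model), random_sd = ft$random_sd,
                 model = ft$model, data = df, predictors = terms),
            class = "constraintFit")
}

#' @exportS3Method base::print
print.constraintFit <- function(x, ...) {
  cat(sprintf("Poisson count model: information %s (%s troop intercept, sd %.3g)\n",
              x$response, x$method, x$random_sd))
  print(cbind(x$terms["term"], round(x$terms[-1], 4)))
  invisible(x)
}

#' Backward elimination to the minimal count model
#'
#' Iteratively drops the predictor with the largest non-significant p-value
#' (p >= alpha) and refits, until every retained term is significant. Each
#' dropped term is then re-added singly to the minimal model to confirm it
#' stays non-significant; a re-added term that turns significant is flagged
#' as an inconsistency in the trace (the minimal model is not changed).
#'
#' @param fit a `"constraintFit"` from [fitPoissonCounts()].
#' @param alpha significance level (default 0.05).
#' @return A `"constraintFit"` for the minimal model with an added
#'   `elimination_trace` data.frame (`term`, `p_at_drop`, `p_readded`,
#'   `flagged`) in drop order.
#' @export
backwardEliminate <- function(fit, alpha = 0.05) {
  terms <- fit$predictors
  df <- fit$data
  trace <- data.frame(term = character(), p_at_drop = numeric(),
                      p_readded = numeric(), flagged = logical(),
                      stringsAsFactors = FALSE)
  current <- fit
  repeat {
    tt <- current$terms
    tt <- tt[tt$term %in% terms, , drop = FALSE]
    if (!nrow(tt)) break
    worst <- tt[which.max(tt$p), ]
    if (is.na(worst$p) || worst$p < alpha) break
    terms <- setdiff(terms, worst$term)
    trace <- rbind(trace, data.frame(term = worst$term,
                                     p_at_drop = worst$p,
                                     p_readded = NA_real_, flagged = FALSE))
    ft <- .fitCountModel(df, ".y", terms, fit$method)
    current <- fit
    current$terms <- .coefTable(ft$model)
    current$random_sd <- ft$random_sd
    current$model <- ft$model
  }
  # dropped terms re-added singly to the minimal model to check significance
  for (i in seq_len(nrow(trace))) {
    ft <- .fitCountModel(df, ".y", c(terms, trace$term[i]), fit$method)
    ct <- .coefTable(ft$model)
    p <- ct$p[ct$term == trace$term[i]]
    trace$p_readded[i] <- p
    trace$flagged[i] <- is.finite(p) && p < alpha
  }
  out <- current
  out$predictors <- terms
  out$elimination_trace <- trace
  class(out) <- "constraintFit"
  out
}

#' Collinearity screen of the predictor set
#'
#' Pairwise Spearman correlations among the six phenotypic predictors,
#' flagging pairs whose |rho| reaches the concern threshold.
#'
#' @param predictors data.frame from [constraintPredictors()].
#' @param threshold absolute correlation of concern (default 0.7).
#' @return The [spearmanScreen()] table with a `flagged` column.
#' @export
collinearityScreen <- function(predictors, threshold = 0.7) {
  num <- predictors[setdiff(names(predictors),
                            c("individual_id", "troop_id"))]
  spearmanScreen(num, flagThreshold = threshold)
}
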