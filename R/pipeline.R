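#' @importFrom utils packageVersion capture.output
NULL

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

.sig <- function(df, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}

.configHash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Validate and normalise a pipeline configuration
#'
#' A configuration is a named list with either a `simulate` element
#' (arguments to [simScenario()]) or a `paths` element naming the four
#' input CSVs (`phenotypes`, `scans`, `interactions`, `diffusions`), plus
#' optional analysis settings: `rules` (networks to build/compare, default
#' all eight), `forms`, `ilvs`, `deltaThreshold` (model-averaging cutoff,
#' default 2), `alpha` (default 0.05), `seed`, `outDir`.
#'
#' @param config named list.
#' @return The completed config; errors (missing files, unknown rules,
#'   nonpositive threshold) are raised before any computation.
#' @export
validateConfig <- function(config) {
  defaults <- list(rules = networkRules(),
                   forms = c("additive", "multiplicative"),
                   ilvs = ilvNames(), deltaThreshold = 2, alpha = 0.05,
                   seed = 1L, outDir = NULL)
  config <- modifyList(defaults, config)
  if (!all(config$rules %in% networkRules()))
    stop("unknown network rule(s): ",
         paste(setdiff(config$rules, networkRules()), collapse = ", "))
  if (config$deltaThreshold <= 0) stop("deltaThreshold must be positive")
  if (is.null(config$simulate) == is.null(config$paths))
    stop("config needs exactly one of 'simulate' or 'paths'")
  if (!is.null(config$paths)) {
    need <- c("phenotypes", "scans", "interactions", "diffusions")
    if (!all(need %in% names(config$paths)))
      stop("paths must name ", paste(need, collapse = ", "))
    for (p in unlist(config$paths))
      if (!file.exists(p)) stop("input file not found: ", p)
  }
  config
}

#' Run the full diffusion-analysis pipeline
#'
#' End-to-end orchestration: load (or simulate) the records, build the
#' eight candidate networks per troop, compute centralities and the
#' strength-betweenness rank-correlation screen, compare transmission
#' networks by AICc, search ILV subsets on the best network and
#' model-average the retained set, tally information-use counts with
#' co-feeding and discovery-position summaries, and fit the phenotypic
#' constraint models (full and minimal) for the three responses. The run is
#' a pure function of (inputs, config, seed); numeric tables are written at
#' 6 significant digits for reproducible diffs.
#'
#' @param config see [validateConfig()].
#' @return Invisibly, the report bundle: a named list of all tables and
#'   fitted objects. If `config$outDir` is set, every table is also written
#'   there as CSV together with a `run_log.txt` (versions, config hash,
#'   per-stage wall time).
#' @export
runPipeline <- function(config) {
  config <- .stage("config", validateConfig(config))
  t0 <- proc.time()[["elapsed"]]; timing <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timing[[name]] <<- t1 - t0; t0 <<- t1
  }

  if (!is.null(config$simulate)) {
    scen <- do.call(simScenario, modifyList(list(seed = config$seed),
                                            config$simulate))
    study <- .stage("simulate", simulateStudy(scen))
    pop <- study$population; scans <- study$scans
    inter <- study$interactions; logs <- study$logs
    networks <- study$networks
  } else {
    pop <- .stage("read", readRecords(config$paths$phenotypes, "phenotypes"))
    scans <- .stage("read", readRecords(config$paths$scans, "scans"))
    inter <- .stage("read", readRecords(config$paths$interactions,
                                        "interactions"))
    logs <- .stage("read", readRecords(config$paths$diffusions, "diffusions"))
    troops <- unique(pop$troop_id)
    networks <- .stage("networks", lapply(setNames(troops, troops),
      function(tr) buildNetworks(scans[scans$troop_id == tr, ],
                                 inter[inter$troop_id == tr, ],
                                 ids = pop$individual_id[pop$troop_id == tr])))
  }
  networksAll <- networks  # constraints always use ten_m + groom_directed
  networks <- lapply(networks, function(x) x[config$rules])
  tick("inputs")

  centrality <- .stage("centrality", do.call(rbind, unlist(lapply(networks,
    function(byRule) lapply(byRule, centralityTable)), recursive = FALSE)))
  rownames(centrality) <- NULL
  sbScreen <- .stage("centrality", do.call(rbind, lapply(
    unlist(networks, recursive = FALSE), function(m) {
      ct <- centralityTable(m)
      sc <- spearmanScreen(ct[c("strength", "betweenness")])
      cbind(troop = m@troop, rule = m@rule, sc)
    })))
  rownames(sbScreen) <- NULL
  tick("centrality")

  netTable <- .stage("compare_networks", compareNetworks(
    logs, networks, pop, rules = config$rules, forms = config$forms,
    ilvs = config$ilvs))
  bestRule <- netTable$network[which(netTable$form != "asocial")[1]]
  bestForm <- netTable$form[which(netTable$form != "asocial")[1]]
  tick("compare_networks")

  ilvTable <- .stage("ilv_search", ilvSubsetSearch(
    logs, networks, pop, rule = bestRule, forms = config$forms))
  avgForm <- ilvTable$form[1]
  avgBetas <- .stage("ilv_search", modelAverage(ilvTable,
                                                config$deltaThreshold))
  tick("ilv_search")

  counts <- .stage("tallies", suppressWarnings(
    tallyCounts(logs, ids = pop$individual_id)))
  cofeed <- .stage("tallies", cofeedSummary(logs))
  discovery <- .stage("tallies", discoverySummary(logs))
  tick("tallies")

  preds <- .stage("constraints", constraintPredictors(pop, networksAll))
  collin <- .stage("constraints", collinearityScreen(preds))
  constraintFits <- .stage("constraints", lapply(
    setNames(c("acquired", "applied", "exploited"),
             c("acquired", "applied", "exploited")),
    function(resp) {
      full <- fitPoissonCounts(counts, preds, response = resp)
      list(full = full, minimal = backwardEliminate(full, config$alpha))
    }))
  tick("constraints")

  bundle <- list(config = config, population = pop, networks = networks,
                 centrality = centrality, strengthBetweenness = sbScreen,
                 networkComparison = netTable, bestRule = bestRule,
                 bestForm = bestForm, ilvSearch = ilvTable,
                 averagedBetas = avgBetas, averagedForm = avgForm,
                 counts = counts, cofeed = cofeed, discovery = discovery,
                 predictors = preds, collinearity = collin,
                 constraints = constraintFits, logs = logs,
                 timing = timing)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name)
      write.csv(.sig(as.data.frame(df)), file.path(config$outDir,
                                                   paste0(name, ".csv")),
                row.names = FALSE)
    for (tr in names(networks)) for (rl in names(networks[[tr]]))
      writeEdgeList(networks[[tr]][[rl]],
                    file.path(config$outDir,
                              sprintf("network_%s_%s.csv", rl, tr)))
    wr(centrality, "centrality")
    wr(sbScreen, "strength_betweenness_screen")
    wr(as.data.frame(netTable), "network_comparison")
    wr(as.data.frame(ilvTable), "ilv_search")
    wr(data.frame(ilv = names(avgBetas), beta = as.numeric(avgBetas)),
       "averaged_betas")
    wr(counts, "information_counts")
    wr(cofeed, "cofeed_summary")
    wr(discovery, "discovery_summary")
    wr(collin, "collinearity")
    for (resp in names(constraintFits))
      wr(constraintFits[[resp]]$minimal$terms,
         paste0("constraints_", resp, "_minimal"))
    writeLines(c(sprintf("SocialDiffusion %s, R %s",
                         as.character(packageVersion("SocialDiffusion")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("config hash: %s", .configHash(config)),
                 sprintf("seed: %s", config$seed),
                 sprintf("stage timing (s): %s",
                         paste(names(timing), round(unlist(timing), 2),
                               sep = "=", collapse = ", "))),
               file.path(config$outDir, "run_log.txt"))
    writeReport(bundle, file.path(config$outDir, "report.txt"))
  }
  invisible(bundle)
}

#' Write a human-readable pipeline report
#'
#' One section per table family: network comparison (model, form, network,
#' df, logLik, AICc), ILV search with Akaike weights and the model-averaged
#' effects, the social-transmission estimate on both scales, information-use
#' tallies with the co-feeding and discovery summaries, and the minimal
#' constraint models.
#'
#' @param bundle result of [runPipeline()].
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
writeReport <- function(bundle, path) {
  fmt <- function(df) capture.output(print(.sig(as.data.frame(df)),
                                           row.names = FALSE))
  out <- c("Social information diffusion: pipeline report",
           strrep("=", 46), "")
  nt <- bundle$networkComparison
  out <- c(out, "-- Transmission network comparison (OADA, AICc) --",
           if (is.null(nt) || !nrow(nt)) "no models fitted" else
             fmt(nt[c("model", "network", "form", "k", "loglik", "aicc",
                      "delta_aicc", "akaike_weight")]), "")
  best <- if (!is.null(nt) && nrow(nt)) attr(nt, "fits")[[nt$model[1]]]
  if (!is.null(best))
    out <- c(out, sprintf("best model: %s; social transmission s = %.6g (unbounded) = %.6g (bounded)",
                          nt$model[1], best@sUnbounded, best@sBounded), "")
  it <- bundle$ilvSearch
  out <- c(out, "-- ILV subset search on the best network --",
           if (is.null(it) || !nrow(it)) "no models fitted" else
             fmt(utils::head(as.data.frame(it)[c("model", "k", "loglik",
                                                 "aicc", "delta_aicc",
                                                 "akaike_weight")], 10)), "",
           "model-averaged ILV effects (delta AICc <= threshold):",
           fmt(data.frame(ilv = names(bundle$averagedBetas),
                          beta = as.numeric(bundle$averagedBetas))), "")
  out <- c(out, "-- Information use --",
           fmt(bundle$cofeed), "", fmt(bundle$discovery), "")
  for (resp in names(bundle$constraints))
    out <- c(out, sprintf("-- Minimal constraint model: information %s --",
                          resp),
             fmt(bundle$constraints[[resp]]$minimal$terms), "")
  writeLines(out, path)
  invisible(path)
}
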