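#' @importFrom utils read.csv write.csv
NULL

## Reserved id for acquirers that field observers could not identify.
## Such events are representable in diffusion logs but are dropped (with a
## warning) from tallies and likelihoods.
UNKNOWN_ID <- "UNKNOWN"

.schemas <- list(
  phenotypes   = c("individual_id", "troop_id", "sex", "age",
                   "absolute_rank", "boldness"),
  scans        = c("scan_id", "troop_id", "timestamp", "rule",
                   "focal_id", "associates"),
  interactions = c("event_id", "troop_id", "timestamp", "type",
                   "actor_id", "recipient_id"),
  diffusions   = c("task_id", "troop_id", "event_type", "event_index",
                   "individual_id", "fed", "cofeed", "protest",
                   "discovery_position")
)

.rowError <- function(rows, what) {
  stop(sprintf("malformed record(s) at row %s: %s",
               paste(rows, collapse = ", "), what), call. = FALSE)
}

.validatePhenotypes <- function(df) {
  if (any(bad <- !df$sex %in% c("female", "male")))
    .rowError(which(bad), "sex must be 'female' or 'male'")
  if (any(bad <- !is.finite(df$age) | df$age <= 0))
    .rowError(which(bad), "age must be a positive number of years")
  if (any(bad <- !is.finite(df$boldness) | df$boldness < 0))
    .rowError(which(bad), "boldness must be a nonnegative time in seconds")
  for (tr in unique(df$troop_id)) {
    r <- sort(df$absolute_rank[df$troop_id == tr])
    if (!identical(as.integer(r), seq_along(r)))
      stop(sprintf("absolute ranks in troop %s are not a permutation of 1..%d",
                   tr, length(r)), call. = FALSE)
  }
  df$age_class <- ifelse(df$age >= 6, "adult", "juvenile")
  df
}

.validateScans <- function(df) {
  ok <- c("ten_m", "five_m_chain", "nearest_neighbour")
  if (any(bad <- !df$rule %in% ok))
    .rowError(which(bad), paste("rule must be one of", paste(ok, collapse = "/")))
  assoc <- strsplit(ifelse(is.na(df$associates), "", df$associates), ";",
                    fixed = TRUE)
  assoc <- lapply(assoc, function(a) a[nzchar(a)])
  if (any(bad <- mapply(function(f, a) f %in% a, df$focal_id, assoc)))
    .rowError(which(bad), "focal_id must not appear among its associates")
  if (any(bad <- df$rule == "nearest_neighbour" & lengths(assoc) > 1L))
    .rowError(which(bad), "nearest_neighbour scans admit at most one associate")
  df
}

.validateInteractions <- function(df) {
  if (any(bad <- !df$type %in% c("groom", "dominance")))
    .rowError(which(bad), "type must be 'groom' or 'dominance'")
  if (any(bad <- df$actor_id == df$recipient_id))
    .rowError(which(bad), "actor and recipient must differ")
  df
}

#' Read a table of validated field records
#'
#' Reads one of the four record tables from CSV (comma-separated, UTF-8, one
#' record per row; multi-member associate lists semicolon-joined within the
#' cell), validates every row against the schema invariants, and returns the
#' records with row order preserved. The `"diffusions"` schema stores one row
#' per event (discovery, acquisition or application) and is returned as a
#' list of [DiffusionLog-class] objects; tied acquisitions share an
#' `event_index`.
#'
#' @param path CSV file path.
#' @param schema one of `"phenotypes"`, `"scans"`, `"interactions"`,
#'   `"diffusions"`.
#' @return A validated data.frame, or a list of `DiffusionLog` for the
#'   diffusions schema. Malformed rows raise an error naming the row and the
#'   violated invariant.
#' @seealso [writeRecords()] for the inverse; the round trip is lossless.
#' @export
readRecords <- function(path, schema = names(.schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- .schemas[[schema]]
  if (!all(need %in% names(df)))
    stop(sprintf("header of %s does not match schema '%s' (missing: %s)",
                 path, schema, paste(setdiff(need, names(df)), collapse = ", ")))
  df <- df[need]
  switch(schema,
         phenotypes   = .validatePhenotypes(df),
         scans        = .validateScans(df),
         interactions = .validateInteractions(df),
         diffusions   = framesToLogs(df))
}

#' Write records to CSV
#'
#' @param x a record data.frame, or a list of [DiffusionLog-class] for the
#'   diffusions schema.
#' @param path output CSV path.
#' @param schema record schema name (see [readRecords()]).
#' @return `path`, invisibly.
#' @export
writeRecords <- function(x, path, schema = names(.schemas)) {
  schema <- match.arg(schema)
  if (schema == "diffusions" && is.list(x) && !is.data.frame(x))
    x <- logsToFrame(x)
  x <- as.data.frame(x)[.schemas[[schema]]]
  write.csv(x, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert diffusion logs to/from the long event table
#'
#' The on-disk form of a diffusion experiment is a long table with one row
#' per event: a `discovery` row for the discoverer (carrying the discovery
#' position), `acquisition` rows ordered by `event_index` (equal indices are
#' a tie group), and `application` rows (patch entries, in order) carrying
#' the `fed`, `cofeed` and `protest` flags.
#'
#' @param logs list of [DiffusionLog-class].
#' @param df long event data.frame with the `diffusions` schema columns.
#' @return `logsToFrame` a data.frame; `framesToLogs` a list of
#'   `DiffusionLog`.
#' @export
logsToFrame <- function(logs) {
  rows <- lapply(logs, function(lg) {
    acq <- lg@acquisitions
    d <- data.frame(task_id = lg@task, troop_id = lg@troop,
                    event_type = "discovery", event_index = 0L,
                    individual_id = lg@discoverer, fed = NA, cofeed = NA,
                    protest = NA, discovery_position = lg@discoveryPosition)
    if (length(acq)) {
      a <- data.frame(task_id = lg@task, troop_id = lg@troop,
                      event_type = "acquisition",
                      event_index = rep(seq_along(acq), lengths(acq)),
                      individual_id = unlist(acq, use.names = FALSE),
                      fed = NA, cofeed = NA, protest = NA,
                      discovery_position = NA_character_)
      d <- rbind(d, a)
    }
    app <- lg@applications
    if (nrow(app)) {
      p <- data.frame(task_id = lg@task, troop_id = lg@troop,
                      event_type = "application", event_index = seq_len(nrow(app)),
                      individual_id = app$individual_id, fed = app$fed,
                      cofeed = app$cofeed, protest = app$protest,
                      discovery_position = NA_character_)
      d <- rbind(d, p)
    }
    d
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @rdname logsToFrame
#' @export
framesToLogs <- function(df) {
  ok <- c("discovery", "acquisition", "application")
  if (any(bad <- !df$event_type %in% ok))
    .rowError(which(bad), "event_type must be discovery/acquisition/application")
  lapply(split(df, factor(df$task_id, levels = unique(df$task_id))),
         function(d) {
    disc <- d[d$event_type == "discovery", ]
    if (nrow(disc) != 1L)
      stop(sprintf("task %s must have exactly one discovery row", d$task_id[1]),
           call. = FALSE)
    acq <- d[d$event_type == "acquisition", ]
    acq <- acq[order(acq$event_index), ]
    groups <- if (nrow(acq))
      unname(split(acq$individual_id, acq$event_index)) else list()
    app <- d[d$event_type == "application", ]
    app <- app[order(app$event_index), ]
    diffusionLog(task = d$task_id[1], troop = d$troop_id[1],
                 discoverer = disc$individual_id,
                 acquisitions = groups,
                 applications = data.frame(
                   individual_id = app$individual_id,
                   fed = as.logical(app$fed),
                   cofeed = as.logical(app$cofeed),
                   protest = as.logical(app$protest)),
                 discoveryPosition = disc$discovery_position)
  })
}

#' Relative dominance rank
#'
#' Scales an absolute rank r (1 = highest) in a troop of n to
#' `1 - (1 - r)/(1 - n)`, which controls for group size and runs from 0
#' (lowest-ranked) to 1 (highest-ranked).
#'
#' @param r absolute rank(s), integer in 1..n.
#' @param n troop size, at least 2.
#' @return Numeric in [0, 1], strictly decreasing in `r`.
#' @examples
#' relativeRank(1, 46)   # 1: the alpha
#' relativeRank(46, 46)  # 0: the lowest rank
#' @export
relativeRank <- function(r, n) {
  if (any(n < 2)) stop("troop size n must be at least 2")
  if (any(r < 1 | r > n)) stop("absolute rank r must lie in 1..n")
  1 - (1 - r) / (1 - n)
}

.dropUnknown <- function(ids, context) {
  if (any(unk <- ids == UNKNOWN_ID)) {
    warning(sprintf("%d unidentified (%s) individual(s) dropped from %s",
                    sum(unk), UNKNOWN_ID, context), call. = FALSE)
    ids <- ids[!unk]
  }
  ids
}

#' Per-individual information-use counts
#'
#' Tallies, over a set of diffusion experiments, how often each individual
#' acquired social information (appeared in an acquisition tie group),
#' applied it (entered the patch) and exploited it (ate from the patch) —
#' excluding, for all three counts, the trials in which that individual
#' discovered the patch itself; discoveries are tallied separately.
#' Unidentified (`UNKNOWN`) acquirers are dropped with a warning.
#'
#' @param logs list of [DiffusionLog-class].
#' @param ids optional character vector of individuals to report (zero rows
#'   of zeros are kept for individuals never observed in a log).
#' @return data.frame with columns `individual_id`, `n_acquired`,
#'   `n_applied`, `n_exploited`, `n_discovered`.
#' @export
tallyCounts <- function(logs, ids = NULL) {
  acq <- app <- exp_ <- disc <- character()
  for (lg in logs) {
    a <- .dropUnknown(unlist(lg@acquisitions, use.names = FALSE),
                      paste("tallies of task", lg@task))
    acq <- c(acq, a)
    ap <- lg@applications
    ap <- ap[ap$individual_id != lg@discoverer, , drop = FALSE]  # discovery occasions excluded
    app <- c(app, ap$individual_id)
    exp_ <- c(exp_, ap$individual_id[ap$fed])
    disc <- c(disc, lg@discoverer)
  }
  if (is.null(ids)) ids <- sort(unique(c(acq, app, disc)))
  cnt <- function(x) as.integer(table(factor(x, levels = ids)))
  data.frame(individual_id = ids, n_acquired = cnt(acq), n_applied = cnt(app),
             n_exploited = cnt(exp_), n_discovered = cnt(disc),
             stringsAsFactors = FALSE)
}

.applicationFrame <- function(x) {
  if (is.data.frame(x)) return(x)
  do.call(rbind, lapply(x, function(lg) {
    ap <- lg@applications
    ap[ap$individual_id != lg@discoverer, , drop = FALSE]
  }))
}

#' Co-feeding summary over patch entries
#'
#' Summarises tolerance at the food patch: total patch entries, co-feeding
#' occasions (two or more individuals feeding simultaneously), protested
#' co-feeds (vocal protest by a party) and tolerated co-feeds (co-feeds
#' minus protested ones), with percentages of all entries reported to one
#' decimal place. With zero entries the percentages are undefined and
#' reported as `NA`.
#'
#' @param x list of [DiffusionLog-class] (discoverers' own entries excluded)
#'   or a data.frame of application events with logical `fed`, `cofeed`,
#'   `protest` columns.
#' @return One-row data.frame: `entries`, `cofeeds`, `protested`,
#'   `tolerated`, `cofeed_pct`, `tolerated_pct`.
#' @export
cofeedSummary <- function(x) {
  ap <- .applicationFrame(x)
  entries <- if (is.null(ap)) 0L else nrow(ap)
  cofeeds <- if (entries) sum(ap$cofeed, na.rm = TRUE) else 0L
  protested <- if (entries) sum(ap$cofeed & ap$protest, na.rm = TRUE) else 0L
  tolerated <- cofeeds - protested
  pct <- function(k) if (entries) round(100 * k / entries, 1) else NA_real_
  data.frame(entries = entries, cofeeds = cofeeds, protested = protested,
             tolerated = tolerated, cofeed_pct = pct(cofeeds),
             tolerated_pct = pct(tolerated))
}

#' Where in the troop were patches discovered?
#'
#' Tallies the spatial position of the discovering individual (leading edge,
#' side periphery, middle-back) over a set of experiments and reports counts
#' and percentages.
#'
#' @param x list of [DiffusionLog-class] with `discoveryPosition` set, or a
#'   character vector of positions.
#' @return data.frame with `position`, `n`, `pct` (one decimal place).
#' @export
discoverySummary <- function(x) {
  pos <- if (is.character(x)) x else
    vapply(x, function(lg) lg@discoveryPosition, character(1))
  pos <- pos[!is.na(pos)]
  levs <- c("leading_edge", "side", "middle_back")
  tab <- table(factor(pos, levels = union(levs, unique(pos))))
  data.frame(position = names(tab), n = as.integer(tab),
             pct = round(100 * as.integer(tab) / length(pos), 1),
             stringsAsFactors = FALSE)
}
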