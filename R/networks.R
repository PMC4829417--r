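#' @importFrom stats cor.test
NULL

.parseAssociates <- function(a) {
  a <- strsplit(ifelse(is.na(a), "", a), ";", fixed = TRUE)
  lapply(a, function(x) x[nzchar(x)])
}

## Groups observed at each sampling occasion. A scan row's group is
## focal + associates; rows sharing a scan_id with overlapping membership
## are merged (field observers may list one chain group over several rows).
## An occasion is one (troop, timestamp) sampling event; distinct groups at
## the same occasion are individuals observed apart.
.scanOccasions <- function(scans) {
  groups <- mapply(function(f, a) unique(c(f, a)), scans$focal_id,
                   .parseAssociates(scans$associates), SIMPLIFY = FALSE)
  occKey <- paste(scans$troop_id, scans$timestamp, sep = "\r")
  if (!anyDuplicated(scans$scan_id))
    return(split(groups, factor(occKey, levels = unique(occKey))))
  merged <- list(); keys <- character()
  byScan <- split(seq_along(groups),
                  factor(scans$scan_id, levels = unique(scans$scan_id)))
  for (idx in byScan) {
    gs <- groups[idx]
    # union overlapping member lists within this scan_id
    i <- 1L
    while (i < length(gs)) {
      j <- i + 1L; grew <- FALSE
      while (j <= length(gs)) {
        if (length(intersect(gs[[i]], gs[[j]]))) {
          gs[[i]] <- union(gs[[i]], gs[[j]]); gs[[j]] <- NULL; grew <- TRUE
        } else j <- j + 1L
      }
      if (!grew) i <- i + 1L
    }
    merged <- c(merged, gs)
    keys <- c(keys, rep(occKey[idx[1]], length(gs)))
  }
  split(merged, factor(keys, levels = unique(keys)))
}

#' Simple-ratio association index matrix
#'
#' Builds the undirected SRI network from proximity scans under one rule.
#' For each dyad the weight is `x / (x + y_ab + y_a + y_b)`, where `x` counts
#' sampling occasions with A and B observed in the same group, `y_ab`
#' occasions with both observed but in different groups, and `y_a` (`y_b`)
#' occasions where only A (only B) was observed.
#'
#' @param scans data.frame of scan records (see [readRecords()]), all of the
#'   requested rule, from one troop.
#' @param rule `"ten_m"` or `"five_m_chain"`.
#' @param ids individuals to include; defaults to every id observed. An id
#'   that was never observed has no defined index and raises an error naming
#'   it.
#' @return An undirected [AssociationMatrix-class] with weights in [0, 1].
#' @export
sriMatrix <- function(scans, rule = c("ten_m", "five_m_chain"), ids = NULL) {
  rule <- match.arg(rule)
  scans <- scans[scans$rule == rule, , drop = FALSE]
  if (!nrow(scans)) stop("no scans of rule ", rule)
  troop <- unique(scans$troop_id)
  if (length(troop) != 1L) stop("scans must come from a single troop")
  occ <- .scanOccasions(scans)
  seen <- unique(unlist(occ, use.names = FALSE))
  if (is.null(ids)) ids <- sort(seen)
  if (length(miss <- setdiff(ids, seen)))
    stop("association index undefined for never-observed individual(s): ",
         paste(miss, collapse = ", "))
  n <- length(ids)
  x <- yab <- ya <- matrix(0, n, n, dimnames = list(ids, ids))
  for (gs in occ) {
    obs <- ids %in% unlist(gs, use.names = FALSE)
    cog <- matrix(FALSE, n, n)
    for (g in gs) {
      m <- ids %in% g
      cog <- cog | outer(m, m, "&")
    }
    both <- outer(obs, obs, "&")
    x <- x + (cog & both)
    yab <- yab + (both & !cog)
    ya <- ya + outer(obs, !obs, "&")
  }
  den <- x + yab + ya + t(ya)
  w <- ifelse(den > 0, x / den, 0)
  diag(w) <- 0
  associationMatrix(w, rule = rule, troop = troop, ids = ids,
                    directed = FALSE)
}

#' Directed interaction / nearest-neighbour count matrix
#'
#' Counts, for each ordered dyad, the events in which A acted toward B: A
#' groomed B, A was aggressive toward B, or A had B as its nearest
#' neighbour (the focal names the neighbour).
#'
#' @param records interaction records of a single type, or nearest-neighbour
#'   scan records.
#' @param type `"groom"`, `"dominance"` or `"nearest_neighbour"`; inferred
#'   when the records are unambiguous.
#' @param ids individuals to include (defaults to all ids appearing).
#' @param troop troop identifier, required only when `records` is empty.
#' @return A directed [AssociationMatrix-class] of counts with rule
#'   `nn_directed`, `groom_directed` or `dom_directed`.
#' @export
directedCountMatrix <- function(records, type = NULL, ids = NULL,
                                troop = NULL) {
  if (!is.null(records$actor_id)) {
    if (is.null(type)) {
      type <- unique(records$type)
      if (length(type) > 1L) stop("records mix interaction types; pass `type`")
      if (!length(type)) stop("empty records; pass `type`")
    }
    records <- records[records$type == type, , drop = FALSE]
    from <- records$actor_id; to <- records$recipient_id
    rule <- c(groom = "groom_directed", dominance = "dom_directed")[[type]]
  } else {
    records <- records[records$rule == "nearest_neighbour", , drop = FALSE]
    assoc <- .parseAssociates(records$associates)
    keep <- lengths(assoc) == 1L
    from <- records$focal_id[keep]
    to <- unlist(assoc[keep], use.names = FALSE)
    rule <- "nn_directed"
  }
  troop <- unique(c(records$troop_id, troop))
  if (length(troop) != 1L)
    stop("records must come from a single troop (or pass `troop` when empty)")
  if (is.null(ids)) ids <- sort(unique(c(records$focal_id, from, to)))
  if (!length(ids)) stop("no individuals: pass `ids` for an empty record set")
  keep <- from %in% ids & to %in% ids
  w <- matrix(as.numeric(table(factor(from[keep], levels = ids),
                               factor(to[keep], levels = ids))),
              length(ids), length(ids), dimnames = list(ids, ids))
  associationMatrix(w, rule = rule, troop = troop, ids = ids, directed = TRUE)
}

#' @rdname symmetrize
#' @export
setMethod("symmetrize", "AssociationMatrix", function(m) {
  if (!m@directed) {
    warning("matrix is already undirected; returning it unchanged")
    return(m)
  }
  associationMatrix(m@weights + t(m@weights),
                    rule = sub("_directed$", "_undirected", m@rule),
                    troop = m@troop, ids = m@ids, directed = FALSE)
})

#' @rdname strength
#' @export
setMethod("strength", "AssociationMatrix", function(m, mode = "total") {
  mode <- match.arg(mode, c("total", "out"))
  w <- m@weights
  s <- if (!m@directed) rowSums(w)
       else if (mode == "total") rowSums(w) + colSums(w)
       else rowSums(w)
  stats::setNames(s, m@ids)
})

.asIgraph <- function(m) {
  g <- igraph::graph_from_adjacency_matrix(
    m@weights, mode = if (m@directed) "directed" else "undirected",
    weighted = TRUE, diag = FALSE)
  g
}

#' @rdname betweenness
#' @export
setMethod("betweenness", "AssociationMatrix", function(m) {
  g <- .asIgraph(m)
  d <- 1 / igraph::E(g)$weight  # strong ties are short paths
  b <- igraph::betweenness(g, directed = m@directed, weights = d,
                           normalized = FALSE)
  stats::setNames(as.numeric(b), m@ids)
})

#' Centrality table for one network
#'
#' @param m an [AssociationMatrix-class].
#' @return data.frame with `individual_id`, `rule`, `strength`,
#'   `betweenness`.
#' @export
centralityTable <- function(m) {
  data.frame(individual_id = m@ids, rule = m@rule,
             strength = as.numeric(strength(m)),
             betweenness = as.numeric(betweenness(m)),
             stringsAsFactors = FALSE)
}

#' Spearman rank-correlation screen
#'
#' Rank correlations for every pair of columns, with average-rank ties, the
#' `S` statistic (sum of squared rank differences), and a large-sample
#' t-approximation p-value. A constant column has no defined correlation and
#' is reported as missing.
#'
#' @param df data.frame of numeric columns over the same individuals (at
#'   least 4 rows).
#' @param flagThreshold absolute rho above which a pair is flagged (e.g. for
#'   collinearity concern); default `NA` flags nothing.
#' @return data.frame with `var1`, `var2`, `rho`, `S`, `p`, `flagged`.
#' @export
spearmanScreen <- function(df, flagThreshold = NA) {
  df <- as.data.frame(df)
  if (nrow(df) < 4) stop("at least 4 paired observations are required")
  vars <- names(df)
  out <- list()
  for (i in seq_along(vars)[-length(vars)]) for (j in (i + 1):length(vars)) {
    x <- df[[i]]; y <- df[[j]]
    if (length(unique(x)) < 2 || length(unique(y)) < 2) {
      rho <- S <- p <- NA_real_
    } else {
      ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                      exact = FALSE))
      rho <- unname(ct$estimate); S <- unname(ct$statistic); p <- ct$p.value
    }
    out[[length(out) + 1L]] <- data.frame(
      var1 = vars[i], var2 = vars[j], rho = rho, S = S, p = p,
      flagged = !is.na(flagThreshold) & !is.na(rho) &
        abs(rho) >= flagThreshold,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Build all eight candidate networks for one troop
#'
#' Constructs the two simple-ratio proximity networks (10 m, 5 m chain), the
#' three directed count networks (nearest neighbour, grooming, dominance)
#' and their symmetrized versions.
#'
#' @param scans scan records of one troop (all three proximity rules).
#' @param interactions interaction records of the same troop.
#' @param ids troop roster (defaults to ids observed in the scans).
#' @return Named list of eight [AssociationMatrix-class] objects keyed by
#'   [networkRules()].
#' @export
buildNetworks <- function(scans, interactions, ids = NULL) {
  nnD <- directedCountMatrix(scans, ids = ids)
  grD <- directedCountMatrix(interactions, type = "groom", ids = ids)
  doD <- directedCountMatrix(interactions, type = "dominance", ids = ids)
  list(ten_m = sriMatrix(scans, "ten_m", ids = ids),
       five_m_chain = sriMatrix(scans, "five_m_chain", ids = ids),
       nn_directed = nnD, nn_undirected = symmetrize(nnD),
       groom_directed = grD, groom_undirected = symmetrize(grD),
       dom_directed = doD, dom_undirected = symmetrize(doD))
}

#' Edge-list export/import for association matrices
#'
#' @param m an [AssociationMatrix-class].
#' @param path CSV path.
#' @return `writeEdgeList` returns `path` invisibly; `readEdgeList` an
#'   AssociationMatrix.
#' @export
writeEdgeList <- function(m, path) {
  w <- m@weights
  idx <- which(w > 0, arr.ind = TRUE)
  if (!m@directed) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  df <- data.frame(id_a = m@ids[idx[, 1]], id_b = m@ids[idx[, 2]],
                   weight = w[idx], directed = m@directed,
                   rule = m@rule, troop = m@troop)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @param ids full roster for the matrix (isolated individuals are absent
#'   from the edge list).
#' @export
readEdgeList <- function(path, ids = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(ids)) ids <- sort(unique(c(df$id_a, df$id_b)))
  w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  directed <- isTRUE(df$directed[1])
  for (k in seq_len(nrow(df))) {
    w[df$id_a[k], df$id_b[k]] <- df$weight[k]
    if (!directed) w[df$id_b[k], df$id_a[k]] <- df$weight[k]
  }
  associationMatrix(w, rule = df$rule[1], troop = df$troop[1], ids = ids,
                    directed = directed)
}
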