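# Independent brute-force oracles and tiny fixture builders.
# These deliberately re-derive quantities from first principles (direct
# counting, exhaustive path/order enumeration) without touching the package's
# computation paths or igraph.

# --- simple-ratio index by direct occasion counting -------------------------
# occasions: list of occasions, each a list of character groups
oracleSRI <- function(occasions, a, b) {
  x <- yab <- ya <- yb <- 0
  for (gs in occasions) {
    inA <- vapply(gs, function(g) a %in% g, logical(1))
    inB <- vapply(gs, function(g) b %in% g, logical(1))
    together <- any(vapply(gs, function(g) a %in% g && b %in% g, logical(1)))
    if (together) x <- x + 1
    else if (any(inA) && any(inB)) yab <- yab + 1
    else if (any(inA)) ya <- ya + 1
    else if (any(inB)) yb <- yb + 1
  }
  den <- x + yab + ya + yb
  if (den == 0) NA_real_ else x / den
}

# turn a list of occasions into scan-record rows (one row per group,
# focal = first member)
occasionsToScans <- function(occasions, rule = "ten_m", troop = "J") {
  rows <- list()
  for (t in seq_along(occasions)) for (g in occasions[[t]]) {
    rows[[length(rows) + 1L]] <- data.frame(
      scan_id = sprintf("s%03d_%d", t, length(rows)), troop_id = troop,
      timestamp = t, rule = rule, focal_id = g[1],
      associates = paste(g[-1], collapse = ";"), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

randomOccasions <- function(ids, nOcc) {
  lapply(seq_len(nOcc), function(t) {
    obs <- ids[runif(length(ids)) < 0.8]
    if (!length(obs)) obs <- sample(ids, 1)
    memb <- sample(seq_len(3), length(obs), replace = TRUE)
    unname(split(obs, memb))
  })
}

# --- shortest-path centrality by exhaustive simple-path enumeration --------
allSimplePaths <- function(adj, from, to, directed) {
  n <- nrow(adj)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == to) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    for (u in seq_len(n)) {
      w <- if (directed) adj[v, u] else max(adj[v, u], adj[u, v])
      if (w > 0 && !(u %in% path)) walk(c(path, u))
    }
  }
  walk(from)
  out
}

oracleBetweenness <- function(adj, directed = FALSE) {
  n <- nrow(adj)
  bw <- numeric(n)
  pairs <- if (directed) {
    p <- expand.grid(s = seq_len(n), t = seq_len(n))
    p[p$s != p$t, ]
  } else {
    p <- expand.grid(s = seq_len(n), t = seq_len(n))
    p[p$s < p$t, ]
  }
  plen <- function(path) {
    sum(vapply(seq_len(length(path) - 1), function(i) {
      w <- if (directed) adj[path[i], path[i + 1]]
           else max(adj[path[i], path[i + 1]], adj[path[i + 1], path[i]])
      1 / w
    }, numeric(1)))
  }
  for (r in seq_len(nrow(pairs))) {
    paths <- allSimplePaths(adj, pairs$s[r], pairs$t[r], directed)
    if (!length(paths)) next
    lens <- vapply(paths, plen, numeric(1))
    short <- paths[abs(lens - min(lens)) < 1e-9 * max(1, min(lens))]
    for (p in short) for (v in p[-c(1, length(p))])
      bw[v] <- bw[v] + 1 / length(short)
  }
  bw
}

# --- exhaustive-order enumeration for the diffusion likelihood -------------
permute <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(permute(v[-i]), function(p) c(v[i], p)))
  out
}

# sum over all complete acquisition orders of the order probability
orderProbabilityMass <- function(m, spec, phen, s, betas, discoverer) {
  naive <- setdiff(if (!is.null(m)) indivIds(m) else phen$individual_id,
                   discoverer)
  tot <- 0
  for (ord in permute(naive)) {
    lg <- diffusionLog("t", phen$troop_id[1], discoverer,
                       as.list(ord))
    tot <- tot + exp(diffusionLoglik(lg, m, spec, phen, s = s,
                                     betas = betas))
  }
  tot
}

# --- tiny fixtures ----------------------------------------------------------
toyPhenotypes <- function(n = 4, troop = "J", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(individual_id = paste0(troop, seq_len(n)), troop_id = troop,
             sex = rep(c("female", "male"), length.out = n),
             age = seq(3, 20, length.out = n),
             absolute_rank = sample(n),
             boldness = round(runif(n, 0, 60), 1),
             stringsAsFactors = FALSE)
}

toyNetwork <- function(w, troop = "J", rule = "ten_m",
                       directed = grepl("_directed$", rule)) {
  ids <- rownames(w)
  if (is.null(ids)) {
    ids <- paste0(troop, seq_len(nrow(w)))
    dimnames(w) <- list(ids, ids)
  }
  associationMatrix(w, rule = rule, troop = troop, ids = ids,
                    directed = directed)
}

randomUndirectedWeights <- function(n, density = 0.7, troop = "J") {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < density) w[i, j] <- w[j, i] <- round(runif(1, 0.1, 1), 3)
  dimnames(w) <- list(paste0(troop, seq_len(n)), paste0(troop, seq_len(n)))
  w
}

smallScenario <- function(seed = 1, n1 = 12, n2 = 13, nDiff = 5, scans = 8,
                          ...) {
  simScenario(seed = seed, troopSizes = c(J = n1, L = n2),
              nDiffusionsPerTroop = nDiff,
              scansPerIndividualPerRule = scans, ...)
}
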