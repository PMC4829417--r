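test_that("SRI matches the direct formula on a constructed scan set", {
  # A,B co-grouped in 3 occasions; both seen apart once; A-only twice;
  # B-only twice -> 3 / (3+1+2+2) = 0.375
  occ <- c(lapply(1:3, function(i) list(c("A", "B"))),
           list(list(c("A", "C"), c("B", "D"))),
           lapply(1:2, function(i) list("A")),
           lapply(1:2, function(i) list("B")))
  m <- sriMatrix(occasionsToScans(occ), "ten_m", ids = c("A", "B", "C", "D"))
  expect_equal(weightMatrix(m)["A", "B"], 0.375)
  expect_equal(weightMatrix(m)["A", "B"], oracleSRI(occ, "A", "B"))
  expect_false(isDirected(m))
  expect_equal(diag(weightMatrix(m)), c(A = 0, B = 0, C = 0, D = 0))
})

test_that("SRI attains its bounds and an unobserved id raises an error", {
  occ <- list(list(c("A", "B")), list(c("A", "B", "C")), list(c("C", "D")))
  m <- sriMatrix(occasionsToScans(occ), "ten_m")
  expect_equal(weightMatrix(m)["A", "B"], 1)   # together whenever sampled
  expect_equal(weightMatrix(m)["A", "D"], 0)   # never co-grouped
  expect_error(sriMatrix(occasionsToScans(occ), "ten_m",
                         ids = c("A", "B", "Z")), "Z")
})

test_that("SRI equals the brute-force occasion counter on random scan sets", {
  set.seed(101)
  ids <- paste0("J", 1:6)
  for (rep in 1:15) {
    occ <- randomOccasions(ids, nOcc = 12)
    seen <- unique(unlist(occ))
    m <- sriMatrix(occasionsToScans(occ), "ten_m", ids = sort(seen))
    w <- weightMatrix(m)
    expect_true(all(w >= 0 & w <= 1))
    for (k in 1:4) {
      ab <- sample(sort(seen), 2)
      expect_equal(w[ab[1], ab[2]], oracleSRI(occ, ab[1], ab[2]),
                   tolerance = 1e-12)
    }
  }
})

test_that("chain groups merge within a scan and ignore member-list order", {
  # one scan_id listing an overlapping 5 m chain over two rows
  scans <- data.frame(
    scan_id = c("s1", "s1", "s2"), troop_id = "J", timestamp = c(1, 1, 2),
    rule = "five_m_chain", focal_id = c("A", "B", "C"),
    associates = c("B", "C", ""), stringsAsFactors = FALSE)
  m <- sriMatrix(scans, "five_m_chain")
  expect_equal(weightMatrix(m)["A", "C"], 0.5)  # merged into one group at t1

  # grouping is invariant to the order in which rows list the members
  perm <- scans[c(2, 1, 3), ]
  expect_equal(weightMatrix(sriMatrix(perm, "five_m_chain")),
               weightMatrix(m))
})

test_that("directed count matrices tally actor->recipient events", {
  inter <- data.frame(event_id = paste0("e", 1:3), troop_id = "J",
                      timestamp = 1:3, type = "groom",
                      actor_id = c("A", "A", "B"),
                      recipient_id = c("B", "B", "A"),
                      stringsAsFactors = FALSE)
  m <- directedCountMatrix(inter)
  expect_equal(weightMatrix(m)["A", "B"], 2)
  expect_equal(weightMatrix(m)["B", "A"], 1)
  expect_true(isDirected(m))

  empty <- inter[0, ]
  z <- directedCountMatrix(empty, type = "groom", ids = c("A", "B"),
                           troop = "J")
  expect_equal(sum(weightMatrix(z)), 0)

  nn <- data.frame(scan_id = "s1", troop_id = "J", timestamp = 1,
                   rule = "nearest_neighbour", focal_id = "A",
                   associates = "B", stringsAsFactors = FALSE)
  m <- directedCountMatrix(nn)
  expect_equal(weightMatrix(m)["A", "B"], 1)
  expect_equal(weightMatrix(m)["B", "A"], 0)
  expect_equal(networkRule(m), "nn_directed")
})

test_that("symmetrization sums given and received and is a guarded no-op twice", {
  w <- matrix(c(0, 2, 0, 1, 0, 0, 0, 0, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m <- toyNetwork(w, rule = "groom_directed")
  u <- symmetrize(m)
  expect_equal(weightMatrix(u)["A", "B"], 3)
  expect_equal(weightMatrix(u)["B", "A"], 3)
  expect_equal(networkRule(u), "groom_undirected")
  expect_warning(u2 <- symmetrize(u), "already undirected")
  expect_equal(weightMatrix(u2), weightMatrix(u))

  z <- toyNetwork(matrix(0, 2, 2), rule = "dom_directed")
  expect_equal(sum(weightMatrix(symmetrize(z))), 0)
})

test_that("strength sums weighted edges (in + out for directed matrices)", {
  w <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  w["A", "B"] <- w["B", "A"] <- 0.5
  w["A", "C"] <- w["C", "A"] <- 0.25
  m <- toyNetwork(w)
  expect_equal(strength(m)[["A"]], 0.75)
  expect_equal(strength(m)[["B"]], 0.5)
  expect_equal(strength(toyNetwork(matrix(0, 2, 2)))[[1]], 0)

  wd <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  wd["A", "B"] <- 2; wd["B", "A"] <- 1
  md <- toyNetwork(wd, rule = "groom_directed")
  expect_equal(strength(md)[["A"]], 3)       # in + out
  expect_equal(strength(md, mode = "out")[["A"]], 2)

  # strength is conserved by symmetrization under the in+out convention
  set.seed(7)
  for (i in 1:5) {
    wd <- matrix(rpois(25, 1), 5, 5); diag(wd) <- 0
    dimnames(wd) <- list(paste0("J", 1:5), paste0("J", 1:5))
    md <- toyNetwork(wd, rule = "dom_directed")
    expect_equal(strength(symmetrize(md)), strength(md))
  }
})

test_that("weighted betweenness matches exhaustive shortest-path counting", {
  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  expect_equal(unname(betweenness(toyNetwork(path))), c(0, 1, 0))

  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(unname(betweenness(toyNetwork(tri))), c(0, 0, 0))

  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(unname(betweenness(toyNetwork(star))), c(3, 0, 0, 0))
  expect_equal(unname(betweenness(toyNetwork(star))),
               oracleBetweenness(star))

  set.seed(11)
  for (i in 1:6) {
    n <- sample(5:8, 1)
    w <- randomUndirectedWeights(n, density = 0.5)
    expect_equal(unname(betweenness(toyNetwork(w))), oracleBetweenness(w),
                 tolerance = 1e-9)
  }
  # directed case against the ordered-pair oracle
  set.seed(12)
  wd <- matrix(round(runif(36, 0, 1), 2) * (runif(36) < 0.5), 6, 6)
  diag(wd) <- 0
  dimnames(wd) <- list(paste0("J", 1:6), paste0("J", 1:6))
  expect_equal(unname(betweenness(toyNetwork(wd, rule = "groom_directed"))),
               oracleBetweenness(wd, directed = TRUE), tolerance = 1e-9)
})

test_that("permuting individuals permutes but does not change centralities", {
  set.seed(21)
  w <- randomUndirectedWeights(6)
  m <- toyNetwork(w)
  p <- sample(6)
  mp <- toyNetwork(w[p, p])
  expect_equal(strength(mp)[indivIds(m)], strength(m))
  expect_equal(betweenness(mp)[indivIds(m)], betweenness(m))
})

test_that("spearman screen reproduces hand-computed rank correlations", {
  df <- data.frame(a = 1:6, b = (1:6)^2, c = 6:1)
  sc <- spearmanScreen(df)
  expect_equal(sc$rho[sc$var1 == "a" & sc$var2 == "b"], 1)
  expect_equal(sc$rho[sc$var1 == "a" & sc$var2 == "c"], -1)

  # sum of squared rank differences d = (1,-1,1,-1): S = 4, rho = 0.6
  sc <- spearmanScreen(data.frame(x = 1:4, y = c(2, 1, 4, 3)))
  expect_equal(sc$rho, 0.6)
  expect_equal(unname(sc$S), 4)

  sc <- spearmanScreen(data.frame(x = 1:5, y = rep(1, 5)))
  expect_true(is.na(sc$rho))
  expect_error(spearmanScreen(data.frame(x = 1:3, y = 1:3)), "at least 4")
})

test_that("edge lists round-trip association matrices", {
  set.seed(31)
  w <- randomUndirectedWeights(5)
  m <- toyNetwork(w)
  tf <- withr::local_tempfile(fileext = ".csv")
  writeEdgeList(m, tf)
  back <- readEdgeList(tf, ids = indivIds(m))
  expect_equal(weightMatrix(back), weightMatrix(m))
  expect_equal(networkRule(back), "ten_m")
})
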