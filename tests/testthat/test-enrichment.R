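test_that("size filtering intersects with the universe first", {
  u <- sprintf("g%03d", 1:100)
  db <- GeneSetDb(list(
    small = u[1:9],                      # 9 in universe -> removed
    big = u[1:51],                       # 51 in universe -> removed
    edge10 = u[1:10],                    # inclusive lower bound
    edge50 = u[1:50],                    # inclusive upper bound
    mixed = c(u[1:15], sprintf("x%02d", 1:15))))  # 15 of 30 in universe
  f <- filterGeneSets(db, u)
  expect_setequal(names(f), c("edge10", "edge50", "mixed"))
  expect_length(geneSetList(f)$mixed, 15)
})

test_that("hypergeometric p matches exact tail enumeration", {
  u <- sprintf("g%02d", 1:20)
  h <- hypergeomTest(u[1:5], u, u[3:7])
  expect_equal(h$overlap, 3L)
  expect_equal(h$p_value, 1126 / 15504, tolerance = 1e-12)

  # overlap 0 covers the whole support
  h0 <- hypergeomTest(u[1:5], u, u[10:14])
  expect_equal(h0$p_value, 1)

  # foreground = set = universe: overlap forced
  hall <- hypergeomTest(u, u, u)
  expect_equal(hall$p_value, 1)

  expect_warning(h_empty <- hypergeomTest(character(0), u, u[1:5]),
                 "empty foreground")
  expect_equal(h_empty$p_value, 1)
})

test_that("hypergeometric p equals the enumeration oracle on small universes", {
  set.seed(5)
  for (i in 1:40) {
    N <- sample(5:25, 1)
    u <- sprintf("u%02d", seq_len(N))
    m <- sample(1:N, 1); n <- sample(1:N, 1)
    set <- sample(u, m); fg <- sample(u, n)
    k <- length(intersect(fg, set))
    expect_equal(hypergeomTest(fg, u, set)$p_value,
                 hyperOracle(k, N, m, n), tolerance = 1e-12)
  }
})

test_that("ORA ranks a constructed positive control first", {
  tr <- simulateTruth(simParams(nGenes = 1000L, deFraction = 0.15,
                                seed = 12L))
  db <- makeGeneSets(tr, nResponse = 5L, nBackground = 20L, seed = 13L)
  u <- tr$gene_id
  fdb <- filterGeneSets(db, u)
  # foreground: the truly-DE members of the first response set
  fg <- intersect(geneSetList(fdb)$response_01,
                  tr$gene_id[tr$isDE])
  tab <- runORA(fg, u, fdb)
  expect_equal(tab$set_name[1], "response_01")
  expect_true(all(diff(tab$p_value) >= 0))
  expect_true(all(tab$fdr >= tab$p_value))

  empty <- runORA(fg, u, fdb[integer(0)])
  expect_equal(nrow(empty), 0)
})

test_that("ORA null calibration is at or below nominal", {
  set.seed(10)
  u <- sprintf("g%04d", 1:1000)
  db <- GeneSetDb(setNames(lapply(1:40, function(i) sample(u, 30)),
                           paste0("s", 1:40)))
  fr <- replicate(200, {
    fg <- sample(u, 100)
    mean(runORA(fg, u, db)$p_value < 0.05)
  })
  expect_gt(mean(fr), 0.005)
  expect_lt(mean(fr), 0.06)  # discrete test: conservative at the threshold
})

test_that("CERNO closed forms hold", {
  ranked <- sprintf("g%03d", 1:100)
  top <- cernoTest(ranked, "g001")
  expect_equal(top$statistic, -2 * log(0.01), tolerance = 1e-12)
  expect_equal(top$df, 2L)
  expect_equal(top$p_value, 0.01, tolerance = 1e-12)

  bottom <- cernoTest(ranked, "g100")
  expect_equal(bottom$statistic, 0)
  expect_equal(bottom$p_value, 1)

  expect_message(out <- cernoTest(ranked, "absent"), "skipped")
  expect_equal(out$n_set, 0L)
})

test_that("CERNO singleton identity p = r/N holds across a grid", {
  for (N in c(10L, 100L, 1234L)) {
    ranked <- sprintf("g%05d", seq_len(N))
    for (r in unique(c(1L, 2L, N %/% 2L, N))) {
      expect_equal(cernoTest(ranked, ranked[r])$p_value, r / N,
                   tolerance = 1e-12)
    }
  }
})

test_that("CERNO over a collection applies BH and drops absent sets", {
  ranked <- sprintf("g%03d", 1:200)
  db <- GeneSetDb(list(top = ranked[1:10], mid = ranked[90:110],
                       absent = c("x1", "x2")))
  tab <- runCERNO(ranked, db)
  expect_setequal(tab$set_name, c("top", "mid"))
  expect_equal(tab$set_name[1], "top")
  expect_true(all(tab$fdr >= tab$p_value))
})

test_that("disco score follows the sign and evidence rules", {
  expect_gt(discoScore(2, 1, 0.01, 0.02), 0)
  expect_lt(discoScore(2, -1, 0.01, 0.02), 0)
  expect_equal(discoScore(3, -2, 1, 1), 0)
  expect_equal(discoScore(0, 5, 0.01, 0.01), 0)
  # antisymmetry in one LFC; symmetry under swapping comparisons
  expect_equal(discoScore(1.5, 2, 0.01, 0.3),
               -discoScore(-1.5, 2, 0.01, 0.3))
  expect_equal(discoScore(1.5, 2, 0.01, 0.3),
               discoScore(2, 1.5, 0.3, 0.01))
  expect_warning(s0 <- discoScore(1, 1, 0, 0.5), "clamped")
  expect_true(is.finite(s0))
  expect_error(discoScore(1, 1, -0.1, 0.5), "\\(0, 1\\]")
})
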