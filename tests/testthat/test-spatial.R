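test_that("contact edges follow the any-atom-pair 5 angstrom rule", {
  atoms <- data.frame(
    residue = c(1, 2), x = c(0, 4.9), y = 0, z = 0
  )
  g <- contact_graph_from_coordinates(atoms)
  expect_equal(nrow(g$edges), 1)
  atoms$x[2] <- 5.1
  g2 <- contact_graph_from_coordinates(atoms)
  expect_equal(nrow(g2$edges), 0)
  # single residue -> empty edge set
  g3 <- contact_graph_from_coordinates(data.frame(residue = 1, x = 0, y = 0, z = 0))
  expect_equal(nrow(g3$edges), 0)
  # residue with no atoms -> warning, isolated node
  expect_warning(
    g4 <- contact_graph_from_coordinates(
      data.frame(residue = c(1, 3), x = c(0, 1), y = 0, z = 0),
      n_residues = 3
    ),
    "isolated"
  )
  expect_equal(g4$n_residues, 3)
})

test_that("contact graphs equal the brute-force all-pairs oracle", {
  set.seed(19)
  atoms <- data.frame(
    residue = rep(1:10, each = 3),
    x = rnorm(30, sd = 4), y = rnorm(30, sd = 4), z = rnorm(30, sd = 4)
  )
  g <- contact_graph_from_coordinates(atoms, cutoff = 5)
  # oracle: explicit double loop over residue pairs and their atoms
  oracle <- matrix(0L, 0, 2)
  for (i in 1:9) {
    for (j in (i + 1):10) {
      ai <- as.matrix(atoms[atoms$residue == i, c("x", "y", "z")])
      aj <- as.matrix(atoms[atoms$residue == j, c("x", "y", "z")])
      dmin <- min(sqrt(outer(rowSums(ai^2), rowSums(aj^2), "+") - 2 * ai %*% t(aj)))
      if (dmin <= 5) oracle <- rbind(oracle, c(i, j))
    }
  }
  expect_equal(unname(g$edges), unname(oracle))
  # cutoff monotonicity: edges at 5 are a subset of edges at 7
  g7 <- contact_graph_from_coordinates(atoms, cutoff = 7)
  key <- function(e) paste(e[, 1], e[, 2])
  expect_true(all(key(g$edges) %in% key(g7$edges)))
})

test_that("consensus interface applies the minimum-support rule", {
  sets <- list(c(5, 9), c(5, 9), c(5), c(5, 9), c(5, 9), c(5))
  ri <- consensus_interface(sets, min_support = 4, total_pairs = 6)
  expect_equal(ri$residues, c(5, 9))    # residue 9: 4/6 in, residue 5: 6/6
  expect_equal(unname(ri$support["9"]), 4L)
  ri2 <- consensus_interface(sets, min_support = 5)
  expect_equal(ri2$residues, 5)         # 4/6 support no longer suffices
  # 3/6 excluded
  sets3 <- list(c(2), c(2), c(2), integer(0), integer(0), integer(0))
  expect_equal(consensus_interface(sets3)$residues, integer(0))
  # raising min_support never grows the set
  for (ms in 1:6) {
    expect_true(all(
      consensus_interface(sets, min_support = min(ms + 1, 6))$residues %in%
        consensus_interface(sets, min_support = ms)$residues
    ))
  }
  expect_equal(consensus_interface(list())$residues, integer(0))
})

test_that("linear hotspot caller flags implanted excess and matches the binomial tail", {
  set.seed(47)
  R <- 200
  expected <- rep(1 / R, R)
  expected[50] <- 0.003
  expected <- expected / sum(expected)
  observed <- integer(R)
  observed[50] <- 30
  observed[-50] <- as.vector(rmultinom(1, 70, expected[-50] / sum(expected[-50])))
  calls <- call_linear_hotspots(observed, expected)
  expect_true(calls$called[50])
  p_oracle <- pbinom(29, 100, expected[50] / sum(expected), lower.tail = FALSE)
  expect_equal(calls$p_value[50], p_oracle, tolerance = 1e-12)
  expect_lt(calls$p_value[50], 1e-10)
})

test_that("spatial caller with edgeless graphs reduces to the linear caller", {
  set.seed(23)
  R <- 60
  observed <- as.vector(rmultinom(1, 300, rep(1 / R, R)))
  observed[10] <- observed[10] + 40
  empty_graph <- contact_graph_from_pairs(matrix(integer(0), 0, 2), R)
  lin <- call_linear_hotspots(observed)
  sp <- call_spatial_hotspots(observed, graphs = list(empty_graph))
  called_lin <- lin$residue[lin$called]
  called_sp <- sort(as.integer(unlist(strsplit(sp$residues, ","))))
  expect_equal(called_sp, called_lin)
})

test_that("jointly extreme contact triangles are called though no single residue passes", {
  set.seed(29)
  R <- 120
  base <- rep(1 / R, R)
  observed <- as.vector(rmultinom(1, 240, base))
  tri <- c(40, 41, 90) # mutually in contact in the toy structure
  observed[tri] <- observed[tri] + 5
  g <- contact_graph_from_pairs(rbind(c(40, 41), c(41, 90), c(40, 90)), R)
  lin <- call_linear_hotspots(observed)
  expect_false(any(lin$called[tri]))
  sp <- call_spatial_hotspots(observed, graphs = list(g))
  expect_true(nrow(sp) >= 1)
  hit <- vapply(
    strsplit(sp$residues, ","),
    function(r) any(as.integer(r) %in% tri), logical(1)
  )
  expect_true(any(hit))
})

test_that("high confidence requires support in every graph", {
  # modest per-residue excess: only the aggregated triangle neighborhood is
  # significant, so detection depends on the graph carrying those contacts
  set.seed(53)
  R <- 80
  observed <- as.vector(rmultinom(1, 160, rep(1 / R, R)))
  tri <- c(10, 11, 12)
  observed[tri] <- observed[tri] + 5
  g_tri <- contact_graph_from_pairs(rbind(c(10, 11), c(11, 12), c(10, 12)), R)
  g_empty <- contact_graph_from_pairs(matrix(integer(0), 0, 2), R)
  expect_false(any(call_linear_hotspots(observed)$called[tri]))
  all5 <- call_spatial_hotspots(observed, graphs = rep(list(g_tri), 5))
  expect_true(any(all5$high_confidence))
  only3 <- call_spatial_hotspots(
    observed,
    graphs = c(rep(list(g_tri), 3), rep(list(g_empty), 2))
  )
  top <- only3[which.max(only3$observed), ]
  expect_equal(top$n_graphs, 3)
  expect_false(top$high_confidence)
})

test_that("interface depletion statistics match the exact binomial", {
  R <- 100
  interface <- 1:10
  expected <- rep(1 / R, R)
  observed <- rep(2L, R)
  observed[interface] <- 0L
  res <- interface_depletion_test(observed, interface, expected)
  n <- sum(observed)
  expect_equal(res$expected_in_set, n * 0.1)
  expect_equal(res$fold_depletion, Inf)
  expect_equal(res$p_value, binom.test(0, n, 0.1)$p.value, tolerance = 1e-12)
  # no depletion: fold near 1, p large
  obs_null <- rep(2L, R)
  res2 <- interface_depletion_test(obs_null, interface, expected)
  expect_equal(res2$fold_depletion, 1)
  expect_equal(res2$p_value, 1)
  expect_error(interface_depletion_test(observed, integer(0)), "empty")
})

test_that("conservation contrasts match the rank-sum oracle", {
  scores <- c(sort(runif(8, 0, 0.4)), sort(runif(8, 0.6, 1)))
  hot <- 1:8
  cold <- 9:16
  res <- conservation_contrast(hot, cold, scores)
  expect_equal(res$direction, "hotspots_lower")
  wt <- wilcox.test(scores[hot], scores[cold])
  expect_equal(res$p_value, wt$p.value)
  # disjoint ranges attain the minimal two-sided p for n = 8 vs 8
  expect_equal(res$p_value, 2 / choose(16, 8), tolerance = 1e-9)
  expect_error(conservation_contrast(1:5, 5:10, scores), "overlap")
  # exhaustive permutation oracle on a small example with distinct values
  set.seed(41)
  s2 <- sample(seq(0.01, 0.99, length.out = 12))
  a <- 1:5
  b <- 6:12
  obs_w <- sum(rank(s2)[a]) - length(a) * (length(a) + 1) / 2
  combs <- combn(12, 5)
  ws <- apply(combs, 2, function(idx) sum(rank(s2)[idx]) - 15)
  p_exact <- mean(abs(ws - mean(ws)) >= abs(obs_w - mean(ws)) - 1e-9)
  res2 <- conservation_contrast(a, b, s2)
  expect_equal(res2$p_value, p_exact, tolerance = 1e-9)
})
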