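test_that("DAG construction validates its invariants", {
  expect_error(dag(c("A", "A")), "duplicate")
  expect_error(dag(c("A", "B"), rbind(c("A", "A"))), "self-loop")
  expect_error(dag(c("A", "B", "C"),
                   rbind(c("A", "B"), c("B", "C"), c("C", "A"))), "cycle")
  expect_error(dag(c("A", "B"), rbind(c("A", "Z"))), "unknown")
})

test_that("DAG enumeration matches the brute-force filter for small n", {
  for (n in 1:4) {
    nodes <- LETTERS[seq_len(n)]
    mine <- enumerate_dags(nodes)
    oracle <- brute_force_dags(nodes)
    expect_equal(length(mine), length(oracle))
    key <- function(a) paste(a, collapse = "")
    expect_setequal(vapply(mine, function(g) key(g$amat), ""),
                    vapply(oracle, key, ""))
  }
})

test_that("five-node enumeration hits the known count and larger sets are refused", {
  expect_equal(count_dags(5), 29281)
  expect_error(enumerate_dags(LETTERS[1:6]), "force")
  expect_error(count_dags(7), "force")
})

test_that("d-separation agrees with the path-enumeration oracle on all small DAGs", {
  for (n in 3:4) {
    nodes <- LETTERS[seq_len(n)]
    dags <- enumerate_dags(nodes)
    if (n == 4) {
      set.seed(1)
      dags <- dags[sample(length(dags), 120)]
    }
    for (g in dags) {
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        others <- setdiff(seq_len(n), c(i, j))
        for (zm in 0:(2^length(others) - 1)) {
          z <- others[bitwAnd(zm, bitwShiftL(1L, seq_along(others) - 1L)) > 0]
          expect_equal(d_separated(g, nodes[i], nodes[j], nodes[z]),
                       path_enum_dsep(g$amat, i, j, z))
        }
      }
    }
  }
})

test_that("d-separation handles the textbook chain and collider cases", {
  chain <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  expect_true(d_separated(chain, "A", "C", "B"))
  expect_false(d_separated(chain, "A", "C"))
  coll <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("C", "B")))
  expect_true(d_separated(coll, "A", "C"))
  expect_false(d_separated(coll, "A", "C", "B"))
  expect_error(d_separated(chain, "A", "Z"), "unknown")
  expect_error(d_separated(chain, "A", "A"), "differ")
})

test_that("ground-truth PAG keeps the skeleton and v-structures of a latent-free DAG", {
  set.seed(2)
  for (rep in 1:20) {
    nodes <- LETTERS[1:4]
    g <- enumerate_dags(nodes)[[sample(543, 1)]]
    p <- ground_truth_pag(g)
    expect_equal(p$amat != 0L, (g$amat + t(g$amat)) > 0, ignore_attr = TRUE)
    # every v-structure appears as an arrowhead-arrowhead pair
    for (z in seq_along(nodes)) {
      pa <- which(g$amat[, z] == 1L)
      for (i in pa) for (j in pa) {
        if (i < j && g$amat[i, j] == 0L && g$amat[j, i] == 0L) {
          expect_equal(p$amat[i, z], 2L)
          expect_equal(p$amat[j, z], 2L)
        }
      }
    }
  }
})

test_that("ground-truth PAG orients the canonical small structures", {
  two <- ground_truth_pag(dag(c("A", "B"), rbind(c("A", "B"))))
  expect_equal(two$amat["A", "B"], 1L)  # A o-o B
  expect_equal(two$amat["B", "A"], 1L)

  coll <- ground_truth_pag(dag(c("A", "B", "C"), rbind(c("A", "B"), c("C", "B"))))
  expect_equal(coll$amat["A", "B"], 2L)  # arrowheads at B
  expect_equal(coll$amat["C", "B"], 2L)
  expect_equal(coll$amat["B", "A"], 1L)  # circles at A and C
  expect_equal(coll$amat["B", "C"], 1L)

  # collider with a descendant: B --> D becomes invariant (tail at B)
  g <- dag(c("A", "B", "C", "D"), rbind(c("A", "B"), c("C", "B"), c("B", "D")))
  p <- ground_truth_pag(g)
  expect_equal(p$amat["D", "B"], 3L)
  expect_equal(p$amat["B", "D"], 2L)
})

test_that("marginalizing a latent confounder leaves an unorientable edge set", {
  # L -> A, L -> B with L latent: A and B stay adjacent, both ends circles
  g <- dag(c("L", "A", "B"), rbind(c("L", "A"), c("L", "B")))
  p <- ground_truth_pag(g, latent = "L")
  expect_equal(sort(p$nodes), c("A", "B"))
  expect_equal(p$amat["A", "B"], 1L)
  expect_equal(p$amat["B", "A"], 1L)
})

test_that("PAG accuracy counts endpoint marks over the edge-set union", {
  gt <- ground_truth_pag(dag(c("A", "B", "C"), rbind(c("A", "B"), c("C", "B"))))
  expect_equal(pag_accuracy(gt, gt), 1)
  empty <- pag(gt$nodes)
  expect_equal(pag_accuracy(empty, gt), 0)
  expect_equal(pag_accuracy(empty, empty), 1)

  # all-circle skeleton against an all-tail truth: marks all wrong,
  # skeleton precision/recall still perfect
  truth <- pag(c("X", "Y"))
  truth <- pag_set_edge(truth, "X", "Y", "tail", "tail")
  est <- pag(c("X", "Y"))
  est <- pag_set_edge(est, "X", "Y", "circle", "circle")
  expect_equal(pag_accuracy(est, truth), 0)
  expect_equal(unname(skeleton_precision_recall(est, truth)), c(1, 1))

  # symmetry and a partial-credit case
  half <- pag_set_edge(pag(c("X", "Y")), "X", "Y", "tail", "circle")
  expect_equal(pag_accuracy(half, truth), pag_accuracy(truth, half))
  expect_equal(pag_accuracy(half, truth), 0.5)
  expect_error(pag_accuracy(truth, pag(c("A", "B"))), "node set")
})

test_that("skeleton precision and recall follow the counting definition", {
  nodes <- LETTERS[1:6]
  truth <- pag(nodes)
  true_edges <- rbind(c(1, 2), c(1, 3), c(2, 3), c(2, 4), c(3, 4),
                      c(3, 5), c(4, 5), c(4, 6), c(5, 6), c(1, 6))
  for (r in seq_len(nrow(true_edges))) {
    truth <- pag_set_edge(truth, nodes[true_edges[r, 1]], nodes[true_edges[r, 2]])
  }
  # 5 inferred, 4 of them true, truth has 10 edges -> (0.8, 0.4)
  est <- pag(nodes)
  for (r in 1:4) est <- pag_set_edge(est, nodes[true_edges[r, 1]], nodes[true_edges[r, 2]])
  est <- pag_set_edge(est, nodes[2], nodes[6])  # spurious
  pr <- skeleton_precision_recall(est, truth)
  expect_equal(unname(pr), c(0.8, 0.4))
  # vacuous precision with an empty estimate
  pr0 <- skeleton_precision_recall(pag(nodes), truth)
  expect_equal(unname(pr0), c(1, 0))
  # perfect recovery
  expect_equal(unname(skeleton_precision_recall(truth, truth)), c(1, 1))
})
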