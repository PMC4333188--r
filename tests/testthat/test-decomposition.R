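test_that("subnet density follows 2m/(n(n-1))", {
  k5 <- toy_clique(letters[1:5])
  expect_identical(subnet_density(k5, letters[1:5]), 1)

  # 5 nodes, 7 induced edges -> 0.7
  g <- toy_net(c("a", "a", "a", "a", "b", "b", "c"),
               c("b", "c", "d", "e", "c", "d", "d"))
  expect_equal(subnet_density(g, letters[1:5]), 0.7)

  expect_error(subnet_density(k5, "a"), "fewer than 2")
  expect_error(subnet_density(k5, c("a", "zz")), "not in the network")
})

test_that("subnet density agrees with an exhaustive pair-scan oracle", {
  withr::local_seed(11)
  for (rep in 1:25) {
    rg <- rand_adj_graph(sample(5:14, 1), runif(1, 0.2, 0.9))
    members <- sample(rg$nodes, sample(2:length(rg$nodes), 1))
    expect_equal(subnet_density(rg$graph, members),
                 oracle_density(rg$adj, members))
  }
})

test_that("find_k_clique locates seeds and reports absence correctly", {
  # unique 4-clique plus a pendant node
  g <- toy_net(c("a", "a", "a", "b", "b", "c", "d"),
               c("b", "c", "d", "c", "d", "d", "e"))
  expect_identical(find_k_clique(g, letters[1:5], 4), letters[1:4])

  # 5-cycle is triangle-free
  cyc <- toy_net(c("a", "b", "c", "d", "e"), c("b", "c", "d", "e", "a"))
  expect_null(find_k_clique(cyc, letters[1:5], 3))

  expect_error(find_k_clique(g, letters[1:5], 1), "integer >= 2")
  # candidates restricted: clique search never leaves the candidate set
  expect_null(find_k_clique(g, c("a", "b", "e"), 3))
})

test_that("random seed mode samples verified cliques reproducibly", {
  withr::local_seed(3)
  rg <- rand_adj_graph(12, 0.6)
  for (rep in 1:10) {
    cl <- find_k_clique(rg$graph, rg$nodes, 3, mode = "random")
    expect_true(oracle_subset_is_clique(rg$adj, cl))
  }
  a <- withr::with_seed(9, find_k_clique(rg$graph, rg$nodes, 3, mode = "random"))
  b <- withr::with_seed(9, find_k_clique(rg$graph, rg$nodes, 3, mode = "random"))
  expect_identical(a, b)
})

test_that("greedy extension follows the accept-if-strictly-denser rule", {
  # fifth node adjacent to all of the K4: extension keeps completeness
  g1 <- toy_clique(letters[1:5])
  sn <- greedy_extend(g1, letters[1:4], letters[1:5], lambda = 0.7)
  expect_identical(sn$members, letters[1:5])
  expect_identical(sn$density, 1)

  # fifth node adjacent to one member: density would be exactly 0.7, rejected
  g2 <- toy_net(c("a", "a", "a", "b", "b", "c", "a"),
                c("b", "c", "d", "c", "d", "d", "e"))
  sn2 <- greedy_extend(g2, letters[1:4], letters[1:5], lambda = 0.7)
  expect_identical(sn2$members, letters[1:4])
  expect_identical(sn2$density, 1)

  # nothing to add
  sn3 <- greedy_extend(g2, letters[1:4], letters[1:4], lambda = 0.7)
  expect_identical(sn3$members, letters[1:4])

  expect_error(greedy_extend(g2, c("a", "b", "e"), letters[1:5], 0.7),
               "not a clique")
  expect_error(greedy_extend(g2, letters[1:4], letters[1:5], 0), "in \\(0, 1\\]")
})

test_that("decompose_complex prunes, repeats, and abandons the residue", {
  # complete K5 complex: consumed in a single pass
  k5 <- toy_clique(letters[1:5])
  d1 <- decompose_complex(k5, letters[1:5], k = 4, lambda = 0.7)
  expect_length(d1, 1L)
  expect_identical(d1[[1]]$members, letters[1:5])
  expect_identical(attr(d1, "abandoned"), character(0))

  # two K4s joined by one bridge edge: the bridge neighbour is rejected
  # (K4 + 1-edge node has density exactly 0.7), giving two clean K4 subnets
  g2 <- toy_net(c("a", "a", "a", "b", "b", "c", "d", "e", "e", "e", "f", "f", "g"),
                c("b", "c", "d", "c", "d", "d", "e", "f", "g", "h", "g", "h", "h"))
  d2 <- decompose_complex(g2, letters[1:8], k = 4, lambda = 0.7)
  expect_length(d2, 2L)
  expect_identical(d2[[1]]$members, letters[1:4])
  expect_identical(d2[[2]]$members, letters[5:8])
  expect_identical(attr(d2, "abandoned"), character(0))

  # 6-cycle holds no 4-clique: everything is abandoned
  cyc <- toy_net(letters[1:6], letters[c(2:6, 1)])
  d3 <- decompose_complex(cyc, letters[1:6], k = 4, lambda = 0.7)
  expect_length(d3, 0L)
  expect_identical(attr(d3, "abandoned"), letters[1:6])

  # members absent from the network are ignored with a warning
  expect_warning(d4 <- decompose_complex(k5, c(letters[1:5], "zz"), k = 4),
                 "absent from the network")
  expect_identical(d4[[1]]$members, letters[1:5])
})

test_that("decomposition invariants hold on random graphs", {
  withr::local_seed(99)
  for (rep in 1:60) {
    n <- sample(6:14, 1)
    rg <- rand_adj_graph(n, runif(1, 0.3, 0.8))
    k <- sample(2:4, 1)
    lambda <- runif(1, 0.5, 0.9)
    d <- decompose_complex(rg$graph, rg$nodes, k = k, lambda = lambda)
    members <- lapply(d, `[[`, "members")
    all_members <- unlist(members)
    # pairwise node-disjoint, union within the complex
    expect_identical(anyDuplicated(all_members), 0L)
    expect_true(all(all_members %in% rg$nodes))
    for (sn in d) {
      expect_gte(sn$n, k)
      expect_gt(sn$density, lambda)  # strict bound
      expect_equal(sn$density, oracle_density(rg$adj, sn$members))
    }
    # abandoned residue contains no k-clique
    resid <- attr(d, "abandoned")
    if (length(resid) >= k) {
      expect_false(oracle_has_k_clique(rg$adj[resid, resid, drop = FALSE], k))
    }
    # deterministic mode: identical reruns
    d2 <- decompose_complex(rg$graph, rg$nodes, k = k, lambda = lambda)
    expect_identical(d, d2)
  }
})
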