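test_that("edge lists are read with set semantics and parse errors name the line", {
  p <- write_tmp_lines(c("# comment", "a b", "b\tc", "a b"))
  expect_message(net <- read_edge_list(p), "1 duplicate")
  expect_equal(net$nodes, c("a", "b", "c"))
  expect_equal(nrow(net$edges), 2L)

  sif <- write_tmp_lines(c("a\tactivates\tb", "b\tinhibits\tc", "c\tbinds\td"))
  net2 <- read_edge_list(sif, dialect = "sif")
  expect_equal(net2$edges$sign[net2$edges$from == "a"], "positive")
  expect_equal(net2$edges$sign[net2$edges$from == "b"], "negative")
  expect_equal(net2$edges$sign[net2$edges$from == "c"], "unknown")

  bad <- write_tmp_lines(c("a b", "oops"))
  expect_error(read_edge_list(bad), "line 2")
  empty <- write_tmp_lines("# only a comment")
  expect_error(read_edge_list(empty), "no edges")
  expect_error(read_edge_list(tempfile()), "not found")
})

test_that("edge-list round trip preserves the network in both dialects", {
  net <- directed_network(cbind(c("a", "b", "c"), c("b", "c", "a")),
                          sign = c("positive", "negative", "unknown"))
  for (dialect in c("two_column", "sif")) {
    p <- withr::local_tempfile()
    write_edge_list(net, p, dialect = dialect, header = "seed: 1")
    back <- read_edge_list(p, dialect = dialect)
    expect_equal(back$nodes, net$nodes)
    expect_equal(back$edges$from, net$edges$from)
    expect_equal(back$edges$to, net$edges$to)
    if (dialect == "sif") expect_equal(back$edges$sign, net$edges$sign)
  }
})

test_that("in-degrees count distinct inputs, including self-loops", {
  t1 <- toy_network_t1()
  expect_equal(in_degrees(t1),
               c(a = 0L, b = 2L, c = 1L, d = 1L, e = 1L))
  loop <- directed_network(cbind("x", "x"), nodes = c("x", "y"))
  expect_equal(in_degrees(loop), c(x = 1L, y = 0L))
})

test_that("feedback-loop membership covers cycles and self-loops", {
  expect_equal(fbl_nodes(toy_network_t1()), c("b", "c"))
  dag <- directed_network(cbind(c("a", "b"), c("b", "c")))
  expect_equal(fbl_nodes(dag), character())
  loop <- directed_network(cbind("x", "x"))
  expect_equal(fbl_nodes(loop), "x")
  expect_equal(fbl_nodes(directed_network(character())), character())
})

test_that("reachability follows paths and includes v only when on a cycle through itself", {
  t1 <- toy_network_t1()
  expect_equal(reachable(t1, "a", "upstream"), character())
  expect_equal(reachable(t1, "a", "downstream"), c("b", "c", "d", "e"))
  # b lies on the b<->c loop, which is an upstream path of b starting at b
  expect_equal(reachable(t1, "b", "upstream"), c("a", "b", "c"))
  expect_equal(reachable(t1, "e", "downstream"), character())
  expect_error(reachable(t1, "zz", "upstream"), "unknown node")
})

test_that("toy fixture classification matches the hand-enumerated oracle", {
  cls <- classify_nodes(toy_network_t1())
  expect_equal(cls$node[cls$is_nfu], "a")
  expect_equal(cls$node[cls$is_nfd], c("d", "e"))
  expect_equal(cls$node[!cls$is_nfu & !cls$is_nfd], c("b", "c"))
  expect_equal(cls$node[cls$is_source], "a")
  expect_equal(cls$node[cls$on_fbl], c("b", "c"))
})

test_that("in an acyclic or empty network every node is both NFU and NFD", {
  dag <- generate_random_network(9, 16, acyclic = TRUE, seed = 5)
  cls <- classify_nodes(dag)
  expect_true(all(cls$is_nfu))
  expect_true(all(cls$is_nfd))
  expect_equal(sum(cls$on_fbl), 0L)

  bare <- directed_network(character(), nodes = c("a", "b"))
  cls2 <- classify_nodes(bare)
  expect_true(all(cls2$is_source & cls2$is_nfu & cls2$is_nfd))
  # the brute-force oracle agrees on the degenerate case
  cls2b <- classify_nodes_bruteforce(bare)
  expect_equal(as.data.frame(cls2), as.data.frame(cls2b))
})

test_that("cycle-involved nodes are never NFU or NFD", {
  for (seed in 1:25) {
    net <- generate_random_network(8, 14, seed = seed)
    cls <- classify_nodes(net)
    expect_false(any(cls$on_fbl & (cls$is_nfu | cls$is_nfd)))
  }
})

test_that("fast classification equals the literal-definition oracle on random networks", {
  for (seed in 1:50) {
    net <- generate_random_network(8, 14, seed = seed,
                                   allow_self_loops = seed %% 5 == 0)
    expect_equal(as.data.frame(classify_nodes(net)),
                 as.data.frame(classify_nodes_bruteforce(net)),
                 info = paste("seed", seed))
  }
  expect_error(classify_nodes_bruteforce(generate_random_network(13, 20, seed = 1)),
               "too large")
})

test_that("classification is equivariant under node relabeling", {
  net <- generate_random_network(8, 14, seed = 11)
  relabel <- stats::setNames(sprintf("g%02d", sample(8)), net$nodes)
  net2 <- directed_network(cbind(unname(relabel[net$edges$from]),
                                 unname(relabel[net$edges$to])),
                           nodes = unname(relabel))
  cls1 <- classify_nodes(net)
  cls2 <- classify_nodes(net2)
  m <- match(relabel[cls1$node], cls2$node)
  for (col in c("is_source", "on_fbl", "is_nfu", "is_nfd")) {
    expect_equal(cls1[[col]], cls2[[col]][m], info = col)
  }
})

test_that("classification TSV uses 1/0 cells under the documented header", {
  p <- withr::local_tempfile()
  write_classification(classify_nodes(toy_network_t1()), p, header = "toy")
  lines <- readLines(p)
  expect_equal(lines[1], "# toy")
  expect_equal(lines[2], "node\tis_source\ton_fbl\tis_nfu\tis_nfd")
  expect_equal(lines[3], "a\t1\t0\t1\t0")
  expect_equal(lines[7], "e\t0\t0\t0\t1")
})
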