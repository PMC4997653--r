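test_that("boolean_network validates truth tables against the wiring", {
  net <- directed_network(cbind(c("a", "b"), c("b", "a")))
  expect_error(boolean_network(net, list(a = list(inputs = "b", outputs = c(1, 0)))),
               "missing update function")
  expect_error(boolean_network(net, list(
    a = list(inputs = "b", outputs = c(1, 0, 0, 1)),
    b = list(inputs = "a", outputs = c(1, 0)))), "2\\^1")
  expect_error(boolean_network(net, list(
    a = list(inputs = "a", outputs = c(1, 0)),
    b = list(inputs = "a", outputs = c(1, 0)))), "do not match")
  # a string truth table is accepted
  bn <- boolean_network(net, list(
    a = list(inputs = "b", outputs = "10"),
    b = list(inputs = "a", outputs = "10")))
  expect_equal(bn$functions[["a"]]$outputs, c(1L, 0L))
})

test_that("a synchronous step follows the truth tables and holds sources", {
  bn <- mutual_negation_bn()
  expect_equal(unname(step_state(bn, c(0, 0))), c(1L, 1L))
  expect_equal(unname(step_state(bn, c(0, 1))), c(0L, 1L))
  expect_error(step_state(bn, c(0, 1, 0)), "length")

  one_src <- boolean_network(directed_network(character(), nodes = "s"), list())
  expect_equal(unname(step_state(one_src, 1L)), 1L)

  # source coordinates never change along any trajectory
  net <- generate_random_network(6, 9, seed = 3)
  bn2 <- random_boolean_functions(net, seed = 4)
  src <- bn2$nodes[bn2$is_source]
  tr <- trajectory(bn2, rep(1L, 6), 20)
  for (v in src) expect_true(all(tr[, v] == tr[1, v]))
})

test_that("attractor detection reports transient, period, and a closed cycle", {
  bn <- mutual_negation_bn()
  a1 <- find_attractor(bn, c(0, 1))
  expect_equal(a1$transient, 0L)
  expect_equal(a1$period, 1L)
  expect_equal(unname(a1$states[1, ]), c(0L, 1L))

  a2 <- find_attractor(bn, c(0, 0))
  expect_equal(a2$period, 2L)
  expect_equal(a2$transient, 0L)
  expect_equal(apply(a2$states, 1, paste, collapse = ""), c("00", "11"))

  # closure invariant on random instances: step maps each cycle state to the next
  for (seed in 1:20) {
    net <- generate_random_network(7, 12, seed = seed)
    bnr <- random_boolean_functions(net, seed = seed + 1000)
    att <- find_attractor(bnr, as.integer(intToBits(seed))[1:7])
    p <- att$period
    for (i in seq_len(p)) {
      nxt <- step_state(bnr, att$states[i, ])
      expect_equal(unname(nxt), unname(att$states[(i %% p) + 1L, ]),
                   info = paste("seed", seed))
    }
  }
})

test_that("attractor equivalence is rotation-invariant and period-aware", {
  bn <- mutual_negation_bn()
  a <- find_attractor(bn, c(0, 0))   # cycle 00 -> 11
  b <- find_attractor(bn, c(1, 1))   # same cycle entered at 11
  fp <- find_attractor(bn, c(0, 1))
  expect_true(attractors_equivalent(a, a))
  expect_true(attractors_equivalent(a, b))
  expect_true(attractors_equivalent(b, a))
  expect_false(attractors_equivalent(a, fp))

  # transitivity over the attractors of random networks
  for (seed in 1:10) {
    bnr <- random_boolean_functions(generate_random_network(6, 10, seed = seed),
                                    seed = seed)
    atts <- attractors_exhaustive(bnr)$attractors
    for (x in atts) for (y in atts) for (z in atts) {
      if (attractors_equivalent(x, y) && attractors_equivalent(y, z)) {
        expect_true(attractors_equivalent(x, z))
      }
    }
  }
})

test_that("frozenness means one constant value per node across the cycle", {
  bn <- mutual_negation_bn()
  fp <- find_attractor(bn, c(0, 1))
  expect_true(is_frozen(fp, c("a", "b")))
  cyc <- find_attractor(bn, c(0, 0))
  expect_false(is_frozen(cyc, "a"))
  expect_true(is_frozen(cyc, character()))
  expect_error(is_frozen(cyc, "zz"), "unknown node")
})

test_that("exhaustive enumeration partitions the state space", {
  one_src <- boolean_network(directed_network(character(), nodes = "s"), list())
  ex <- attractors_exhaustive(one_src)
  expect_equal(length(ex$attractors), 2L)
  expect_equal(sort(ex$basin_sizes), c(1L, 1L))

  ex2 <- attractors_exhaustive(mutual_negation_bn())
  expect_equal(length(ex2$attractors), 3L)
  expect_equal(sum(ex2$basin_sizes), 4L)
  periods <- sort(vapply(ex2$attractors, `[[`, integer(1), "period"))
  expect_equal(periods, c(1L, 1L, 2L))

  for (seed in 1:10) {
    bnr <- random_boolean_functions(generate_random_network(7, 12, seed = seed),
                                    seed = seed + 1)
    ex3 <- attractors_exhaustive(bnr)
    expect_equal(sum(ex3$basin_sizes), 2L^7)
    # the transition-table route agrees with stepwise attractor search
    for (code in c(0L, 37L, 101L)) {
      s0 <- bitwAnd(bitwShiftR(code, 7 - seq_len(7)), 1L)
      att <- find_attractor(bnr, s0)
      expect_true(any(vapply(ex3$attractors, attractors_equivalent,
                             logical(1), att)))
    }
  }
  big <- random_boolean_functions(generate_random_network(25, 40, seed = 1),
                                  seed = 2)
  expect_error(attractors_exhaustive(big), "sample initial states")
})

test_that("boolean function files round-trip bit-exactly", {
  net <- generate_random_network(6, 10, seed = 8)
  bn <- random_boolean_functions(net, seed = 9)
  p <- withr::local_tempfile()
  write_boolean_functions(bn, p)
  bn2 <- read_boolean_functions(p, net)
  for (v in bn$nodes[!bn$is_source]) {
    expect_equal(bn2$functions[[v]]$inputs, bn$functions[[v]]$inputs)
    expect_equal(bn2$functions[[v]]$outputs, bn$functions[[v]]$outputs)
  }
  expect_error(read_boolean_functions(tempfile(), net), "not found")
})
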