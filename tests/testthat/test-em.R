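test_that("a linear chain has exactly one mode through all reactions", {
  for (k in c(1L, 3L, 6L)) {
    inst <- gen_linear_chain(k)
    ems <- enumerate_ems(inst$network)
    expect_equal(n_modes(ems), 1L)
    expect_setequal(em_supports(ems)[[1]], reaction_ids(inst$network))
    expect_equal(unname(participation(ems)),
                 rep(1L, length(inst$network$reactions)))
  }
})

test_that("parallel routes multiply: a diamond has two modes", {
  net <- metabolic_network(list(
    reaction("in", c(Ext1 = -1, A = 1)),
    reaction("r2", c(A = -1, B = 1)),
    reaction("r3", c(A = -1, B = 1)),
    reaction("out", c(B = -1, Ext2 = 1))),
    compounds = data.frame(id = c("Ext1", "A", "B", "Ext2"),
                           role = c("external", "internal", "internal", "external")))
  ems <- enumerate_ems(net)
  expect_equal(n_modes(ems), 2L)
  sup <- set_list_key(em_supports(ems))
  expect_equal(sup, set_list_key(list(c("in", "r2", "out"),
                                      c("in", "r3", "out"))))
})

test_that("layered branching networks have prod(layers) modes", {
  for (layers in list(c(2), c(2, 3), c(1, 1, 1), c(3, 2, 2))) {
    inst <- gen_branching(layers)
    ems <- enumerate_ems(inst$network)
    expect_equal(n_modes(ems), inst$answer$em_count)
  }
})

test_that("reversible reactions yield sign-canonical modes, no split cycles", {
  net <- metabolic_network(list(
    reaction("x1", c(A = -1), reversible = TRUE),   # exchange, both ways
    reaction("r", c(A = -1, B = 1), reversible = TRUE),
    reaction("x2", c(B = -1))),
    compounds = data.frame(id = c("A", "B"), role = c("internal", "internal")))
  ems <- enumerate_ems(net)
  # single mode: x1 imports A (negative exchange), r converts, x2 exports
  expect_equal(n_modes(ems), 1L)
  v <- ems$coef[, 1]
  expect_equal(unname(v[c("x1", "r", "x2")]), c(-1, 1, 1))
})

test_that("enumeration matches the brute-force subset oracle", {
  for (seed in 1:25) {
    net <- random_small_network(seed)
    mine <- enumerate_ems(net)$coef
    oracle <- brute_force_ems(net)
    expect_equal(em_key_set(mine), em_key_set(oracle),
                 label = sprintf("seed %d", seed))
  }
})

test_that("each mode balances internal compounds exactly", {
  for (seed in c(2, 9, 17)) {
    net <- random_small_network(seed)
    ems <- enumerate_ems(net)
    S <- stoich_matrix(net)    # integer stoichiometry in these fixtures
    if (n_modes(ems) > 0)
      expect_true(all(S %*% ems$coef == 0))   # exact, not a tolerance
    irr <- !vapply(net$reactions, `[[`, logical(1), "reversible")
    expect_true(all(ems$coef[irr, ] >= 0))
  }
})

test_that("participation totals equal summed support sizes", {
  mabp <- make_mini_abp_fixture()
  ems <- enumerate_ems(mabp$network)
  expect_equal(sum(participation(ems)), sum(lengths(em_supports(ems))))
})

test_that("the mini pathway fixture enumerates to its hand answer", {
  mabp <- make_mini_abp_fixture()
  ems <- enumerate_ems(mabp$network)
  expect_equal(n_modes(ems), mabp$answer$em_count)
  expect_equal(set_list_key(em_supports(ems)),
               set_list_key(mabp$answer$em_supports))
})

test_that("mode classification follows net external production", {
  mabp <- make_mini_abp_fixture()
  ems <- classify_ems(enumerate_ems(mabp$network), mabp$class_map)
  counts <- table(ems$class_label)
  expect_equal(unname(counts[["anthocyanins"]]), 3L)
  expect_equal(unname(counts[["flavonols1"]]), 1L)
  expect_equal(unname(counts[["flavonols2"]]), 2L)

  # a futile cycle has empty net production and lands in "others"
  cyc <- metabolic_network(list(
    reaction("f", c(A = -1, B = 1)),
    reaction("b", c(B = -1, A = 1))),
    compounds = data.frame(id = c("A", "B"), role = "internal"))
  ems2 <- classify_ems(enumerate_ems(cyc),
                       product_class_map(list(anthocyanins = "nothing")))
  expect_equal(n_modes(ems2), 1L)
  expect_equal(ems2$class_label, "others")
})

test_that("a mixed-class mode is labelled by priority and flagged", {
  net <- metabolic_network(list(
    reaction("in", c(S = -1, A = 1)),
    reaction("split", c(A = -1, P1 = 1, P2 = 1))),
    compounds = data.frame(id = c("S", "A", "P1", "P2"),
                           role = c("external", "internal", "external", "external")))
  cmap <- product_class_map(list(anthocyanins = "P1", benzenoids = "P2"),
                            priority = c("anthocyanins", "benzenoids"))
  expect_warning(ems <- classify_ems(enumerate_ems(net), cmap), "several classes")
  expect_equal(ems$class_label, "anthocyanins")
  expect_equal(attr(ems, "ambiguous"), 1L)
})

test_that("EM matrix export and import round trip", {
  mabp <- make_mini_abp_fixture()
  ems <- enumerate_ems(mabp$network)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ems(ems, path)
  back <- read_ems(path, mabp$network)
  expect_equal(unname(back$coef), unname(ems$coef))
})

test_that("synthetic pathway stand-in: participation mirrors pathway position", {
  sf <- synthetic_flavonoid_network()
  ems <- enumerate_ems(sf$network)
  p <- participation(ems)
  # early reactions (CHS/CHI analogues) carry every naringenin-derived mode;
  # the terminal glucosylations only carry their own anthocyanin branch
  flavonoid_modes <- sum(p["N-C-S-RXN"])
  expect_gt(p[["N-C-S-RXN"]], p[["PELUDP-RXN"]] + p[["RXN1F-775"]])
  expect_equal(p[["APIGNAR-RXN"]], p[["N-C-S-RXN"]])
  anth <- select_target_ems(ems, sf$objective)
  expect_equal(p[["PELUDP-RXN"]] + p[["RXN1F-775"]], n_modes(anth))
})
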