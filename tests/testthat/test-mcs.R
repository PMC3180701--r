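test_that("target selection picks the modes containing an objective", {
  mabp <- make_mini_abp_fixture()
  ems <- enumerate_ems(mabp$network)
  tg <- select_target_ems(ems, mabp$answer$objective)
  expect_equal(set_list_key(em_supports(tg)),
               set_list_key(mabp$answer$target_em_supports))
  # objectives in no mode select nothing; unknown objectives error
  none <- select_target_ems(ems, "mFLS-pg")
  expect_equal(n_modes(select_target_ems(none, "m3UGT-pg")), 0L)
  expect_error(select_target_ems(ems, "no-such-rxn"), "not in network")
})

test_that("one mode with a two-reaction support has two singleton cuts", {
  mcs <- enumerate_mcs(list(c("a", "b")))
  expect_equal(set_list_key(mcs$sets), set_list_key(list("a", "b")))
  expect_equal(mcs$size, c(1L, 1L))
})

test_that("cut sets match brute-force minimal hitting sets", {
  for (seed in 1:25) {
    set.seed(seed)
    n_cand <- sample(4:10, 1)
    candidates <- sprintf("c%02d", seq_len(n_cand))
    supports <- lapply(seq_len(sample(2:6, 1)), function(i)
      sample(candidates, sample(1:4, 1)))
    mine <- enumerate_mcs(supports, candidates = candidates)
    oracle <- brute_force_hitting_sets(supports, candidates)
    expect_equal(set_list_key(mine$sets), set_list_key(oracle),
                 label = sprintf("seed %d", seed))
  }
})

test_that("cut sets hit every target and are support-minimal antichains", {
  mabp <- make_mini_abp_fixture()
  ems <- enumerate_ems(mabp$network)
  tg <- select_target_ems(ems, mabp$answer$objective)
  mcs <- enumerate_mcs(tg)
  supports <- em_supports(tg)
  for (i in seq_along(mcs$sets)) {
    cut <- mcs$sets[[i]]
    expect_true(all(vapply(supports, function(s)
      length(intersect(s, cut)) > 0, logical(1))))
    for (r in cut) {    # minimality: dropping any reaction misses a target
      expect_true(any(vapply(supports, function(s)
        length(intersect(s, setdiff(cut, r))) == 0, logical(1))))
    }
    for (j in seq_along(mcs$sets)) {   # antichain
      if (i != j) expect_false(all(mcs$sets[[j]] %in% cut))
    }
  }
})

test_that("blocking a cut removes every objective mode from the network", {
  mabp <- make_mini_abp_fixture()
  ems <- enumerate_ems(mabp$network)
  tg <- select_target_ems(ems, mabp$answer$objective)
  mcs <- enumerate_mcs(tg)
  for (cut in mcs$sets) {
    reduced <- drop_reactions(mabp$network, cut)
    red_ems <- enumerate_ems(reduced)
    obj_left <- intersect(mabp$answer$objective, reaction_ids(reduced))
    if (length(obj_left) && n_modes(red_ems) > 0)
      expect_true(all(red_ems$coef[obj_left, ] == 0))
  }
})

test_that("blocking only one parallel branch is not a cut", {
  mabp <- make_mini_abp_fixture()
  ems <- enumerate_ems(mabp$network)
  tg <- select_target_ems(ems, mabp$answer$objective)
  supports <- em_supports(tg)
  # the pelargonidin-branch reductase alone leaves the cyanidin modes alive
  expect_true(any(vapply(supports, function(s)
    !"mDFR-pg" %in% s, logical(1))))
  mcs <- enumerate_mcs(tg)
  expect_false(any(vapply(mcs$sets, identical, logical(1), "mDFR-pg")))
})

test_that("mini fixture cut sets equal the hand enumeration", {
  mabp <- make_mini_abp_fixture()
  ems <- enumerate_ems(mabp$network)
  tg <- select_target_ems(ems, mabp$answer$objective)
  mcs <- enumerate_mcs(tg)
  expect_equal(lapply(mcs$sets, sort), mabp$answer$planted_mcs)
})

test_that("uncuttable modes raise an error naming the mode", {
  expect_error(enumerate_mcs(list(c("a", "b"), c("x", "y")),
                             candidates = c("a", "b")),
               "uncuttable.*EM2")
})

test_that("unaffected counts are disjointness counts over the universe", {
  mabp <- make_mini_abp_fixture()
  ems <- enumerate_ems(mabp$network)
  tg <- select_target_ems(ems, mabp$answer$objective)
  mcs <- enumerate_mcs(tg)
  obj <- objective_spec(mabp$answer$objective)
  mcs <- unaffected_counts(mcs, ems, universe = "non-target", objective = obj)
  # brute-force recount
  non_target <- Filter(function(s)
    length(intersect(s, mabp$answer$objective)) == 0, em_supports(ems))
  for (i in seq_along(mcs$sets)) {
    expect_equal(mcs$unaffected[i],
                 sum(vapply(non_target, function(s)
                   length(intersect(s, mcs$sets[[i]])) == 0, integer(1))))
  }
  # the objective-pair cut leaves every non-target mode untouched
  i_pair <- which(vapply(mcs$sets, setequal, logical(1),
                         c("m3UGT-pg", "m3UGT-cy")))
  expect_equal(mcs$unaffected[i_pair], length(non_target))
  # empty cut set leaves the whole universe unaffected
  empty <- unaffected_counts(fluxcut:::new_cutset_list(list(character(0))),
                             ems, universe = "all")
  expect_equal(empty$unaffected, n_modes(ems))
})

test_that("fragility is the mean reciprocal cut size", {
  # singleton membership gives fc = 1
  expect_equal(fragility(enumerate_mcs(list("a")))[["a"]], 1)
  # random cut collections vs direct recomputation
  for (seed in 1:10) {
    set.seed(seed)
    sets <- unique(lapply(1:6, function(i) sort(sample(letters[1:6],
                                                       sample(1:3, 1)))))
    sets <- sets[fluxcut:::minimal_sets(sets)]
    cs <- fluxcut:::new_cutset_list(sets)
    fc <- fragility(cs)
    for (r in names(fc)) {
      sizes <- lengths(sets)[vapply(sets, function(s) r %in% s, logical(1))]
      expect_equal(fc[[r]], mean(1 / sizes))
    }
    expect_true(all(fc > 0 & fc <= 1))
  }
})

test_that("the packaged cut-set table reproduces published fragility scores", {
  cs <- table3_cutsets()
  expect_equal(length(cs), 22L)
  expect_equal(sort(unique(cs$size)), c(1L, 2L, 3L))
  fc <- round(fragility(cs), 2)
  expect_equal(unname(fc[abp_candidate_reactions()]),
               c(0.50, 0.43, 0.43, 0.33, 1, 0.50, 0.50, 0.38, 0.43, 0.50,
                 0.38, 1))
})

test_that("pipeline on the synthetic pathway reproduces the packaged table", {
  sf <- synthetic_flavonoid_network()
  ems <- enumerate_ems(sf$network)
  tg <- select_target_ems(ems, sf$objective)
  mcs <- enumerate_mcs(tg, candidates = abp_candidate_reactions())
  expect_equal(length(mcs), 22L)
  expect_equal(set_list_key(mcs$sets), set_list_key(table3_cutsets()$sets))
  expect_equal(round(fragility(mcs), 10),
               round(fragility(table3_cutsets()), 10))
  # gene labels travel with the cuts
  i2 <- which(vapply(mcs$sets, identical, logical(1), "N-C-S-RXN"))
  expect_equal(mcs$genes[[i2]], "CHS")
})

test_that("cutset_table lays out membership, size, unaffected and genes", {
  cs <- table3_cutsets()
  tab <- cutset_table(cs, candidates = abp_candidate_reactions())
  expect_equal(nrow(tab), 22L)
  expect_equal(tab$total_rxns, cs$size)
  expect_equal(rowSums(tab[, abp_candidate_reactions()]), cs$size,
               ignore_attr = TRUE)
  back <- cutsets_from_matrix(tab[, abp_candidate_reactions()])
  expect_equal(set_list_key(back$sets), set_list_key(cs$sets))
})
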