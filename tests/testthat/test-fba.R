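test_that("the LP solver handles feasible, infeasible and unbounded cases", {
  # min x1 + x2 st x1 + x2 >= 1, x1 <= 0.3
  s <- lp_solve(c(1, 1), rbind(c(1, 1), c(1, 0)), c(">=", "<="), c(1, 0.3))
  expect_equal(s$status, "optimal")
  expect_equal(s$value, 1)
  # equality system
  s2 <- lp_solve(c(1, 1, 1), rbind(c(1, -1, 0), c(0, 1, -1), c(1, 0, 0)),
                 c("=", "=", "="), c(0, 0, 2))
  expect_equal(s2$status, "optimal")
  expect_equal(s2$x, c(2, 2, 2))
  expect_equal(lp_solve(1, rbind(1, 1), c("<=", ">="), c(1, 2))$status,
               "infeasible")
  expect_equal(lp_solve(-1, matrix(1, 0, 1), character(0), numeric(0))$status,
               "unbounded")
})

test_that("LP optima match brute-force vertex enumeration", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 3L; m <- 3L
    A <- matrix(sample(-3:3, m * n, TRUE), m)
    x0 <- runif(n, 0, 2)
    rhs <- as.vector(A %*% x0) + runif(m, 0.1, 1)   # x0 strictly feasible
    obj <- runif(n, 0.2, 1)                         # positive => bounded
    dir <- rep("<=", m)
    sol <- lp_solve(obj, A, dir, rhs)
    expect_equal(sol$status, "optimal")
    # oracle: enumerate all basic solutions of [A | I] z = rhs
    Aug <- cbind(A, diag(m))
    best <- Inf
    for (cols in utils::combn(ncol(Aug), m, simplify = FALSE)) {
      B <- Aug[, cols, drop = FALSE]
      if (abs(det(B)) < 1e-9) next
      z <- rep(0, ncol(Aug))
      z[cols] <- solve(B, rhs)
      if (all(z >= -1e-9)) best <- min(best, sum(obj * z[seq_len(n)]))
    }
    expect_equal(sol$value, best, tolerance = 1e-7,
                 label = sprintf("seed %d", seed))
  }
})

test_that("concentration conversion divides by molar mass", {
  expect_equal(round(convert_concentration(28.9, 449.4), 4), 0.0643)
  expect_equal(round(convert_concentration(37.3, 464.4), 4), 0.0803)
  expect_equal(convert_concentration(0, 123), 0)
  expect_equal(convert_concentration(c(28.9, 37.3), c(449.4, 464.4)),
               c(28.9 / 449.4, 37.3 / 464.4))
  expect_error(convert_concentration(1, 0), "positive")
  expect_error(convert_concentration(-1, 10), "nonnegative")
})

test_that("lignin growth contribution multiplies fraction by growth rate", {
  lf <- lignin_growth_flux()
  expect_equal(lf$rate, 0.027)
  expect_equal(lf$reaction$stoich[["CONIFERYL-ALCOHOL"]], -370)
  expect_equal(lf$reaction$stoich[["SINAPYL-ALCOHOL"]], -238)
  expect_equal(lf$reaction$stoich[["COUMARYL-ALCOHOL"]], -60)
  expect_equal(lignin_growth_flux(lignin_spec(biomass_fraction = 0.5,
                                              growth_rate_mu = 0.2))$rate, 0.1)
  expect_error(lignin_spec(biomass_fraction = 0))
})

test_that("constraint tables validate and round trip through files", {
  fc <- flux_constraints(c("a", "b"), c(1, 0), c(1, 5),
                         c("fixed-value", "range"))
  path <- withr::local_tempfile(fileext = ".val")
  write_constraints(fc, path)
  back <- read_constraints(path)
  expect_equal(back$reaction_id, fc$reaction_id)
  expect_equal(back$min, fc$min)
  expect_equal(back$max, fc$max)
  expect_equal(back$provenance, fc$provenance)
  expect_error(flux_constraints("a", 2, 1), "min > max")
  expect_error(flux_constraints("a", 1, 2, "fixed-value"), "min == max")
})

test_that("the reference state is feasible, deterministic and L1-minimal", {
  sf <- synthetic_flavonoid_network()
  ref <- solve_reference_state(sf$network, sf$constraints)
  expect_lt(ref$residual_norm, 1e-9)
  for (i in seq_len(nrow(sf$constraints))) {
    v <- ref$rates[[sf$constraints$reaction_id[i]]]
    expect_gte(v, sf$constraints$min[i] - 1e-9)
    expect_lte(v, sf$constraints$max[i] + 1e-9)
  }
  ref2 <- solve_reference_state(sf$network, sf$constraints)
  expect_identical(ref$rates, ref2$rates)
  # inputs recorded for the exchanges consuming external compounds only
  expect_setequal(names(ref$inputs),
                  c("PAL-RXN", "BENZYL-ALC-DEHYDROGENASE-RXN"))
})

test_that("contradictory bounds make the reference infeasible, and an
           unconstrained network rests at zero flux", {
  toy <- metabolic_network(list(
    reaction("in", c(X = -1, A = 1)),
    reaction("out", c(A = -1, Y = 1))),
    compounds = data.frame(id = c("X", "A", "Y"),
                           role = c("external", "internal", "external")))
  expect_error(solve_reference_state(
    toy, flux_constraints(c("in", "out"), c(2, 0), c(2, 1))),
    "no feasible reference")
  zero <- solve_reference_state(toy, NULL)
  expect_equal(unname(zero$rates), c(0, 0))
})

test_that("an empty cut reproduces the reference state", {
  sf <- synthetic_flavonoid_network()
  ref <- solve_reference_state(sf$network, sf$constraints)
  again <- simulate_cut_state(sf$network, ref, character(0))
  expect_equal(again$rates, ref$rates, tolerance = 1e-6)
  expect_length(again$relaxed, 0L)
})

test_that("blocked states zero the cut, keep inputs fixed, and stay balanced", {
  sf <- synthetic_flavonoid_network()
  ref <- solve_reference_state(sf$network, sf$constraints)
  ems <- enumerate_ems(sf$network)
  tg <- select_target_ems(ems, sf$objective)
  mcs <- enumerate_mcs(tg, candidates = abp_candidate_reactions())
  for (i in c(1, 2, 16)) {     # a singleton, the other singleton, a pair
    b <- simulate_cut_state(sf$network, ref, mcs, cut_index = i)
    expect_true(all(b$rates[mcs$sets[[i]]] == 0))
    expect_lt(b$residual_norm, 1e-7)
    expect_equal(b$rates[names(ref$inputs)], ref$inputs, tolerance = 1e-7)
  }
})

test_that("every cut drives the LP-maximal objective flux to zero", {
  mabp <- make_mini_abp_fixture()
  ems <- enumerate_ems(mabp$network)
  tg <- select_target_ems(ems, mabp$answer$objective)
  mcs <- enumerate_mcs(tg)
  for (cut in mcs$sets) {
    for (obj in mabp$answer$objective) {
      expect_equal(max_flux(mabp$network, obj, zero_reactions = cut), 0)
    }
  }
  # sanity: without the cut the objective can carry flux
  expect_gt(max_flux(mabp$network, "m3UGT-pg"), 0)
})

test_that("flux ratios are blocked/reference with NA where reference is zero", {
  sf <- synthetic_flavonoid_network()
  ref <- solve_reference_state(sf$network, sf$constraints)
  same <- simulate_cut_state(sf$network, ref, character(0))
  rr <- ratio_report(same, ref, sf$class_map, sf$network)
  defined <- !is.na(rr$per_reaction_ratio)
  expect_true(all(abs(rr$per_reaction_ratio[defined] - 1) < 1e-5))
  expect_true(all(abs(stats::na.omit(rr$per_class_average) - 1) < 1e-5))
  # reactions at zero reference rate are undefined, not zero
  zero_ref <- names(ref$rates)[abs(ref$rates) < 1e-9]
  expect_true(all(is.na(rr$per_reaction_ratio[zero_ref])))
})

test_that("ratios match a hand-solved four-reaction knockout", {
  # in -> A; A -> P1 (fixed 2); A -> P2 (fixed 1); block P1 with input fixed:
  # all influx must leave through P2, so P2 ratio = 3
  net <- metabolic_network(list(
    reaction("in", c(X = -1, A = 1)),
    reaction("mk1", c(A = -1, P1 = 1)),
    reaction("mk2", c(A = -1, P2 = 1))),
    compounds = data.frame(id = c("X", "A", "P1", "P2"),
                           role = c("external", "internal", "external", "external")))
  cons <- flux_constraints(c("mk1", "mk2"), c(2, 1), c(2, 1), "fixed-value")
  ref <- solve_reference_state(net, cons)
  expect_equal(unname(ref$rates), c(3, 2, 1))
  blocked <- simulate_cut_state(net, ref, "mk1")
  expect_equal(unname(blocked$rates), c(3, 0, 3), tolerance = 1e-7)
  cmap <- product_class_map(list(one = "P1", two = "P2"))
  rr <- ratio_report(blocked, ref, cmap, net)
  expect_equal(rr$per_class_average[["one"]], 0, tolerance = 1e-7)
  expect_equal(rr$per_class_average[["two"]], 3, tolerance = 1e-7)
})

test_that("scaling all constraints leaves every flux ratio unchanged", {
  sf <- synthetic_flavonoid_network()
  for (scale in c(1, 7.5)) {
    cons <- sf$constraints
    cons$min <- cons$min * scale
    cons$max <- cons$max * scale
    ref <- solve_reference_state(sf$network, cons)
    b <- simulate_cut_state(sf$network, ref, c("PELUDP-RXN", "RXN1F-775"))
    rr <- ratio_report(b, ref, sf$class_map, sf$network)
    if (scale == 1) first <- rr
  }
  expect_equal(rr$per_reaction_ratio, first$per_reaction_ratio,
               tolerance = 1e-5)
  expect_equal(rr$per_class_average, first$per_class_average,
               tolerance = 1e-5)
})

test_that("zero/low/high ratio patterns persist without range constraints", {
  sf <- synthetic_flavonoid_network()
  ems <- enumerate_ems(sf$network)
  tg <- select_target_ems(ems, sf$objective)
  mcs <- enumerate_mcs(tg, candidates = abp_candidate_reactions())
  i15 <- which(vapply(mcs$sets, setequal, logical(1),
                      c("PELUDP-RXN", "RXN1F-775")))
  pattern <- function(cons) {
    ref <- solve_reference_state(sf$network, cons)
    b <- simulate_cut_state(sf$network, ref, mcs, cut_index = i15)
    r <- ratio_report(b, ref, sf$class_map, sf$network)$per_class_average
    ifelse(is.na(r), "na", ifelse(abs(r) < 1e-5, "0",
           ifelse(r < 1 - 1e-5, "<1", ifelse(r > 1 + 1e-5, ">1", "1"))))
  }
  with_ranges <- pattern(sf$constraints)
  no_ranges <- pattern(sf$constraints[sf$constraints$provenance != "range", ])
  expect_equal(no_ranges, with_ranges)
})
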