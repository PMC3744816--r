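test_that("model validation enforces probability and modality rules", {
  expect_error(bond_model("t1", list(macrostate(0.5, 0, 5),
                                     macrostate(0.4, 100, 5))) |>
                 list() |> dynamic_model(),
               "sum to")
  expect_error(dynamic_model(list(bond_model("t1", list()))), "between 1 and 3")
  expect_error(macrostate(1.2, 0, 5), "occupancy")
  expect_error(macrostate(0.5, 0, -2), "spread")
  # coupled members must share occupancies
  expect_error(dynamic_model(list(
    bond_model("a", list(macrostate(0.6, 0, 5), macrostate(0.4, 100, 5)),
               coupling = "g"),
    bond_model("b", list(macrostate(0.5, 0, 5), macrostate(0.5, 100, 5)),
               coupling = "g"))), "differ in occupancies")
})

test_that("sampling defaults to 300 microstates and honours sigma = 0", {
  tpl <- get_probe()
  m <- dynamic_model(list(bond_model("t1", list(macrostate(1, 77, 0)))),
                     template = tpl)
  ens <- sample_ensemble(m, tpl, seed = 3)
  expect_equal(nrow(ens$torsions), 300)
  expect_true(all(ens$torsions[, "t1"] == 77))
})

test_that("macrostate selection frequencies follow the occupancies", {
  tpl <- get_probe()
  m <- dynamic_model(list(bond_model("t1", list(macrostate(0.62, -60, 5),
                                                macrostate(0.38, 120, 5)))),
                     template = tpl)
  n <- 10000
  ens <- sample_ensemble(m, tpl, n = n, seed = 11)
  f1 <- mean(ens$modes[, 1] == 1)
  se <- sqrt(0.62 * 0.38 / n)
  expect_lt(abs(f1 - 0.62), 3 * se)
})

test_that("wrapped-normal sampling is circularly correct near the cut", {
  tpl <- get_probe()
  m <- dynamic_model(list(bond_model("t1", list(macrostate(1, 179, 10)))),
                     template = tpl)
  ens <- sample_ensemble(m, tpl, n = 1e5, seed = 5)
  cm <- circ_mean(ens$torsions[, "t1"])
  expect_lt(circ_dist(cm, 179), 1)
  expect_gt(circ_dist(cm, 0), 90)
  expect_lt(abs(circ_sd(ens$torsions[, "t1"]) - 10), 0.5)
})

test_that("coupled bonds select one joint macrostate index", {
  tpl <- toy_chain_template(5)
  m <- dynamic_model(list(
    bond_model("t1", list(macrostate(0.5, -60, 1), macrostate(0.5, 120, 1)),
               coupling = "g"),
    bond_model("t2", list(macrostate(0.5, 30, 1), macrostate(0.5, -150, 1)),
               coupling = "g")), template = tpl)
  ens <- sample_ensemble(m, tpl, n = 2000, seed = 9)
  k1 <- ifelse(circ_dist(ens$torsions[, "t1"], -60) < 30, 1, 2)
  k2 <- ifelse(circ_dist(ens$torsions[, "t2"], 30) < 30, 1, 2)
  expect_true(all(k1 == k2))
  expect_equal(ncol(ens$modes), 1)  # one joint group
})

test_that("unnormalised probabilities are rejected, not renormalised", {
  tpl <- get_probe()
  m <- dynamic_model(list(bond_model("t1", list(macrostate(1, 0, 5)))),
                     template = tpl)
  m$bonds$t1$macrostates[[1]]$pi <- 0.9
  expect_error(sample_ensemble(m, tpl), "sum to")
})

test_that("macrostate enumeration follows the product rule", {
  tpl <- toy_chain_template(5)
  m <- dynamic_model(list(
    bond_model("t1", list(macrostate(0.5, 0, 5), macrostate(0.5, 120, 5))),
    bond_model("t2", list(macrostate(0.5, 60, 5), macrostate(0.5, 180, 5)))),
    template = tpl)
  st <- enumerate_macrostates(m)
  expect_equal(nrow(st$modes), 4)
  expect_equal(st$occupancy, rep(0.25, 4))
  expect_equal(sum(st$occupancy), 1, tolerance = 1e-12)

  uni <- dynamic_model(list(bond_model("t1", list(macrostate(1, 0, 5))),
                            bond_model("t2", list(macrostate(1, 60, 5)))),
                       template = tpl)
  expect_equal(nrow(enumerate_macrostates(uni)$modes), 1)
  expect_equal(enumerate_macrostates(uni)$occupancy, 1)
})

test_that("the fixture ground-truth model has 12 macrostates", {
  m <- ground_truth_model()
  st <- enumerate_macrostates(m)
  expect_equal(nrow(st$modes), 12)
  expect_equal(sum(st$occupancy), 1, tolerance = 1e-9)
})

test_that("family clustering reproduces occupancy sums exactly", {
  m <- ground_truth_model()
  st <- enumerate_macrostates(m)
  fam <- cluster_families(st, m, c("phi23", "psi23"))
  expect_equal(nrow(fam), 2)
  expect_equal(fam$population, c(0.62, 0.38), tolerance = 1e-12)
  expect_equal(sum(fam$population), 1, tolerance = 1e-12)
  # brute-force oracle: group occupancies by the linkage mode column
  key <- st$modes[, "link23"]
  want <- sort(tapply(st$occupancy, key, sum), decreasing = TRUE)
  expect_equal(fam$population, as.vector(want), tolerance = 1e-12)
  # member lists cover all states once
  expect_equal(sort(unlist(attr(fam, "members"))), 1:12)
  expect_error(cluster_families(st, m, character()), "non-empty")
  expect_error(cluster_families(st, m, "nope"), "not in model")
})

test_that("degenerate single-family clustering gives population 1", {
  tpl <- get_probe()
  m <- dynamic_model(list(bond_model("t1", list(macrostate(1, 0, 5)))),
                     template = tpl)
  fam <- cluster_families(enumerate_macrostates(m), m, "t1")
  expect_equal(nrow(fam), 1)
  expect_equal(fam$population, 1)
})

test_that("dynamic-model JSON round trip is lossless", {
  m <- ground_truth_model()
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  for (bn in names(m$bonds)) {
    for (k in seq_along(m$bonds[[bn]]$macrostates)) {
      expect_equal(m2$bonds[[bn]]$macrostates[[k]],
                   m$bonds[[bn]]$macrostates[[k]])
    }
    expect_equal(m2$bonds[[bn]]$coupling, m$bonds[[bn]]$coupling)
  }
  expect_equal(lapply(m2$rings, `[[`, "states"),
               lapply(m$rings, `[[`, "states"))
})

test_that("ensemble sampling is reproducible by seed", {
  tpl <- get_probe()
  m <- dynamic_model(list(bond_model("t1", list(macrostate(0.5, 0, 10),
                                                macrostate(0.5, 120, 10)))),
                     template = tpl)
  a <- sample_ensemble(m, tpl, n = 50, seed = 123)
  b <- sample_ensemble(m, tpl, n = 50, seed = 123)
  expect_identical(a, b)
  c <- sample_ensemble(m, tpl, n = 50, seed = 124)
  expect_false(identical(a$torsions, c$torsions))
})
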