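adult_fixture <- function(seed = 7) {
  sys <- mbac_test_system(unlimited = TRUE)
  ad <- grow_to_adult(sys, seed = seed)
  list(sys = sys, cfg = ad$cfg, cell = ad$cell_id, t = ad$iterations)
}

test_that("remove_tile leaves a hole in the membrane", {
  fx <- adult_fixture()
  ci <- morphosys:::cell_index(fx$cfg, fx$cell)
  n0 <- sum(!is.na(fx$cfg$cells[[ci]]$occ))
  cfg2 <- inflict(fx$cfg, injury("remove_tile", "r1a", fx$cell), fx$sys)
  cl2 <- cfg2$cells[[ci]]
  expect_equal(sum(!is.na(cl2$occ)), n0 - 1)
  expect_false(morphosys:::cell_closed(cl2))
  expect_gt(morphosys:::open_fraction(cl2), 0)
})

test_that("break_bond retains both tiles but cuts the bond", {
  fx <- adult_fixture()
  ci <- morphosys:::cell_index(fx$cfg, fx$cell)
  cl <- fx$cfg$cells[[ci]]
  b0 <- nrow(morphosys:::cell_bonds(cl))
  key <- morphosys:::bond_key("poleA", "r1a")
  cfg2 <- inflict(fx$cfg, injury("break_bond", key, fx$cell), fx$sys)
  cl2 <- cfg2$cells[[ci]]
  expect_equal(sum(!is.na(cl2$occ)), sum(!is.na(cl$occ)))
  expect_equal(nrow(morphosys:::cell_bonds(cl2)), b0 - 1)
})

test_that("remove_protion disables transport at the host tile", {
  fx <- adult_fixture()
  ci <- morphosys:::cell_index(fx$cfg, fx$cell)
  cfg2 <- inflict(fx$cfg, injury("remove_protion", "r1b", fx$cell), fx$sys)
  expect_false(cfg2$cells[[ci]]$protion_ok[["r1b"]])
  # the tile itself is still in place
  expect_false(is.na(cfg2$cells[[ci]]$occ[["r1b"]]))
})

test_that("injecting zero floating objects changes nothing", {
  fx <- adult_fixture()
  cfg2 <- inflict(fx$cfg, injury("inject_floats", character(0), fx$cell),
                  fx$sys)
  expect_identical(cfg2$floats, fx$cfg$floats)
})

test_that("injuries on missing targets fail naming the component", {
  fx <- adult_fixture()
  expect_error(inflict(fx$cfg, injury("remove_tile", "rod1", fx$cell), fx$sys),
               "rod1")
  expect_error(inflict(fx$cfg, injury("break_bond", "x|y", fx$cell), fx$sys),
               "x\\|y")
})

test_that("uninjured cells always survive with ratio exactly one", {
  sys <- mbac_test_system(unlimited = TRUE)
  est <- survival_experiment(sys, 0, n_runs = 4, seed = 1,
                             generation_time = 11)
  expect_equal(est$p_survive, 1)
  expect_equal(est$mean_recovery_ratio, 1, tolerance = 1e-12)
})

test_that("destroying every component is unsurvivable, ratio undefined", {
  sys <- mbac_test_system(unlimited = TRUE)
  est <- survival_experiment(sys, 34, n_runs = 4, seed = 2,
                             generation_time = 11)
  expect_equal(est$p_survive, 0)
  expect_true(is.na(est$mean_recovery_ratio))
})

test_that("repair takes extra time: recovery ratio at least one", {
  sys <- mbac_test_system(unlimited = TRUE)
  est <- survival_experiment(sys, 4, n_runs = 6, seed = 3,
                             generation_time = 11)
  if (est$p_survive > 0) expect_gte(est$mean_recovery_ratio, 1)
})

test_that("the sequential random-times schedule runs and scores", {
  sys <- mbac_test_system(unlimited = TRUE)
  est <- survival_experiment(sys, 2, schedule = "random_times",
                             n_runs = 4, seed = 4, generation_time = 11)
  expect_true(est$p_survive >= 0 && est$p_survive <= 1)
})
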