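test_that("species presets carry the calibrated protocol lengths", {
  expect_equal(mbac_preset("ecoli")$target_iterations, 100L)
  expect_equal(mbac_preset("slactis")$target_iterations, 150L)
  expect_equal(mbac_preset("lacidophilus")$target_iterations, 400L)
  expect_error(mbac_preset("bsubtilis"))
})

test_that("the bacterial system has the published inventory", {
  sys <- build_mbac(mbac_preset("ecoli"))
  expect_length(sys$tile_specs, 7)   # 4 polygonal + 3 rod-shaped
  kinds <- vapply(sys$tile_specs, function(t) t$shape$kind, character(1))
  expect_equal(sum(kinds == "polygon2D"), 4)
  expect_equal(sum(kinds == "rod1D"), 3)
  expect_length(sys$floating_specs, 2)
  protions <- unique(unlist(lapply(sys$tile_specs, function(t)
    vapply(t$protions, `[[`, character(1), "name"))))
  expect_length(protions, 1)
  rules <- table(vapply(sys$rules, `[[`, character(1), "kind"))
  expect_equal(length(sys$rules), 9L)
  expect_equal(as.integer(rules[c("metabolic", "creation", "destruction",
                                  "division")]),
               c(1L, 6L, 1L, 1L))
})

test_that("an adult cell exposes exactly 34 injurable components", {
  sys <- mbac_test_system(unlimited = TRUE)
  ad <- grow_to_adult(sys, seed = 3)
  tg <- injury_targets(ad$cfg, ad$cell_id)
  expect_equal(nrow(tg), 34)
  expect_equal(as.integer(table(tg$kind)[c("tile", "protion", "bond")]),
               c(10L, 6L, 18L))
  expect_true(is_adult_cell(ad$cfg$cells[[morphosys:::cell_index(ad$cfg,
                                                                 ad$cell_id)]]))
})

test_that("a zero nutrient budget freezes the population at one cell", {
  sys <- mbac_test_system(unlimited = FALSE, budget = 0)
  tr <- ms_run(sys, 30, seed = 1)
  expect_true(all(tr$census$cells == 1))
  expect_true(all(tr$census$tiles == 1))  # creation rules can never fire
})

test_that("limited nutrients give self-limiting sigmoidal growth", {
  sys <- mbac_test_system(unlimited = FALSE, budget = 300)
  tr <- ms_run(sys, 120, seed = 9)
  cen <- tr$census
  expect_true(all(diff(cen$cells) >= 0))
  # growth happened, then stopped without external intervention:
  # the whole budget is spent and the late census is flat
  expect_gt(utils::tail(cen$cells, 1), 5)
  expect_equal(tr$final$budget_left[["a"]], 0)
  # growth decelerates strongly once the supply is spent
  inc <- function(w1, w2) cen$cells[cen$iteration == w2] -
    cen$cells[cen$iteration == w1]
  expect_lt(inc(100, 120), inc(60, 80) / 2)
})

test_that("maturity emerges from septum completion, not a preset time", {
  sys <- mbac_test_system(unlimited = TRUE)
  # adulthood time varies across seeds because it is an emergent event
  t_adult <- vapply(1:4, function(s) grow_to_adult(sys, seed = s)$iterations,
                    numeric(1))
  expect_gt(length(unique(t_adult)), 1)
  # and the adult state itself always carries a single complete septum
  ad <- grow_to_adult(sys, seed = 5)
  cl <- ad$cfg$cells[[morphosys:::cell_index(ad$cfg, ad$cell_id)]]
  expect_true(morphosys:::septum_complete(cl))
  expect_equal(sum(!is.na(cl$occ[c("f1", "f2")])), 2)
})
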