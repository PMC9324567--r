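# White-box access to engine internals for constructing precise states.
slot_world_ <- function(sys, cl, s) morphosys:::slot_world(sys$template, cl, s)

# Bacterial system with the environment supply shut off, so tests place
# every floating object explicitly.
quiet_system <- function() {
  sys <- mbac_test_system(unlimited = FALSE, budget = 0)
  sys
}

put_float <- function(cfg, label, pos, cell = 0L) {
  morphosys:::add_floats(cfg, label, matrix(pos, 1, 3), cell)
}

test_that("no instances are applicable in an empty configuration", {
  sys <- quiet_system()
  sys$seed_tiles <- list()
  cfg <- ms_init(sys)
  expect_length(applicable_instances(cfg, sys), 0)
})

test_that("reagents beyond the interaction radius do not trigger rules", {
  sys <- quiet_system()
  cfg <- ms_init(sys)
  cfg$cells[[1]]$occ["r1a"] <- "sideA"
  cfg$cells[[1]]$protion_ok["r1a"] <- TRUE
  site <- slot_world_(sys, cfg$cells[[1]], "r1a")
  far <- put_float(cfg, "a", site + c(2 * sys$interaction_radius, 0, 0))
  inst <- applicable_instances(far, sys)
  expect_false(any(vapply(inst, function(i) i$kind == "metabolic", logical(1))))

  near <- put_float(cfg, "a", site + c(sys$interaction_radius / 2, 0, 0))
  inst <- applicable_instances(near, sys)
  met <- Filter(function(i) i$kind == "metabolic", inst)
  expect_length(met, 1)
  expect_identical(met[[1]]$slot, "r1a")
})

test_that("metabolic transport conserves the transported object", {
  sys <- quiet_system()
  # pure transport: a(out) -> a(in), no signal by-product; immobile
  # reagent so it stays at the channel mouth through the Brownian phase
  sys$rules[[1]] <- metabolic_rule("pch", consumed = "a", produced = "a")
  sys$floating_specs$a$mobility <- 0
  cfg <- ms_init(sys)
  cfg$cells[[1]]$occ["r1a"] <- "sideA"
  cfg$cells[[1]]$protion_ok["r1a"] <- TRUE
  site <- slot_world_(sys, cfg$cells[[1]], "r1a")
  cfg <- put_float(cfg, "a", site + c(0.3, 0, 0))
  n_a0 <- sum(cfg$floats$label == "a")
  cfg2 <- ms_step(cfg, sys)
  expect_equal(sum(cfg2$floats$label == "a"), n_a0)
  # the object crossed to the cell interior
  expect_true(any(cfg2$floats$label == "a" & cfg2$floats$cell == 1L))
})

test_that("competing creation instances consume one object only once", {
  # a closed cell with the seed rod placed: the rod-arm and rod-bridge
  # creation rules are both applicable at their scaffold slots, and a
  # single signal object sits within reach of both
  sys <- quiet_system()
  sys$floating_specs$s$mobility <- 0
  cfg <- ms_init(sys)
  cl <- cfg$cells[[1]]
  cl$occ[c("r1a", "r1b", "r1c")] <- "sideA"
  cl$occ[c("r2a", "r2b", "r2c")] <- "sideB"
  cl$occ["poleB"] <- "septum_face"
  cl$occ["rod1"] <- "rod_seed"
  cfg$cells[[1]] <- cl
  c2 <- morphosys:::capture_site(sys$template, cl, "rod2", "in")
  c3 <- morphosys:::capture_site(sys$template, cl, "rod3", "in")
  mid <- (c2 + c3) / 2
  expect_lt(sqrt(sum((mid - c2)^2)), sys$interaction_radius)
  set.seed(99)
  filled <- replicate(20, {
    cfg1 <- put_float(cfg, "s", mid, cell = 1L)
    inst <- applicable_instances(cfg1, sys)
    creat <- Filter(function(i) i$kind == "creation", inst)
    expect_length(creat, 2)
    cfg2 <- ms_step(cfg1, sys)
    expect_equal(sum(cfg2$floats$label == "s"), 0)
    sum(!is.na(cfg2$cells[[1]]$occ[c("rod2", "rod3")]))
  })
  # exactly one of the two competing scaffold slots fires each time,
  # and over repeats both slots get their turn (randomised order)
  expect_true(all(filled == 1))
})

test_that("a step with no rules and no objects only advances time", {
  sys <- quiet_system()
  sys$rules <- list()
  cfg <- ms_init(sys)
  cfg2 <- ms_step(cfg, sys)
  expect_equal(cfg2$iteration, cfg$iteration + 1L)
  expect_identical(cfg2$cells, cfg$cells)
  expect_identical(cfg2$floats, cfg$floats)
})

test_that("runs are deterministic and bit-stable under a fixed seed", {
  sys <- mbac_test_system(unlimited = FALSE, budget = 150)
  t1 <- ms_run(sys, 40, seed = 11)
  t2 <- ms_run(sys, 40, seed = 11)
  expect_identical(t1$census, t2$census)
  t3 <- ms_run(sys, 40, seed = 12)
  expect_false(identical(t1$census, t3$census))
})

test_that("run handles degenerate iteration counts", {
  sys <- quiet_system()
  tr <- ms_run(sys, 0, seed = 1)
  expect_equal(nrow(tr$census), 1)
  expect_error(ms_run(sys, -1), ">= 0")
})

test_that("object bookkeeping balances outside rule applications", {
  sys <- mbac_test_system(unlimited = FALSE, budget = 200)
  tr <- ms_run(sys, 60, seed = 5)
  cfg <- tr$final
  for (lab in c("a", "s")) {
    expect_equal(sum(cfg$floats$label == lab),
                 unname(cfg$ledger$injected[[lab]] -
                          cfg$ledger$consumed[[lab]] +
                          cfg$ledger$produced[[lab]]))
  }
})

test_that("bonds only join occupied slots after arbitrary evolution", {
  sys <- mbac_test_system(unlimited = TRUE)
  tr <- ms_run(sys, 50, seed = 21)
  for (cl in tr$final$cells) {
    b <- morphosys:::cell_bonds(cl)
    if (nrow(b)) {
      expect_false(any(is.na(cl$occ[b[, 1]])))
      expect_false(any(is.na(cl$occ[b[, 2]])))
    }
  }
})

test_that("division splits a mature cell into two closed daughters", {
  sys <- mbac_test_system(unlimited = TRUE)
  ad <- grow_to_adult(sys, seed = 7)
  cfg <- ad$cfg
  tiles_before <- morphosys:::count_tiles(cfg)
  inst <- list(rule = which(vapply(sys$rules, `[[`, character(1), "kind") ==
                              "division"),
               kind = "division", cell = ad$cell_id, floats = integer(0))
  cfg2 <- apply_division(cfg, inst, sys)
  expect_equal(length(cfg2$cells), length(cfg$cells) + 1)
  expect_equal(morphosys:::count_tiles(cfg2), tiles_before)
  for (cl in cfg2$cells) expect_true(morphosys:::cell_closed(cl))
})

test_that("division on an immature cell warns and is a no-op", {
  sys <- mbac_test_system(unlimited = TRUE)
  cfg <- ms_init(sys)
  inst <- list(kind = "division", cell = cfg$cells[[1]]$id,
               floats = integer(0))
  expect_warning(cfg2 <- apply_division(cfg, inst, sys), "trigger")
  expect_equal(length(cfg2$cells), 1)
})

test_that("repeated division yields exponential growth while fed", {
  sys <- mbac_test_system(unlimited = TRUE)
  tr <- ms_run(sys, 60, seed = 13)
  cen <- tr$census
  expect_true(all(diff(cen$cells) >= 0))   # cell count never decreases
  expect_gte(utils::tail(cen$cells, 1), 8) # several generations in 60 min
})
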