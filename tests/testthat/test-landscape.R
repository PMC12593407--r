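test_that("explicit landscapes evaluate to the additive closed form", {
  catalog <- reagent_catalog(
    precatalysts = c("NiCl2.dme", "NiBr2.dme"),
    ligands = data.frame(id = c("L1", "L2"), d1 = c(0.1, 0.2)),
    additives = data.frame(id = c("none", "MgCl2"), cation = c("none", "Mg"),
                           anion = c("none", "Cl")),
    solvents = data.frame(id = c("THF", "DMA"), d1 = c(1, 2)),
    substrates = data.frame(id = c("am1", "ac1"), role = c("amine", "acid"),
                            d1 = c(0, 0)))
  l <- make_landscape(catalog,
                      effects = list(precatalyst = c(NiCl2.dme = 5),
                                     ligand = c(L1 = 20),
                                     additive = c(none = 0),
                                     solvent = c(THF = 3)),
                      base = 20)
  cond <- list(precatalyst = "NiCl2.dme", ligand = "L1", additive = "none",
               solvent = "THF")
  expect_equal(eval_yield(l, cond), 48)        # 20 + 5 + 20 + 0 + 3
  # clipping to [0, 100], preserving order
  big <- make_landscape(catalog, effects = list(ligand = c(L1 = 200, L2 = 150)),
                        base = 20)
  y <- eval_yield(big, data.frame(precatalyst = "NiCl2.dme",
                                  ligand = c("L1", "L2"),
                                  additive = "none", solvent = "THF"))
  expect_equal(y, c(100, 100))
  low <- make_landscape(catalog, effects = list(ligand = c(L1 = -50)), base = 20)
  expect_equal(eval_yield(low, cond), 0)
  # interactions add only on matching id pairs
  li <- make_landscape(catalog, base = 20,
                       interactions = data.frame(class1 = "ligand", id1 = "L1",
                                                 class2 = "solvent", id2 = "THF",
                                                 effect = 7))
  expect_equal(eval_yield(li, cond), 27)
  expect_equal(eval_yield(li, modifyList(cond, list(solvent = "DMA"))), 20)
  expect_error(make_landscape(catalog, effects = list(ligand = c(L9 = 1))),
               "ligand")
})

test_that("landscape pairs share ligand effects and are seed-deterministic", {
  catalog <- tiny_catalog(3, 5, 4, 3)
  p1 <- make_landscape_pair(catalog, landscape_spec(), seed = 10)
  p2 <- make_landscape_pair(catalog, landscape_spec(), seed = 10)
  expect_identical(p1, p2)
  expect_identical(p1$source$effects$ligand, p1$target$effects$ligand)
  # divergence 0: source and target landscapes coincide entirely
  p0 <- make_landscape_pair(catalog, landscape_spec(divergence = 0), seed = 10)
  expect_identical(p0$source$effects, p0$target$effects)
  expect_identical(p0$source$interactions, p0$target$interactions)
  # full divergence decorrelates the non-shared classes
  expect_false(identical(p1$source$effects$solvent, p1$target$effects$solvent))
  # noiseless evaluation is pure
  conds <- enumerate_space(catalog)[1:20, ]
  expect_identical(eval_yield(p1$target, conds), eval_yield(p1$target, conds))
  expect_error(make_landscape_pair(catalog, list(divergence = 2), seed = 1),
               "divergence")
})

test_that("noiseless argmax matches per-class best effects without interactions", {
  catalog <- example_catalog()
  spec <- landscape_spec(interaction_density = 0, noise_sd = 0)
  pair <- make_landscape_pair(catalog, spec, seed = 3)
  conds <- enumerate_space(catalog)
  y <- eval_yield(pair$target, conds)
  best <- conds[which.max(y), ]
  eff <- pair$target$effects
  expect_identical(best$precatalyst, names(which.max(eff$precatalyst)))
  expect_identical(best$ligand, names(which.max(eff$ligand)))
  expect_identical(best$additive, names(which.max(eff$additive)))
  expect_identical(best$solvent, names(which.max(eff$solvent)))
})

test_that("synthetic source datasets have the stated size, bias and determinism", {
  catalog <- example_catalog()
  pair <- make_landscape_pair(catalog, landscape_spec(), seed = 5)
  src <- source_dataset_from_landscape(pair$source, catalog, seed = 9)
  expect_identical(nrow(src), 72L)
  expect_true(all(src$domain == "source") && all(src$iteration == 0L))
  expect_identical(anyDuplicated(src[, c("precatalyst", "ligand", "additive",
                                         "solvent")]), 0L)
  # 80% bias toward the best source ligand, within binomial 99% bounds
  best_lig <- names(which.max(pair$source$effects$ligand))
  frac <- mean(src$ligand == best_lig)
  bounds <- qbinom(c(0.005, 0.995), 72, 0.8) / 72
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
  expect_identical(src,
                   source_dataset_from_landscape(pair$source, catalog, seed = 9))
  expect_error(source_dataset_from_landscape(pair$source, catalog,
                                             sampling = list(n = 1e6), seed = 1),
               "space")
})

test_that("landscape JSON round trip reproduces evaluations exactly", {
  catalog <- tiny_catalog(2, 4, 3, 2)
  pair <- make_landscape_pair(catalog, landscape_spec(), seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_landscape(pair, path)
  back <- read_landscape(path)
  conds <- enumerate_space(catalog)
  expect_identical(eval_yield(back$target, conds), eval_yield(pair$target, conds))
  expect_identical(eval_yield(back$source, conds), eval_yield(pair$source, conds))
  # single landscape round trip
  write_landscape(pair$target, path)
  expect_identical(eval_yield(read_landscape(path), conds),
                   eval_yield(pair$target, conds))
})
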