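test_that("cuboid8 is a 27-node, 8-element lattice with a manifest", {
  model <- make_cuboid8()
  expect_equal(nrow(model$mesh$nodes), 27)
  expect_equal(nrow(model$mesh$elements), 8)
  expect_equal(sum(model$mesh$volumes), 8e-9, tolerance = 1e-12)
  man <- attr(model, "manifest")
  expect_equal(man$fixture, "cuboid8")
  expect_true(!is.null(man$parameters$sfo))
})

test_that("synthetic histories are seeded, reproducible and recoverable", {
  h1 <- make_synthetic_histories(seed = 42, n = 6, peak_strains = c(0.2, 0.8))
  h2 <- make_synthetic_histories(seed = 42, n = 6, peak_strains = c(0.2, 0.8))
  expect_identical(h1, h2)
  h3 <- make_synthetic_histories(seed = 43, n = 6, peak_strains = c(0.2, 0.8))
  expect_false(identical(h1, h3))

  peaks <- attr(h1, "manifest")$peak_strains
  for (i in seq_along(h1)) {
    expect_equal(max(apply(h1[[i]]$strain, 1, effective_strain)), peaks[i],
                 tolerance = 1e-9)
  }

  # prescribe peaks so exactly k of n exceed a threshold
  hp <- make_synthetic_histories(seed = 1, n = 5,
                                 peak_strains = c(0.1, 0.2, 0.7, 0.8, 0.9),
                                 plastic_fraction = 0)
  fv <- failed_element_volume(hp, "effective_strain", threshold = 0.59)
  expect_equal(length(fv$parts), 3L)

  # plastic histories accumulate, elastic ones stay zero
  hq <- make_synthetic_histories(seed = 2, n = 4, plastic_fraction = 0.5)
  eps <- vapply(hq, function(h) {
    suppressMessages(tail(effective_plastic_strain(h), 1))
  }, numeric(1))
  expect_true(all(eps[1:2] > 0))
  expect_identical(unname(eps[3:4]), c(0, 0))
})

test_that("drop block with zero speed and no gravity never touches the plane", {
  model <- make_drop_block(impact_speed = 0, termination = 2e-3)
  run <- run_simulation(model)
  expect_equal(max(run$contact$magnitude), 0)
  expect_lt(max(abs(run$node$u)), 1e-12)
})

test_that("fixture decks serialize with their loading", {
  deck <- model_to_deck(make_drop_block(sfo = 2))
  expect_equal(length(deck$walls), 1L)
  expect_equal(deck$initial_velocity[3], -3, tolerance = 1e-12)  # m/s = mm/ms
  lines <- write_deck(deck)
  re <- parse_deck(lines)
  model2 <- deck_to_model(re)
  expect_equal(model2$mesh$nodes, make_drop_block(sfo = 2)$mesh$nodes,
               tolerance = 1e-9)
  # coupon prescribed motion cannot be serialized and warns
  expect_warning(model_to_deck(make_uniaxial_coupon()), "prescribed")
})
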