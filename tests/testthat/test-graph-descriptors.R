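uniform_layer <- function(w) {
  m <- matrix(w, 6, 6, dimnames = list(MN_CHANNELS, MN_CHANNELS))
  diag(m) <- 0
  m
}

test_that("mean nodal strength matches hand computations", {
  expect_equal(mean_nodal_strength(uniform_layer(0.2)), 1)
  expect_equal(mean_nodal_strength(uniform_layer(0)), 0)
  one <- uniform_layer(0)
  one["RTEMP", "LTEMP"] <- one["LTEMP", "RTEMP"] <- 0.6
  expect_equal(mean_nodal_strength(one), 0.2)
})

test_that("assortativity is undefined on degenerate layers, negative for hubs", {
  expect_true(is.na(assortativity(uniform_layer(0.5))))
  one <- uniform_layer(0)
  one[1, 2] <- one[2, 1] <- 0.5
  expect_true(is.na(assortativity(one)))
  hub <- uniform_layer(0)
  hub[1, 2:6] <- hub[2:6, 1] <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  expect_lt(assortativity(hub), 0)
})

test_that("efficiency and assortativity match independent oracles on random layers", {
  for (s in 1:50) {
    lay <- random_layer(s)
    expect_equal(global_efficiency(lay), ge_floyd_warshall(lay),
                 tolerance = 1e-10)
    a1 <- assortativity(lay)
    a2 <- assortativity_covwt(lay)
    if (is.na(a1) || is.na(a2)) expect_equal(is.na(a1), is.na(a2))
    else expect_equal(a1, a2, tolerance = 1e-8)
  }
})

test_that("global efficiency equals the direct weight on uniform layers", {
  expect_equal(global_efficiency(uniform_layer(0.37)), 0.37)
  expect_equal(global_efficiency(uniform_layer(0)), 0)
})

test_that("weighted clustering follows the max-normalized geometric-mean form", {
  expect_equal(unname(weighted_clustering(uniform_layer(0.4))), rep(1, 6))
  one <- uniform_layer(0)
  one[1, 2] <- one[2, 1] <- 0.8
  expect_equal(unname(weighted_clustering(one)[1]), 0)
  tri <- uniform_layer(0)
  tri[1, 2] <- tri[2, 1] <- 0.8
  tri[1, 3] <- tri[3, 1] <- 0.4
  tri[2, 3] <- tri[3, 2] <- 0.2
  manual <- (1 / (2 * 1)) * 2 * ((0.8 / 0.8) * (0.4 / 0.8) * (0.2 / 0.8))^(1 / 3)
  expect_equal(unname(weighted_clustering(tri)[1]), manual, tolerance = 1e-10)
})

test_that("laterality index follows the right-minus-left normalized form", {
  sym <- uniform_layer(0.3)
  for (pt in c("TEMP_MAS", "TEMP_ABD", "MAS_ABD")) {
    expect_equal(laterality_index(sym, pt), 0)
  }
  lay <- uniform_layer(0)
  lay["RTEMP", "RMAS"] <- lay["RMAS", "RTEMP"] <- 0.4
  lay["LTEMP", "LMAS"] <- lay["LMAS", "LTEMP"] <- 0.2
  lay["RABD", "LABD"] <- lay["LABD", "RABD"] <- 1.4
  expect_equal(laterality_index(lay, "TEMP_MAS"), 0.1)
  expect_equal(laterality_index(uniform_layer(0), "MAS_ABD"), 0)
  lay2 <- random_layer(7)
  for (pt in c("TEMP_MAS", "TEMP_ABD", "MAS_ABD")) {
    expect_lte(abs(laterality_index(lay2, pt)), 1)
  }
})

test_that("edgewise features count 36 and respond to scaling as expected", {
  net <- multiplex_weights(preprocess_semg(simulate_semg(effect_profile(), 4, seed = 5)))
  ef <- edgewise_features(net)
  expect_equal(ncol(ef), 36L)

  lay <- random_layer(3, p_zero = 0)
  c0 <- 2.5
  expect_equal(mean_nodal_strength(c0 * lay), c0 * mean_nodal_strength(lay))
  expect_equal(global_efficiency(c0 * lay), c0 * global_efficiency(lay))
  expect_equal(weighted_clustering(c0 * lay), weighted_clustering(lay))
  expect_equal(assortativity(c0 * lay), assortativity(lay))
  expect_equal(laterality_index(c0 * lay, "TEMP_MAS"),
               laterality_index(lay, "TEMP_MAS"))
})

test_that("descriptors are invariant to consistent node relabeling", {
  lay <- random_layer(11, p_zero = 0.2)
  perm <- c(2, 1, 4, 3, 6, 5)  # swap left/right within pairs
  lp <- lay[perm, perm]
  expect_equal(mean_nodal_strength(lp), mean_nodal_strength(lay))
  expect_equal(global_efficiency(lp), global_efficiency(lay), tolerance = 1e-10)
  a1 <- assortativity(lp); a2 <- assortativity(lay)
  expect_equal(a1, a2, tolerance = 1e-10)
  expect_equal(sort(unname(weighted_clustering(lp))),
               sort(unname(weighted_clustering(lay))), tolerance = 1e-10)
})
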