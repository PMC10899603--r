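## small recipes reused across TEA tests
one_item_recipe <- function() {
  recipe(volume_L = 1000,
         items = list(list(name = "indoxyl", kg = 1)),
         product = list(molar_mass = 1000, substrate_conc = 0.001,
                        conversion = 1, stoichiometry = 1))
  ## product mass = 1000 L x 0.001 mol/L x 1 x 1 x 1000 g/mol / 1000 = 1 kg
}

toy_recipe <- function() {
  recipe(volume_L = 1000, time_h = 24,
         items = list(
           list(name = "indoxyl", kg = 10),
           list(name = "sucrose", mol_per_L = 0.2, molar_mass = 342.3),
           list(name = "electricity", kWh = 50)),
         product = list(molar_mass = 295.3, substrate_conc = 0.1,
                        conversion = 0.65, stoichiometry = 1))
}

test_that("a 1 kg item priced 5 USD/kg making 1 kg product costs 5 USD/kg", {
  prices <- default_price_table()
  cb <- material_cost_per_kg(one_item_recipe(), prices)
  expect_equal(cb$total, 5)
  expect_equal(unname(cb$items["indoxyl"]), 5)
})

test_that("toy recipe cost equals a hand spreadsheet summation", {
  prices <- default_price_table()
  cb <- material_cost_per_kg(toy_recipe(), prices)
  prod_kg <- 1000 * 0.1 * 0.65 * 1 * 295.3 / 1000  # 19.1945 kg
  hand <- (10 * 5 +                       # indoxyl mass
           0.2 * 342.3 * 1000 / 1000 * 0.5 +  # sucrose via molar spec
           50 * 0.12) / prod_kg           # electricity
  expect_equal(cb$total, hand, tolerance = 1e-12)
  expect_equal(sum(cb$items), cb$total)   # exact additivity
  expect_true(all(cb$items >= 0))
})

test_that("cost per kg is invariant under batch scaling", {
  prices <- default_price_table()
  r <- toy_recipe()
  doubled <- recipe(volume_L = 2 * r$volume_L, time_h = r$time_h,
                    items = list(
                      list(name = "indoxyl", kg = 20),
                      list(name = "sucrose", mol_per_L = 0.2,
                           molar_mass = 342.3),
                      list(name = "electricity", kWh = 100)),
                    product = r$product)
  expect_equal(material_cost_per_kg(r, prices)$total,
               material_cost_per_kg(doubled, prices)$total,
               tolerance = 1e-12)
})

test_that("missing prices and degenerate recipes fail loudly", {
  prices <- price_table("sucrose", 0.5)
  r <- one_item_recipe()
  expect_error(material_cost_per_kg(r, prices), "indoxyl")
})

test_that("the raw-material cost target formula multiplies out", {
  expect_identical(cost_target(5, 3, 0.6), 9 * 1.0)
  expect_equal(cost_target(1, 1, 1), 1)
  ## linear in each argument
  expect_equal(cost_target(10, 3, 0.6), 2 * cost_target(5, 3, 0.6))
  expect_equal(cost_target(5, 6, 0.6), 2 * cost_target(5, 3, 0.6))
  expect_equal(cost_target(5, 3, 0.3), cost_target(5, 3, 0.6) / 2)
})

test_that("tornado sensitivity matches brute-force re-evaluation", {
  prices <- default_price_table()
  r <- toy_recipe()
  params <- c("prices.indoxyl", "prices.sucrose",
              "recipe.items.electricity", "recipe.product.conversion")
  tor <- sensitivity_tornado(r, prices, params, span = 0.5)
  expect_equal(nrow(tor), 4)
  ## brute force each entry
  for (i in seq_len(nrow(tor))) {
    p <- tor$parameter[i]
    v <- indikit:::get_param(r, prices, p)
    for (side in c("cost_low", "cost_high")) {
      mult <- if (side == "cost_low") 0.5 else 1.5
      s <- indikit:::set_param(r, prices, p, v * mult)
      expect_equal(tor[[side]][i],
                   material_cost_per_kg(s$recipe, s$prices)$total,
                   tolerance = 1e-12)
    }
  }
  ## sorted by descending range
  expect_true(all(diff(tor$range) <= 1e-12))
  ## unknown path errors
  expect_error(sensitivity_tornado(r, prices, "prices.unobtainium"),
               "unknown parameter")
})

test_that("a single-item recipe responds linearly to its own price", {
  prices <- default_price_table()
  tor <- sensitivity_tornado(one_item_recipe(), prices, "prices.indoxyl",
                             span = 0.5)
  expect_equal(tor$cost_low, 2.5)
  expect_equal(tor$cost_high, 7.5)
})

test_that("point distributions reproduce the deterministic cost exactly", {
  prices <- default_price_table()
  r <- toy_recipe()
  det <- material_cost_per_kg(r, prices)$total
  dists <- list(price_distribution("indoxyl", "point", value = 5),
                price_distribution("sucrose", "point", value = 0.5))
  mc <- monte_carlo_cost(r, prices, dists, n = 200, seed = 4)
  expect_equal(mc$mean, det, tolerance = 1e-12)
  expect_equal(mc$p5, det, tolerance = 1e-12)
  expect_equal(mc$p50, det, tolerance = 1e-12)
  expect_equal(mc$p95, det, tolerance = 1e-12)
})

test_that("Monte-Carlo summaries are seed-reproducible", {
  prices <- default_price_table()
  r <- toy_recipe()
  dists <- gen_price_distributions(3)$distributions
  a <- monte_carlo_cost(r, prices, dists, n = 500, seed = 11)
  b <- monte_carlo_cost(r, prices, dists, n = 500, seed = 11)
  expect_identical(a, b)
  c2 <- monte_carlo_cost(r, prices, dists, n = 500, seed = 12)
  expect_false(identical(a$mean, c2$mean))
})

test_that("uniform price uncertainty converges to the analytic mean", {
  prices <- default_price_table()
  r <- one_item_recipe()
  dists <- list(price_distribution("indoxyl", "uniform",
                                   min = 2.5, max = 7.5))
  mc <- monte_carlo_cost(r, prices, dists, n = 1e5, seed = 21,
                         keep_sample = TRUE)
  se <- stats::sd(mc$sample) / sqrt(mc$n)
  expect_lt(abs(mc$mean - 5), 3 * se)
})

test_that("invalid distribution parameters fail before sampling", {
  expect_error(price_distribution("x", "uniform", min = 5, max = 2),
               "invalid")
  expect_error(price_distribution("x", "triangular", min = 1, mode = 0,
                                  max = 2), "invalid")
  expect_error(price_distribution("x", "point", value = -1), "invalid")
})

test_that("breakeven matches the closed-form inversion of a linear cost", {
  ## dyeing-style per-pair recipe: cost(V) = a + b V with V the water volume
  prices <- price_table(c("indican", "water", "electricity"),
                        c(9.9, 0.0077, 0.12),
                        c("USD/kg", "USD/kg", "USD/kWh"))
  mk <- function(vol_kg) recipe(
    volume_L = 1, functional_unit = "pair",
    items = list(list(name = "indican", kg = 0.005),
                 list(name = "water", kg = vol_kg),
                 list(name = "electricity", kWh = 0.4)))
  a <- 0.005 * 9.9 + 0.4 * 0.12
  b <- 0.0077
  target <- 0.11
  closed <- (target - a) / b
  got <- breakeven(mk(3.2), prices, "recipe.items.water", target,
                   bounds = c(0.1, 10))
  expect_equal(got, closed, tolerance = 1e-5)
  ## solved parameter reproduces the target cost
  s <- indikit:::set_param(mk(3.2), prices, "recipe.items.water", got)
  expect_equal(dyeing_cost_per_jean(s$recipe, s$prices)$total, target,
               tolerance = 1e-6)
  expect_error(breakeven(mk(3.2), prices, "recipe.items.water", 99,
                         bounds = c(0.1, 10)), "no-solution")
})

test_that("breakeven agrees with a dense grid scan on a dyeing recipe", {
  prices <- default_price_table()
  r <- recipe(volume_L = 1, functional_unit = "pair",
              items = list(list(name = "indican", kg = 0.004),
                           list(name = "phosphate_buffer", kg = 3.2),
                           list(name = "enzymes", kg = 1e-4),
                           list(name = "electricity", kWh = 0.3)))
  target <- dyeing_cost_per_jean(r, prices)$total * 0.9
  got <- breakeven(r, prices, "recipe.items.phosphate_buffer", target,
                   bounds = c(0.1, 10))
  grid <- seq(0.1, 10, length.out = 4001)
  costs <- vapply(grid, function(v) {
    s <- indikit:::set_param(r, prices, "recipe.items.phosphate_buffer", v)
    dyeing_cost_per_jean(s$recipe, s$prices)$total
  }, numeric(1))
  expect_lt(abs(got - grid[which.min(abs(costs - target))]), 5e-3)
})

test_that("per-jean costing prices electricity in USD/kWh", {
  prices <- price_table(c("dye", "electricity"), c(10, 0.12),
                        c("USD/kg", "USD/kWh"))
  r <- recipe(volume_L = 1, functional_unit = "pair",
              items = list(list(name = "dye", kg = 0.001),
                           list(name = "electricity", kWh = 0.4)))
  cb <- dyeing_cost_per_jean(r, prices)
  expect_equal(cb$total, 0.058)
  expect_equal(sum(cb$items), cb$total)
  zero <- recipe(volume_L = 1, functional_unit = "pair",
                 items = list(list(name = "dye", kg = 0)))
  expect_equal(dyeing_cost_per_jean(zero, prices)$total, 0)
})

test_that("market scale reproduces the printed 320-tank projection", {
  ms <- market_scale(annual_dye_tonnes = 50000, dye_molar_mass = 262.3,
                     product_molar_mass = 295.3, mol_ratio = 2,
                     batch_titer = 0.065, tank_volume_m3 = 100,
                     cycle_days = 2)
  expect_equal(ms$tanks_reported, 320)
  expect_gt(ms$tanks_exact, 300)
  ## doubling the titer halves the exact tank count
  ms2 <- market_scale(50000, 262.3, 295.3, 2, 0.13, 100, 2)
  expect_equal(ms2$tanks_exact, ms$tanks_exact / 2)
  ## annual product tonnage by hand: mol dye x ratio x M / 1e6
  hand <- (50000 * 1e6 / 262.3) * 2 * 295.3 / 1e6
  expect_equal(ms$annual_product_tonnes, hand)
  ## reported rounding still covers demand within rounding slack
  per_tank <- 0.065 * 100 * 1000 * (365 / 2)
  expect_gte(ms$tanks_reported * per_tank * 1.05,
             (50000 * 1e6 / 262.3) * 2)
})
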