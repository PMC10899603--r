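#' Price table for techno-economic costing
#'
#' @param items character item names.
#' @param price non-negative prices.
#' @param unit per-item unit, `"USD/kg"` or `"USD/kWh"`.
#' @return Object of class `price_table` (data frame).
#' @export
price_table <- function(items, price, unit = "USD/kg") {
  stopifnot(length(items) == length(price), all(price >= 0),
            all(unit %in% c("USD/kg", "USD/kWh")))
  out <- data.frame(item = as.character(items), price = price,
                    unit = rep_len(unit, length(items)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$item)) stop("duplicate price-table items")
  class(out) <- c("price_table", "data.frame")
  out
}

#' Default bulk price table
#'
#' Raw-material and electricity prices for the indican production and dyeing
#' processes: bulk-traded commodity prices, with buffers priced per kg of
#' prepared aqueous solution (1 L of solution taken as 1 kg).
#'
#' @return A [price_table()].
#' @export
default_price_table <- function() {
  price_table(
    items = c("indoxyl", "enzymes", "UDP", "UDP-glucose", "sucrose", "water",
              "HEPES", "citrate_phosphate_buffer", "phosphate_buffer",
              "HCl_30pct", "caustic_soda", "sodium_hydrosulphite",
              "setamol", "wetting_agent", "indican", "electricity"),
    price = c(5, 25, 50, 84900, 0.5, 0.0077,
              246.5, 0.1, 0.059,
              0.06, 4.5, 1.15,
              0.04, 0.09, 9.9, 0.12),
    unit = c(rep("USD/kg", 15), "USD/kWh")
  )
}

#' Process recipe
#'
#' A batch recipe: consumed items (mass, molar spec, or energy) plus the
#' product definition used to express costs per kg of product.
#'
#' @param volume_L batch volume in litres (> 0).
#' @param items list of item specs; each a list with `name` and one of
#'   `kg` (mass per batch), `mol_per_L` + `molar_mass` (solute converted to
#'   kg via the batch volume), or `kWh` (energy per batch).
#' @param time_h batch reaction time in hours.
#' @param product `NULL`, or list `molar_mass` (g/mol), `substrate_conc`
#'   (mol/L), `conversion` (fraction in (0, 1\]), `stoichiometry` (product per
#'   substrate, default 1).
#' @param functional_unit `"kg"` (costs per kg product) or `"pair"` (per-pair
#'   recipe, e.g. dyeing one pair of jeans).
#' @return Object of class `recipe`.
#' @export
recipe <- function(volume_L, items, time_h = 24, product = NULL,
                   functional_unit = c("kg", "pair")) {
  functional_unit <- match.arg(functional_unit)
  stopifnot(volume_L > 0, time_h >= 0)
  if (functional_unit == "kg") {
    stopifnot(!is.null(product))
    if (is.null(product$stoichiometry)) product$stoichiometry <- 1
    stopifnot(product$molar_mass > 0, product$substrate_conc > 0,
              product$conversion > 0, product$conversion <= 1)
  }
  for (it in items) {
    if (is.null(it$name)) stop("recipe item without a name")
    n_spec <- sum(!is.null(it$kg), !is.null(it$kWh),
                  !is.null(it$mol_per_L) && !is.null(it$molar_mass))
    if (n_spec != 1)
      stop("item '", it$name, "' needs exactly one of kg, mol_per_L+molar_mass, kWh")
  }
  structure(list(volume_L = volume_L, items = items, time_h = time_h,
                 product = product, functional_unit = functional_unit),
            class = "recipe")
}

## per-batch amounts: data frame (name, amount, unit)
recipe_quantities <- function(recipe) {
  rows <- lapply(recipe$items, function(it) {
    if (!is.null(it$kg)) {
      data.frame(name = it$name, amount = it$kg, unit = "kg",
                 stringsAsFactors = FALSE)
    } else if (!is.null(it$kWh)) {
      data.frame(name = it$name, amount = it$kWh, unit = "kWh",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(name = it$name,
                 amount = it$mol_per_L * it$molar_mass * recipe$volume_L / 1000,
                 unit = "kg", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Product mass per batch
#'
#' `volume x substrate concentration x conversion x stoichiometry x molar
#' mass`, in kg.
#'
#' @param recipe a [recipe()] with a product definition.
#' @return Product mass in kg per batch.
#' @export
product_mass_kg <- function(recipe) {
  p <- recipe$product
  if (is.null(p)) stop("recipe has no product definition")
  recipe$volume_L * p$substrate_conc * p$conversion * p$stoichiometry *
    p$molar_mass / 1000
}

lookup_prices <- function(quantities, prices) {
  idx <- match(quantities$name, prices$item)
  if (anyNA(idx))
    stop("missing-price: no price for item(s) ",
         paste(quantities$name[is.na(idx)], collapse = ", "))
  pr <- prices$price[idx]
  pu <- prices$unit[idx]
  exp_unit <- ifelse(quantities$unit == "kWh", "USD/kWh", "USD/kg")
  if (any(pu != exp_unit))
    stop("unit mismatch for item(s) ",
         paste(quantities$name[pu != exp_unit], collapse = ", "))
  pr
}

new_cost_breakdown <- function(items, costs, functional_unit) {
  total <- sum(costs)
  structure(list(items = stats::setNames(costs, items), total = total,
                 functional_unit = functional_unit),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  unit <- if (x$functional_unit == "kg") "USD/kg product" else "USD/pair"
  cat("Cost breakdown (", unit, ")\n", sep = "")
  for (nm in names(x$items))
    cat(sprintf("  %-28s %12.6g\n", nm, x$items[[nm]]))
  cat(sprintf("  %-28s %12.6g\n", "TOTAL", x$total))
  invisible(x)
}

#' Raw-material cost per kg of product
#'
#' @param recipe a [recipe()] with functional unit `"kg"`.
#' @param prices a [price_table()].
#' @return A `cost_breakdown` whose item costs sum exactly to `total`.
#' @export
material_cost_per_kg <- function(recipe, prices) {
  stopifnot(inherits(recipe, "recipe"), recipe$functional_unit == "kg")
  q <- recipe_quantities(recipe)
  pr <- lookup_prices(q, prices)
  pm <- product_mass_kg(recipe)
  if (pm <= 0) stop("degenerate-recipe: zero product mass")
  new_cost_breakdown(q$name, q$amount * pr / pm, "kg")
}

#' Dyeing cost per pair of jeans
#'
#' @param recipe a per-pair [recipe()] (functional unit `"pair"`) listing dye,
#'   enzyme, buffer, water and electricity amounts for one pair.
#' @param prices a [price_table()] (electricity priced in USD/kWh).
#' @return A `cost_breakdown` in USD per pair.
#' @export
dyeing_cost_per_jean <- function(recipe, prices) {
  stopifnot(inherits(recipe, "recipe"), recipe$functional_unit == "pair")
  q <- recipe_quantities(recipe)
  pr <- lookup_prices(q, prices)
  new_cost_breakdown(q$name, q$amount * pr, "pair")
}

## unified evaluation for either functional unit
evaluate_cost <- function(recipe, prices) {
  if (recipe$functional_unit == "kg") material_cost_per_kg(recipe, prices)
  else dyeing_cost_per_jean(recipe, prices)
}

#' Raw-material cost target
#'
#' The stated target construction: a material-cost fraction of a multiple of
#' the incumbent dye selling price.
#'
#' @param base_price incumbent selling price (USD/kg, default 5).
#' @param price_multiplier allowed price multiple (default 3).
#' @param material_fraction raw-material share of total cost (default 0.6).
#' @return Target raw-material cost in USD/kg.
#' @export
cost_target <- function(base_price = 5, price_multiplier = 3,
                        material_fraction = 0.6) {
  stopifnot(base_price > 0, price_multiplier > 0, material_fraction > 0)
  base_price * price_multiplier * material_fraction
}

## ---- parameter paths -------------------------------------------------------
## "prices.<item>", "recipe.volume_L", "recipe.time_h",
## "recipe.product.conversion" (etc.), "recipe.items.<name>" (the amount).

get_param <- function(recipe, prices, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (parts[1] == "prices") {
    i <- match(paste(parts[-1], collapse = "."), prices$item)
    if (is.na(i)) stop("unknown parameter path: ", path)
    return(prices$price[i])
  }
  if (parts[1] != "recipe") stop("unknown parameter path: ", path)
  if (parts[2] == "items") {
    nm <- paste(parts[-(1:2)], collapse = ".")
    for (it in recipe$items) {
      if (it$name == nm)
        return(it$kg %||% it$kWh %||% it$mol_per_L)
    }
    stop("unknown parameter path: ", path)
  }
  if (parts[2] == "product") {
    v <- recipe$product[[parts[3]]]
    if (is.null(v)) stop("unknown parameter path: ", path)
    return(v)
  }
  v <- recipe[[parts[2]]]
  if (is.null(v) || !is.numeric(v)) stop("unknown parameter path: ", path)
  v
}

set_param <- function(recipe, prices, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (parts[1] == "prices") {
    i <- match(paste(parts[-1], collapse = "."), prices$item)
    if (is.na(i)) stop("unknown parameter path: ", path)
    prices$price[i] <- value
  } else if (parts[1] == "recipe" && parts[2] == "items") {
    nm <- paste(parts[-(1:2)], collapse = ".")
    found <- FALSE
    for (k in seq_along(recipe$items)) {
      it <- recipe$items[[k]]
      if (it$name == nm) {
        slot <- if (!is.null(it$kg)) "kg" else if (!is.null(it$kWh)) "kWh"
                else "mol_per_L"
        recipe$items[[k]][[slot]] <- value
        found <- TRUE
      }
    }
    if (!found) stop("unknown parameter path: ", path)
  } else if (parts[1] == "recipe" && parts[2] == "product") {
    if (is.null(recipe$product[[parts[3]]]))
      stop("unknown parameter path: ", path)
    recipe$product[[parts[3]]] <- value
  } else if (parts[1] == "recipe") {
    if (is.null(recipe[[parts[2]]])) stop("unknown parameter path: ", path)
    recipe[[parts[2]]] <- value
  } else stop("unknown parameter path: ", path)
  list(recipe = recipe, prices = prices)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-at-a-time sensitivity (tornado) analysis
#'
#' Re-evaluates the total cost with each parameter at `(1 - span)` and
#' `(1 + span)` of its base value, all else fixed.
#'
#' @param recipe a [recipe()].
#' @param prices a [price_table()].
#' @param parameters character vector of parameter paths (see details in
#'   [breakeven()]).
#' @param span relative span (default 0.5, i.e. +/- 50%).
#' @return Data frame `parameter`, `base_value`, `cost_low`, `cost_high`,
#'   `range`, sorted by descending range.
#' @export
sensitivity_tornado <- function(recipe, prices, parameters, span = 0.5) {
  base_cost <- evaluate_cost(recipe, prices)$total
  rows <- lapply(parameters, function(p) {
    v <- get_param(recipe, prices, p)
    lo <- set_param(recipe, prices, p, v * (1 - span))
    hi <- set_param(recipe, prices, p, v * (1 + span))
    cl <- evaluate_cost(lo$recipe, lo$prices)$total
    ch <- evaluate_cost(hi$recipe, hi$prices)$total
    data.frame(parameter = p, base_value = v, cost_low = cl, cost_high = ch,
               range = abs(ch - cl), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$range), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_cost") <- base_cost
  out
}

#' Price distribution specification
#'
#' @param item item name in the price table.
#' @param family one of `"point"`, `"uniform"`, `"triangular"`, `"lognormal"`.
#' @param ... family parameters: point: `value`; uniform: `min`, `max`;
#'   triangular: `min`, `mode`, `max`; lognormal: `meanlog`, `sdlog`.
#' @return Object of class `price_distribution`.
#' @export
price_distribution <- function(item, family = c("point", "uniform",
                                                "triangular", "lognormal"),
                               ...) {
  family <- match.arg(family)
  p <- list(...)
  ok <- switch(family,
    point = !is.null(p$value) && p$value >= 0,
    uniform = !is.null(p$min) && !is.null(p$max) &&
      p$min >= 0 && p$max >= p$min,
    triangular = !is.null(p$min) && !is.null(p$mode) && !is.null(p$max) &&
      p$min >= 0 && p$min <= p$mode && p$mode <= p$max,
    lognormal = !is.null(p$meanlog) && !is.null(p$sdlog) && p$sdlog >= 0)
  if (!ok) stop("invalid ", family, " distribution parameters for ", item)
  structure(list(item = item, family = family, params = p),
            class = "price_distribution")
}

sample_price_distribution <- function(dist, n) {
  p <- dist$params
  switch(dist$family,
    point = rep(p$value, n),
    uniform = stats::runif(n, p$min, p$max),
    triangular = {
      u <- stats::runif(n)
      fc <- (p$mode - p$min) / (p$max - p$min)
      ifelse(u < fc,
             p$min + sqrt(u * (p$max - p$min) * (p$mode - p$min)),
             p$max - sqrt((1 - u) * (p$max - p$min) * (p$max - p$mode)))
    },
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog))
}

#' Monte-Carlo cost uncertainty
#'
#' Draws prices from the supplied distributions (items without a distribution
#' stay at their point price) and re-evaluates the total cost. The cost is
#' linear in prices, so sampling is vectorized over fixed per-functional-unit
#' quantities.
#'
#' @param recipe a [recipe()].
#' @param prices a [price_table()].
#' @param distributions list of [price_distribution()] objects.
#' @param n number of draws (>= 100).
#' @param seed RNG seed.
#' @param keep_sample return the full cost sample as well.
#' @return List `mean`, `p5`, `p50`, `p95`, `n`, and optionally `sample`.
#' @export
monte_carlo_cost <- function(recipe, prices, distributions, n = 10000,
                             seed = 1, keep_sample = FALSE) {
  stopifnot(n >= 100)
  for (d in distributions)
    if (!inherits(d, "price_distribution"))
      stop("distributions must be price_distribution objects")
  base <- evaluate_cost(recipe, prices)
  q <- recipe_quantities(recipe)
  denom <- if (recipe$functional_unit == "kg") product_mass_kg(recipe) else 1
  qty <- stats::setNames(q$amount / denom, q$name)
  base_prices <- stats::setNames(lookup_prices(q, prices), q$name)
  cost <- with_seed(seed, {
    total <- rep(0, n)
    for (nm in names(qty)) {
      d <- Filter(function(x) x$item == nm, distributions)
      pvec <- if (length(d) > 0) sample_price_distribution(d[[1]], n)
              else rep(base_prices[[nm]], n)
      total <- total + qty[[nm]] * pvec
    }
    total
  })
  out <- list(mean = mean(cost),
              p5 = unname(stats::quantile(cost, 0.05)),
              p50 = unname(stats::quantile(cost, 0.50)),
              p95 = unname(stats::quantile(cost, 0.95)),
              n = n, base_cost = base$total)
  if (keep_sample) out$sample <- cost
  out
}

#' Solve for a breakeven parameter value
#'
#' Bisection on a cost-monotone parameter until the total cost equals
#' `target_cost`, to a relative tolerance of 1e-6.
#'
#' Parameter paths: `"prices.<item>"` (a unit price), `"recipe.volume_L"`,
#' `"recipe.time_h"`, `"recipe.items.<name>"` (an item amount),
#' `"recipe.product.<field>"`.
#'
#' @param recipe a [recipe()].
#' @param prices a [price_table()].
#' @param parameter parameter path.
#' @param target_cost target total cost.
#' @param bounds length-2 numeric bracket for the parameter.
#' @return Parameter value at which total cost equals `target_cost`.
#' @export
breakeven <- function(recipe, prices, parameter, target_cost, bounds) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  cost_at <- function(v) {
    s <- set_param(recipe, prices, parameter, v)
    evaluate_cost(s$recipe, s$prices)$total - target_cost
  }
  flo <- cost_at(bounds[1]); fhi <- cost_at(bounds[2])
  if (sign(flo) == sign(fhi))
    stop(sprintf(
      "no-solution: target %.6g not bracketed (cost %.6g at %.6g, %.6g at %.6g)",
      target_cost, flo + target_cost, bounds[1], fhi + target_cost, bounds[2]))
  lo <- bounds[1]; hi <- bounds[2]
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    fm <- cost_at(mid)
    if (fm == 0 || (hi - lo) <= 1e-6 * max(1, abs(mid))) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

#' Market-scale projection
#'
#' Number of production tanks required to replace an annual dye demand with a
#' glycoside precursor produced batchwise.
#'
#' @param annual_dye_tonnes annual incumbent dye demand (tonnes).
#' @param dye_molar_mass incumbent dye molar mass (g/mol).
#' @param product_molar_mass precursor molar mass (g/mol).
#' @param mol_ratio moles of precursor per mole of dye.
#' @param batch_titer product titer per batch (mol/L).
#' @param tank_volume_m3 tank volume (m^3).
#' @param cycle_days days per batch cycle.
#' @param days_per_year operating days per year (default 365).
#' @return List `tanks_exact`, `tanks_reported` (2 significant figures),
#'   `annual_product_tonnes`.
#' @export
market_scale <- function(annual_dye_tonnes, dye_molar_mass,
                         product_molar_mass, mol_ratio, batch_titer,
                         tank_volume_m3, cycle_days, days_per_year = 365) {
  stopifnot(annual_dye_tonnes > 0, dye_molar_mass > 0,
            product_molar_mass > 0, mol_ratio > 0, batch_titer > 0,
            tank_volume_m3 > 0, cycle_days > 0, days_per_year > 0)
  dye_mol <- annual_dye_tonnes * 1e6 / dye_molar_mass
  product_mol <- dye_mol * mol_ratio
  per_tank_mol <- batch_titer * tank_volume_m3 * 1000 *
    (days_per_year / cycle_days)
  tanks <- product_mol / per_tank_mol
  list(tanks_exact = tanks,
       tanks_reported = signif2(tanks, 2),
       annual_product_tonnes = product_mol * product_molar_mass / 1e6)
}
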