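# Shared fixtures: tiny hand-built participant tables and toy value sets.

# A minimal complete participant table: `n` participants per arm, four waves
# on the default grid, constant resource-use counts, full health, all smokers.
toy_trial <- function(n_per_arm = 2, counts = 0, status = 1L,
                      wave_times = c(0, 0.115, 0.5, 1)) {
  arms <- rep(arm_levels(), each = n_per_arm)
  n <- length(arms)
  rows <- lapply(seq_along(wave_times), function(w) {
    df <- data.frame(id = seq_len(n), arm = arms, age = 48, sex = "female",
                     education = "medium", wave = w,
                     wave_time = wave_times[w], stringsAsFactors = FALSE)
    for (cat in cost_categories()) df[[cat]] <- counts
    for (it in eq5d_items()) df[[it]] <- 1L
    df$smoking_status <- status
    df$ftnd <- 5L
    df
  })
  out <- do.call(rbind, rows)
  out[order(out$id, out$wave), ]
}

# Flat unit prices (every category the same price, already in the index
# year so valuation is transparent).
flat_prices <- function(price = 10) {
  data.frame(category = cost_categories(), unit_price = price,
             price_year = 2011L, source = "standard",
             stringsAsFactors = FALSE)
}

# Toy additive value set: utility = 1 - 0.1 per level above 1.
toy_value_set <- function() {
  vs <- dutch_tariff_3l()
  lev <- do.call(rbind, lapply(strsplit(vs$state, ""), as.integer))
  vs$utility <- 1 - 0.1 * rowSums(lev - 1)
  vs
}

# Identity CPI pair: no price-year indexing.
no_index <- list(cpi_from = 100, cpi_to = 100)
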