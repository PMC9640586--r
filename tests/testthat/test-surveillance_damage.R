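test_that("damage attribution fires each clause in precedence order", {
  cases <- rbind(
    make_fruit("f1", larvae = 3L),                          # live sap beetle
    make_fruit("f2", larvae = 2L, moth = TRUE),             # both
    make_fruit("f3", moth = TRUE),                          # live moth
    make_fruit("f4", silk = TRUE),                          # silk -> moth
    make_fruit("f5", frass = 0.8),                          # coarse frass -> moth
    make_fruit("f6", frass = 0.08),                         # fine frass -> sap beetle
    make_fruit("f7", frass = 0.3),                          # gap -> undetermined
    make_fruit("f8"))                                       # nothing -> none
  out <- classify_damage(cases)
  expect_equal(out$label,
               c("sap_beetle", "both", "moth", "moth", "moth",
                 "sap_beetle", "undetermined", "none"))
  expect_equal(out$rule_fired[c(1, 2, 4, 6, 7, 8)],
               c("live_sap_beetle", "live_sap_beetle_and_moth",
                 "silk_or_coarse_frass", "fine_frass",
                 "intermediate_frass", "no_evidence"))
  # precedence: live stages beat trace evidence
  mixed <- classify_damage(make_fruit("m", adults = 1L, silk = TRUE))
  expect_equal(mixed$label, "sap_beetle")
  # boundary diameters: 0.1 is fine frass, 0.5 is not coarse
  expect_equal(classify_damage(make_fruit("b1", frass = 0.1))$label,
               "sap_beetle")
  expect_equal(classify_damage(make_fruit("b2", frass = 0.5))$label,
               "undetermined")
  # totality: every record gets exactly one label
  expect_false(any(is.na(out$label)))
  expect_error(classify_damage(make_fruit("x", adults = -1L)), "negative")
})

test_that("site infestation percentages print truncated, 10/18 -> 55.5", {
  # 18 sites, fruits at all; 10 sites have one sap-beetle fruit
  recs <- do.call(rbind, lapply(1:18, function(s)
    make_fruit(sprintf("f%02d", s), sprintf("site%02d", s),
               larvae = if (s <= 10) 1L else 0L)))
  s <- site_infestation_summary(recs)$by_year
  expect_equal(s$n_sites, 18L)
  expect_equal(s$n_infested, 10L)
  expect_equal(s$percent_truncated, 55.5)
  expect_equal(s$percent_rounded, 55.6)

  # no infested sites
  clean <- site_infestation_summary(
    make_fruit("f1", "s1"))$by_year
  expect_equal(clean$percent_truncated, 0)

  # 28 of 63 is 44.4 truncated (not the published 45.3)
  recs2 <- do.call(rbind, lapply(1:63, function(s)
    make_fruit(sprintf("g%02d", s), sprintf("t%02d", s),
               larvae = if (s <= 28) 1L else 0L)))
  expect_equal(site_infestation_summary(recs2)$by_year$percent_truncated,
               44.4)

  # moth-only fruit does not make a site sap-beetle infested
  moth_site <- make_fruit("f9", "s9", silk = TRUE)
  expect_equal(site_infestation_summary(moth_site)$by_year$n_infested, 0L)

  # per-site-type breakdown
  recs$year <- 2019L
  sites <- data.frame(site_id = sprintf("site%02d", 1:18),
                      site_type = rep(c("warehouse", "orchard"), 9))
  bt <- site_infestation_summary(recs, sites)$by_site_type
  expect_equal(sum(bt$n_sites), 18L)
  expect_equal(sum(bt$n_infested), 10L)
})

test_that("category damage table aggregates site percentages and beetle loads", {
  # one site, 20 fruits, 2 damaged: 10 percent, SE 0
  one <- do.call(rbind, lapply(1:20, function(f)
    make_fruit(sprintf("f%02d", f), "s1",
               larvae = if (f <= 2) 2L else 0L)))
  t1 <- category_damage_table(one)
  expect_equal(t1$pct_damaged_mean, 10)
  expect_equal(t1$pct_damaged_se, 0)
  expect_equal(t1$beetles_per_walnut_mean, 2)

  # two sites at 5% and 50%
  two <- rbind(
    do.call(rbind, lapply(1:20, function(f)
      make_fruit(sprintf("a%02d", f), "sA",
                 larvae = if (f <= 1) 1L else 0L))),
    do.call(rbind, lapply(1:20, function(f)
      make_fruit(sprintf("b%02d", f), "sB",
                 larvae = if (f <= 10) 1L else 0L))))
  t2 <- category_damage_table(two)
  expect_equal(t2$pct_damaged_mean, 27.5)
  expect_equal(t2$pct_damaged_min, 5)
  expect_equal(t2$pct_damaged_max, 50)

  # conservation: per-category fruit counts sum to the total
  fr <- gen_fruit_records(seed = 3)
  ct <- category_damage_table(fr)
  expect_equal(sum(ct$n_fruits), nrow(fr))
  s <- site_infestation_summary(fr)$by_year
  expect_lte(s$n_infested, s$n_sites)
})

test_that("generator round trip recovers category infestation probabilities", {
  probs <- c(sorted = 0.10, unsorted = 0.16, discarded = 0.32, ground = 0.22)
  fr <- gen_fruit_records(probs, n_sites = 12L, fruits_per_site = 25L,
                          seed = 5)
  ct <- category_damage_table(fr)
  for (cat in names(probs)) {
    row <- ct[ct$category == cat, ]
    expect_lt(abs(row$pct_damaged_mean - 100 * probs[[cat]]),
              2 * max(row$pct_damaged_se, 2))
  }
  # co-infestation rate ~3% of infested fruits
  fr2 <- gen_fruit_records(probs, n_sites = 40L, fruits_per_site = 25L,
                           moth_coinfestation = 0.03, seed = 6)
  cl <- classify_damage(fr2)
  inf <- cl$label %in% c("sap_beetle", "both")
  expect_lt(abs(mean(cl$label[inf] == "both") - 0.03), 0.03)
})
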