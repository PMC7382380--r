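# Mass-balance indices: enrichment, pools, per-plant indices, summaries.

test_that("enrichment is the atom-percent difference, optionally clamped", {
  expect_identical(enrichment(0.3660, 0.3660), 0)
  expect_equal(enrichment(1.3660, 0.3660), 1.0)
  expect_equal(enrichment(0.3600, 0.3660), -0.006)
  expect_identical(enrichment(0.3600, 0.3660, clamp = TRUE), 0)
  expect_error(enrichment(101, 0.366))
})

test_that("pools are true masses under the percent-as-fraction convention", {
  expect_equal(n_pools(100, 4.0, 1.0), data.frame(qty_n_mg = 4.0, qty_15n_mg = 0.04))
  expect_equal(n_pools(0, 4.0, 1.0)$qty_n_mg, 0)
  expect_equal(n_pools(200, 0, 1.0)$qty_15n_mg, 0)
  expect_error(n_pools(-1, 4, 1), "domain")
})

test_that("hand-checkable plant: allocations, HI, NUE and NRE", {
  # fixture plant with QtyN = (1, 5, 4) mg and tracer fractions (0.1, 0.4, 0.5)
  idx <- plant_indices(fixture_small())
  p <- idx[idx$plant_id == "g63_control_1_r1", ]
  expect_equal(unlist(p[c("alloc_n_rosette", "alloc_n_stem", "alloc_n_seeds")],
                      use.names = FALSE), c(0.1, 0.5, 0.4), tolerance = 1e-12)
  expect_equal(p$nhi, 0.4, tolerance = 1e-12)
  expect_equal(p$hi, 800 / 2000, tolerance = 1e-12)
  expect_equal(p$nue, 1.0, tolerance = 1e-12)
  expect_equal(p$nhi15, 0.5, tolerance = 1e-9)
  expect_equal(p$nre, 0.5 / 0.4, tolerance = 1e-9)
  expect_equal(p$nute, 2000 / 10, tolerance = 1e-12)
})

test_that("control-scale dry weights give HI near 31% and NUE near 1.3", {
  ds <- nue_dataset(plant_with_dw(c(230, 1590, 840)))
  idx <- plant_indices(ds)
  expect_equal(idx$hi, 840 / 2660, tolerance = 1e-12)   # 0.3158
  # NHI = 0.40 with HI = 0.3158 implies NUE = 1.267
  expect_equal(0.40 / (840 / 2660), 1.2666, tolerance = 1e-4)
})

test_that("degenerate seed guard: sterile plants get NaN ratios, HI intact", {
  idx <- plant_indices(fixture_small())
  sterile <- idx[idx$plant_id == "g401_heat_1_r2", ]
  expect_true(sterile$degenerate)
  expect_true(is.nan(sterile$nue))
  expect_true(is.nan(sterile$nre))
  expect_identical(sterile$hi, 0)
  expect_equal(sterile$nhi, 0)
  # near-sterile heat plants (seed DW ~20 mg) stay above the default guard
  expect_false(any(idx$degenerate[idx$plant_id != "g401_heat_1_r2"]))
})

test_that("allocations conserve mass and match brute-force recomputation", {
  set.seed(41)
  ds <- random_plants_dataset(60)
  idx <- plant_indices(ds)
  expect_equal(idx$alloc_n_rosette + idx$alloc_n_stem + idx$alloc_n_seeds,
               rep(1, nrow(idx)), tolerance = 1e-9)
  expect_equal(idx$alloc_15n_rosette + idx$alloc_15n_stem + idx$alloc_15n_seeds,
               rep(1, nrow(idx)), tolerance = 1e-9)
  expect_equal(idx$nue * idx$hi, idx$nhi, tolerance = 1e-9)
  expect_equal(idx$nre * idx$hi, idx$nhi15, tolerance = 1e-9)
  # brute-force from raw records, one plant
  rec <- ds$records[ds$records$plant_id == idx$plant_id[7], ]
  rec <- rec[match(c("rosette", "stem", "seeds"), rec$organ), ]
  qn <- rec$dw_mg * rec$n_pct / 100
  expect_equal(idx$alloc_n_seeds[7], qn[3] / sum(qn), tolerance = 1e-12)
  q15 <- rec$dw_mg * ((rec$a15_pct - 0.366) / 100) * (rec$n_pct / 100)
  expect_equal(idx$alloc_15n_stem[7], max(q15[2], 0) / sum(pmax(q15, 0)),
               tolerance = 1e-12)
})

test_that("indices are scale invariant in DW and N% as expected", {
  set.seed(7)
  base <- random_plant("p1")
  idx1 <- plant_indices(nue_dataset(base))
  scaled <- base; scaled$dw_mg <- scaled$dw_mg * 3.7
  idx2 <- plant_indices(nue_dataset(scaled))
  for (col in c("hi", "alloc_n_seeds", "alloc_15n_rosette", "nue", "nre")) {
    expect_equal(idx2[[col]], idx1[[col]], tolerance = 1e-12, label = col)
  }
  nscaled <- base; nscaled$n_pct <- nscaled$n_pct * 1.8
  idx3 <- plant_indices(nue_dataset(nscaled))
  expect_equal(idx3$alloc_n_seeds, idx1$alloc_n_seeds, tolerance = 1e-12)
  expect_equal(idx3$nhi, idx1$nhi, tolerance = 1e-12)
  expect_equal(idx3$nute, idx1$nute / 1.8, tolerance = 1e-12)
})

test_that("condition summaries are means of per-plant ratios with SE", {
  rec <- rbind(plant_with_dw(c(100, 500, 380), id = "a"),
               plant_with_dw(c(100, 500, 420), id = "b"))
  rec$n_pct <- rep(c(1, 1, 1), 2)   # NHI = dw_seeds / total
  idx <- plant_indices(nue_dataset(rec))
  expect_equal(sort(idx$nhi), c(380 / 980, 420 / 1020), tolerance = 1e-12)
  cs <- condition_summary(idx, by = "condition", index_cols = "nhi")
  expect_equal(cs$mean, mean(idx$nhi), tolerance = 1e-12)
  expect_equal(cs$se, stats::sd(idx$nhi) / sqrt(2), tolerance = 1e-12)

  # explicit two-value example: 0.38 / 0.42
  tab <- data.frame(condition = "c", nhi = c(0.38, 0.42), degenerate = FALSE)
  cs2 <- condition_summary(tab, by = "condition", index_cols = "nhi")
  expect_equal(cs2$mean, 0.40)
  expect_equal(cs2$se, 0.02)

  # single plant: SE missing
  cs3 <- condition_summary(tab[1, ], by = "condition", index_cols = "nhi")
  expect_true(is.na(cs3$se))

  # an all-degenerate cell reports the ratio index as missing, not zero
  tab4 <- data.frame(condition = "heat", nue = c(NaN, NaN), degenerate = TRUE)
  cs4 <- condition_summary(tab4, by = "condition", index_cols = "nue")
  expect_identical(cs4$n, 0L)
  expect_true(is.na(cs4$mean))
  expect_identical(cs4$n_degenerate, 2L)
})

test_that("plants missing an organ are skipped, not silently indexed", {
  rec <- fixture_small()$records
  rec <- rec[!(rec$plant_id == "g63_heat_1_r1" & rec$organ == "stem"), ]
  expect_warning(idx <- plant_indices(nue_dataset(rec)), "skipped")
  expect_false("g63_heat_1_r1" %in% idx$plant_id)
})
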