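make_conditions <- function(hdr = c(10, 5), nhej = c(30, 30), mmej = c(8, 8),
                            fluor = c(30000, 30000)) {
  data.frame(
    drug = c("drugA", "DMSO"),
    concentration_um = c(10, 0),
    plate = "p1", well = c("w1", "m1"),
    reads = 15000,
    hdr_pct = hdr, nhej_pct = nhej, mmej_pct = mmej, mix_pct = c(4, 4),
    fluorescence = fluor, is_mock = c(FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

test_that("metrics are fold-changes over the plate's mock mean", {
  m <- relative_to_mock(make_conditions())
  expect_equal(m$rel_hdr[1], 2)         # 10% vs mock 5%
  expect_equal(m$rel_hdr[2], 1)         # mock against itself
  expect_equal(m$rel_nhej, c(1, 1))

  # two mocks 4% and 6%: denominator is their mean
  df <- rbind(make_conditions(hdr = c(10, 4)),
              transform(make_conditions(hdr = c(10, 6))[2, ], well = "m2"))
  m2 <- relative_to_mock(df)
  expect_equal(m2$rel_hdr[1], 2)
})

test_that("a plate without a mock or with a zero mock metric is handled", {
  df <- make_conditions(); df$is_mock <- FALSE
  expect_error(relative_to_mock(df), "without a mock")
  df0 <- make_conditions(hdr = c(10, 0))
  m <- relative_to_mock(df0)
  expect_true(all(is.na(m$rel_hdr)))
  expect_match(attr(m, "undefined_metrics"), "rel_hdr")
})

test_that("the depth filter boundary sits exactly at 1000 reads", {
  df <- data.frame(drug = letters[1:5], reads = c(0, 999, 1000, 1001, 50000))
  kept <- read_depth_filter(df)
  expect_equal(kept$reads, c(1001, 50000))
  expect_equal(attr(kept, "excluded")$reads, c(0, 999, 1000))
})

test_that("quartiles follow the linear-interpolation convention", {
  expect_equal(compute_quartiles(c(1, 2, 3, 4, 5)), c(q1 = 2, q3 = 4))
  expect_equal(compute_quartiles(rep(7, 10)), c(q1 = 7, q3 = 7))
  set.seed(3); v <- runif(40)
  expect_equal(compute_quartiles(v), compute_quartiles(sample(v)))
  expect_error(compute_quartiles(c(1, 2, 3)), "at least 4")
})

fixed_bounds <- function(q1 = 0.8, q3 = 1.2) {
  structure(list(rel_hdr = c(q1 = q1, q3 = q3),
                 rel_nhej = c(q1 = q1, q3 = q3),
                 rel_mmej = c(q1 = q1, q3 = q3),
                 rel_survival = c(q1 = q1, q3 = q3)),
            class = "quartile_bounds")
}

test_that("directional category rules reproduce the worked examples", {
  b <- fixed_bounds()
  expect_equal(categorize_condition(1.5, 0.9, 1.0, 1.0, b), "hdr_enhancer")
  expect_equal(categorize_condition(1.0, 1.0, 1.0, 1.0, b), character(0))
  # hdr 1.3 / nhej 0.5 / mmej 1.3: hdr_enhancer fails on mmej > q3,
  # mmej_enhancer fails on hdr > q3, only nhej_inhibitor holds
  expect_equal(categorize_condition(1.3, 0.5, 1.3, 1.0, b), "nhej_inhibitor")
  expect_equal(categorize_condition(1.0, 1.0, 1.0, 1.5, b),
               "survival_enhancer")
  # a drug lifting everything is not a pathway hit
  expect_equal(setdiff(categorize_condition(1.5, 1.5, 1.5, 1.0, b),
                       "survival_enhancer"), character(0))
})

test_that("conditions may satisfy several categories and mocks stay neutral at zero noise", {
  b <- fixed_bounds()
  multi <- categorize_condition(1.5, 0.5, 1.0, 1.5, b)
  expect_true(all(c("hdr_enhancer", "nhej_inhibitor", "survival_enhancer")
                  %in% multi))
  expect_equal(categorize_condition(1, 1, 1, 1, b), character(0))
})

test_that("MMEJ detection-limit normalization maps the floor to zero", {
  expect_equal(normalize_mmej_detection_limit(0.74), 0)
  expect_equal(normalize_mmej_detection_limit(1.0), 1)
  expect_equal(normalize_mmej_detection_limit(0.87), 0.5)
  expect_equal(normalize_mmej_detection_limit(0.5), 0)   # clamped below
  expect_equal(normalize_mmej_detection_limit(1.6), 1.6) # > 1 untouched
  # non-decreasing
  x <- seq(0, 2, by = 0.01)
  expect_true(all(diff(normalize_mmej_detection_limit(x)) >= 0))
  expect_error(normalize_mmej_detection_limit(1, floor = 1.2), "between 0 and 1")
})

test_that("top-hit selection deduplicates drugs and keeps the planted leader first", {
  scr <- simulate_screen(n_drugs = 60, n_per_category = 0, frac_null = 1,
                         noise_cv = 0.05, seed = 21)
  # plant one 6-fold mmej enhancer by hand on two concentrations of one drug
  m <- relative_to_mock(scr$conditions, scr$blanks)
  m <- m[!m$is_mock, ]
  m$rel_mmej[m$drug == "drug_0007"] <- 6
  extra <- m[m$drug == "drug_0007", ][1, ]
  extra$concentration_um <- 1; extra$rel_mmej <- 4
  m <- rbind(m, extra)
  top <- select_top_hits(m, "rel_mmej", n = 30, direction = "enhancer")
  expect_equal(top$drug[1], "drug_0007")
  expect_equal(top$rel_mmej[1], 6)              # best concentration kept
  expect_equal(sum(top$drug == "drug_0007"), 1) # deduplicated
  expect_equal(nrow(top), 30)
  # n larger than the drug count returns everything once
  all_hits <- select_top_hits(m, "rel_mmej", n = 1000)
  expect_equal(nrow(all_hits), length(unique(m$drug)))
})

test_that("enrichment reports classes with at least two top drugs", {
  lib <- sprintf("d%02d", 1:100)
  ann <- data.frame(drug = lib,
                    target_class = rep(c("X", "Y", "Z", "W"), c(10, 30, 50, 10)))
  top <- c(lib[1:6], lib[11:14], lib[61:80])  # 6 X, 4 Y, 20 Z
  expect_equal(length(top), 30L)
  e <- target_class_enrichment(top, ann, lib)
  x <- e[e$target_class == "X", ]
  expect_equal(x$n_top, 6L)
  expect_equal(x$top_share, 0.2)
  expect_equal(x$library_share, 0.1)
  expect_equal(x$fold_enrichment, 2)
  # class with a single top drug is omitted
  topW <- c(lib[1:6], lib[91])  # one W drug only
  eW <- target_class_enrichment(topW, ann, lib)
  expect_false("W" %in% eW$target_class)
  expect_error(target_class_enrichment(character(0), ann, lib), "empty")
})

test_that("a uniformly drawn top list shows no systematic enrichment", {
  set.seed(12)
  lib <- sprintf("d%03d", 1:400)
  ann <- data.frame(drug = lib, target_class = rep(c("X", "Y"), each = 200))
  folds <- replicate(200, {
    e <- target_class_enrichment(sample(lib, 30), ann, lib)
    mean(e$fold_enrichment)
  })
  expect_equal(mean(folds), 1, tolerance = 0.05)
})

test_that("the dose ladder multiplies the base by 0.2/0.5/1/2/5", {
  expect_equal(build_dose_ladder(1), c(0.2, 0.5, 1, 2, 5))
  expect_equal(build_dose_ladder(10), c(2, 5, 10, 20, 50))
  expect_true(1.7 %in% build_dose_ladder(1.7))
  expect_error(build_dose_ladder(0), "positive")
  expect_error(build_dose_ladder(-1), "positive")
})

test_that("dose-response shortlist extends until four non-toxic hits; 0.79 is toxic", {
  df <- data.frame(
    drug = sprintf("d%02d", 1:10),
    categories = "mmej_enhancer",
    rel_hdr = 1, rel_nhej = 1,
    rel_mmej = seq(4, 1.3, length.out = 10),
    rel_survival = c(0.5, 0.3, 0.9, 0.79, 1.0, 0.95, 0.2, 1.1, 0.85, 0.9),
    stringsAsFactors = FALSE
  )
  sl <- select_subset_for_dose_response(df)
  short <- sl$mmej_enhancer
  # ranked by rel_mmej descending; non-toxic members are d03, d05, d06, d08
  # (d04 at exactly 0.79 counts as toxic), so the shortlist runs to d08
  expect_equal(short$drug, sprintf("d%02d", 1:8))
  expect_equal(sum(short$nontoxic), 4)
  expect_false(short$nontoxic[short$rel_survival == 0.79])

  # all members toxic: everything returned with a warning
  df$rel_survival <- 0.3
  expect_warning(sl2 <- select_subset_for_dose_response(df), "non-toxic")
  expect_equal(nrow(sl2$mmej_enhancer), 10)
})

test_that("metric correlation is plain two-tailed Pearson", {
  df <- data.frame(a = 1:20, b = 2 * (1:20), c = rep(1, 20))
  r <- metric_correlation(df, "a", "b")
  expect_equal(r$r, 1)
  expect_equal(metric_correlation(df, "b", "a")$r, r$r)  # symmetric
  expect_true(is.na(metric_correlation(df, "a", "c")$r))
  set.seed(8)
  df2 <- data.frame(x = rnorm(1000), y = rnorm(1000))
  r2 <- metric_correlation(df2, "x", "y")
  expect_lt(abs(r2$r), 0.1)
  expect_gt(r2$p_value, 0.05)
})
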