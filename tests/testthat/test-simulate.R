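test_that("amplicon simulation is deterministic under seed and respects geometry", {
  a1 <- simulate_amplicon(seed = 3)
  a2 <- simulate_amplicon(seed = 3)
  expect_identical(a1$amplicon$sequence, a2$amplicon$sequence)
  expect_identical(a1$mh_deletions, a2$mh_deletions)
  g <- a1$guide
  expect_gte(g$protospacer_start, 0L)
  expect_lte(g$protospacer_end, a1$amplicon$length)
  expect_error(simulate_amplicon(seed = 1, length = 50), "at least 80")
  expect_error(simulate_amplicon(), "seed is mandatory")
})

test_that("GC content is honoured on long amplicons", {
  a <- simulate_amplicon(seed = 5, length = 10000)
  gc <- nchar(gsub("[AT]", "", a$amplicon$sequence)) / 10000
  expect_equal(gc, 0.5, tolerance = 0.02)
  a3 <- simulate_amplicon(seed = 5, length = 10000, gc = 0.3)
  gc3 <- nchar(gsub("[AT]", "", a3$amplicon$sequence)) / 10000
  expect_equal(gc3, 0.3, tolerance = 0.02)
})

test_that("read simulation is deterministic and truth rows match reads one to one", {
  sim <- test_design()
  r1 <- simulate_reads(sim, n_reads = 200, error_rate = 0.01, seed = 4)
  r2 <- simulate_reads(sim, n_reads = 200, error_rate = 0.01, seed = 4)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth, r2$truth)
  expect_equal(names(r1$reads), r1$truth$read_id)
})

test_that("every generated mmej allele has >= 2 bp junction microhomology (oracle)", {
  sim <- test_design()
  for (se in sim$mh_deletions) {
    expect_gte(mh_brute(sim$amplicon$sequence, se[1], se[2]), 2L)
  }
  # and nhej deletions in generated reads really have < 2 bp at the junction
  rr <- simulate_reads(sim, n_reads = 500, seed = 19)
  calls <- classify_reads(rr$reads, sim$amplicon, sim$guide, sim$edits)
  nd <- which(rr$truth$generative_kind == "nhej_del")
  expect_true(all(calls$mh_length[nd] < 2))
})

test_that("an hdr-only mixture round-trips to 100% hdr calls", {
  sim <- test_design()
  mix <- c(unmodified = 0, hdr = 1, nhej_ins = 0, nhej_del = 0,
           mmej_del = 0, mix = 0)
  rr <- simulate_reads(sim, n_reads = 300, mixture = mix, seed = 6)
  calls <- classify_reads(rr$reads, sim$amplicon, sim$guide, sim$edits)
  expect_true(all(calls$category == "hdr"))
})

test_that("classified mmej share matches the planted mixture within binomial error", {
  sim <- test_design()
  mix <- c(unmodified = 0.4, hdr = 0.1, nhej_ins = 0.1, nhej_del = 0.1,
           mmej_del = 0.3, mix = 0)
  n <- 4000
  rr <- simulate_reads(sim, n_reads = n, mixture = mix, seed = 23)
  calls <- classify_reads(rr$reads, sim$amplicon, sim$guide, sim$edits)
  share <- mean(calls$category == "mmej")
  ci99 <- 2.58 * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(share - 0.3), ci99)
})

test_that("screen simulation is deterministic and structurally sound", {
  s1 <- simulate_screen(n_drugs = 40, seed = 9)
  s2 <- simulate_screen(n_drugs = 40, seed = 9)
  expect_identical(s1$conditions, s2$conditions)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$truth, s2$truth)
  expect_true(all(table(s1$conditions$plate[s1$conditions$is_mock]) >= 1))
  expect_equal(sort(unique(s1$truth$drugs$drug)),
               sort(unique(s1$conditions$drug[!s1$conditions$is_mock])))
  expect_error(simulate_screen(n_drugs = 40), "seed is mandatory")
  expect_error(simulate_screen(n_drugs = 10, n_per_category = 4, seed = 1),
               "too small")
})

test_that("a null screen with zero noise yields relative metrics of exactly 1", {
  scr <- simulate_screen(n_drugs = 30, n_per_category = 0, frac_null = 1,
                         toxic_frac = 0, noise_cv = 0, fluor_sd = 0, seed = 13)
  m <- relative_to_mock(scr$conditions, scr$blanks)
  expect_equal(m$rel_hdr, rep(1, nrow(m)))
  expect_equal(m$rel_nhej, rep(1, nrow(m)))
  expect_equal(m$rel_mmej, rep(1, nrow(m)))
  expect_equal(m$rel_survival, rep(1, nrow(m)), tolerance = 1e-6)
})

test_that("planted toxicity suppresses read counts into the depth filter", {
  scr <- simulate_screen(n_drugs = 150, seed = 27)
  m <- relative_to_mock(scr$conditions, scr$blanks)
  kept <- read_depth_filter(m)
  excl <- attr(kept, "excluded")
  truth <- scr$truth$drugs
  if (nrow(excl) > 0) {
    # every depth-filtered condition belongs to a strongly toxic drug
    expect_true(all(truth$survival_effect[match(excl$drug, truth$drug)] < 0.1))
  }
  # deep toxicity (survival 0.05 at 15000 mean reads -> ~750 reads) is caught
  toxic <- truth$drug[truth$survival_effect < 0.05]
  if (length(toxic) > 0) {
    expect_true(all(m$reads[m$drug %in% toxic] < 1500))
  }
})

test_that("fastq round trip preserves reads and names", {
  sim <- test_design()
  rr <- simulate_reads(sim, n_reads = 50, seed = 2)
  fp <- tempfile(fileext = ".fastq")
  write_fastq(rr$reads, fp)
  back <- read_fastq(fp)
  expect_identical(back, rr$reads)
  unlink(fp)
})
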