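# Shared design: 150 bp amplicon, cut at 75, window [65, 85), donor
# substitution at position 79.
design <- test_design()
amp <- design$amplicon
guide <- design$guide
edits <- design$edits
cut <- cut_site(guide)
win <- quant_window(guide, amp$length)

test_that("the shared design is what the tests assume", {
  expect_equal(cut, 75L)
  expect_equal(win, c(65L, 85L))
  expect_equal(edits$positions, 79L)
})

test_that("wild-type and donor-edited reads get their trivial categories", {
  expect_equal(classify_read(amp$sequence, amp, guide, edits)$category,
               "unmodified")
  expect_equal(classify_read(edits$expected_hdr_sequence, amp, guide,
                             edits)$category, "hdr")
})

test_that("a microhomology-flanked deletion at the cut is called mmej", {
  se <- design$mh_deletions[[1]]
  read <- delete_interval(amp$sequence, se[1], se[2])
  # oracle: the junction carries >= 2 bp microhomology
  expect_gte(mh_brute(amp$sequence, se[1], se[2]), 2L)
  call <- classify_read(read, amp, guide, edits)
  expect_equal(call$category, "mmej")
  expect_gte(call$mh_length, 2L)
})

test_that("a 1 bp insertion at the cut is called nhej", {
  left_base <- substring(amp$sequence, cut, cut)
  ins <- setdiff(c("A", "C", "G", "T"), left_base)[1]
  read <- insert_at(amp$sequence, cut, ins)
  expect_equal(classify_read(read, amp, guide, edits)$category, "nhej")
})

test_that("donor substitution plus a window indel is called mix", {
  read <- insert_at(edits$expected_hdr_sequence, cut, "A")
  call <- classify_read(read, amp, guide, edits)
  expect_equal(call$category, "mix")
  expect_true(call$edits_present)
})

test_that("deletions are split between mmej and nhej exactly at 2 bp microhomology", {
  # scan the window for 3 bp deletions of known microhomology
  found1 <- FALSE; found2 <- FALSE
  for (s in (win[1]):(win[2] - 3)) {
    mh <- mh_brute(amp$sequence, s, s + 3)
    read <- delete_interval(amp$sequence, s, s + 3)
    call <- classify_read(read, amp, guide, edits)
    if (call$category %in% c("nhej", "mmej")) {
      expect_equal(call$category, if (call$mh_length >= 2) "mmej" else "nhej",
                   info = paste("deletion at", s))
      if (call$mh_length == 1) found1 <- TRUE
      if (call$mh_length == 2) found2 <- TRUE
    }
  }
  expect_true(found1 || found2)  # the boundary was actually exercised
})

test_that("indels outside the quantification window do not trigger indel calls", {
  inside <- delete_interval(amp$sequence, win[2] - 1, win[2])
  outside <- delete_interval(amp$sequence, win[2] + 5, win[2] + 6)
  expect_true(classify_read(inside, amp, guide, edits)$category
              %in% c("nhej", "mmej"))
  expect_equal(classify_read(outside, amp, guide, edits)$category,
               "unmodified")
})

test_that("the wild-type retention boundary sits exactly at 70% similarity", {
  # substitutions far from window and donor position; 45 of 150 -> sim
  # exactly 0.70 kept, 46 -> 0.693 discarded (minimum of 70% similarity)
  pos_pool <- c(0:55, 95:145)
  read70 <- mutate_positions(amp$sequence, pos_pool[seq(1, 90, 2)])  # 45 subs
  read69 <- mutate_positions(amp$sequence, pos_pool[seq(1, 92, 2)])  # 46 subs
  c70 <- classify_read(read70, amp, guide, edits)
  c69 <- classify_read(read69, amp, guide, edits)
  expect_equal(c70$similarity_to_wt, 0.70)
  expect_equal(c70$category, "unmodified")
  expect_equal(c69$category, "discarded")
  expect_equal(c69$discard_reason, "low_similarity")
})

test_that("the HDR boundary sits exactly at 95% similarity to the donor sequence", {
  pos_pool <- c(0:55, 95:145)
  hdr7 <- mutate_positions(edits$expected_hdr_sequence, pos_pool[1:7])
  hdr8 <- mutate_positions(edits$expected_hdr_sequence, pos_pool[1:8])
  c7 <- classify_read(hdr7, amp, guide, edits)   # 143/150 = 0.9533
  c8 <- classify_read(hdr8, amp, guide, edits)   # 142/150 = 0.9467
  expect_gte(c7$similarity_to_hdr, 0.95)
  expect_equal(c7$category, "hdr")
  expect_lt(c8$similarity_to_hdr, 0.95)
  expect_equal(c8$category, "unmodified")  # substitutions disregarded
})

test_that("unexpected substitutions are disregarded everywhere", {
  # errors near (but not in) the window and at non-donor window positions
  read <- mutate_positions(amp$sequence, c(10, 66, 84, 120))
  expect_equal(classify_read(read, amp, guide, edits)$category, "unmodified")
  # an error on top of an MMEJ deletion does not change the call
  se <- design$mh_deletions[[1]]
  read2 <- mutate_positions(delete_interval(amp$sequence, se[1], se[2]), 10)
  expect_equal(classify_read(read2, amp, guide, edits)$category, "mmej")
})

test_that("multi-indel reads are attributed to nhej, not mmej", {
  # two separate 1 bp window deletions: not a single microhomology junction,
  # so the conservative reading assigns nhej whatever the individual mh
  read <- delete_interval(delete_interval(amp$sequence, 78, 79), 70, 71)
  call <- classify_read(read, amp, guide, edits)
  expect_equal(call$category, "nhej")
  expect_equal(call$n_window_del, 2L)
})

test_that("reads with many N bases are discarded with a reason", {
  chars <- strsplit(amp$sequence, "", fixed = TRUE)[[1]]
  chars[1:20] <- "N"  # 13% N
  call <- classify_read(paste(chars, collapse = ""), amp, guide, edits)
  expect_equal(call$category, "discarded")
  expect_equal(call$discard_reason, "too_many_N")
})

test_that("lowering the similarity threshold never loses reads; raising mh_min never gains mmej", {
  rr <- simulate_reads(design, n_reads = 400, error_rate = 0.02, seed = 31)
  retained <- vapply(c(0.95, 0.9, 0.8, 0.7, 0.6, 0.5), function(th) {
    calls <- classify_reads(rr$reads, amp, guide, edits,
                            classify_thresholds(min_wt_similarity = th))
    sum(calls$category != "discarded")
  }, 1L)
  expect_true(all(diff(retained) >= 0))

  mmej_n <- vapply(c(1L, 2L, 3L, 4L), function(mh) {
    calls <- classify_reads(rr$reads, amp, guide, edits,
                            classify_thresholds(mh_min = mh))
    sum(calls$category == "mmej")
  }, 1L)
  expect_true(all(diff(mmej_n) <= 0))
})

test_that("category counts are conserved across the cascade", {
  rr <- simulate_reads(design, n_reads = 500, error_rate = 0.05, seed = 77)
  calls <- classify_reads(rr$reads, amp, guide, edits)
  expect_equal(sum(table(calls$category)), 500L)
  s <- summarize_sample(calls)
  expect_equal(s$retained + s$discarded, s$total)
})

test_that("a window outside the amplicon is a configuration error", {
  g_bad <- guide_spec(0, 8, cut_offset = -3)  # cut at 5, window [-5, 15)
  expect_error(classify_read(amp$sequence, amp, g_bad, edits),
               "outside the amplicon")
})
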