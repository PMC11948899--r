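# Junction model, the start-window/soft-clip read filter, and the junction
# read simulator.

test_that("junction model derives the insert length from its boundaries", {
  jm <- junction_model("tx", 605, 1002)
  expect_equal(jm$insert_length, 397)
  expect_error(junction_model("tx", 1002, 605))
})

test_that("the start-window rule retains exactly the enumerated reads", {
  jm <- junction_model("tx", 605, 2000)
  reads <- data.frame(read_id = sprintf("r%03d", 500:610),
                      start = 500:610, cigar = "100M",
                      stringsAsFactors = FALSE)
  hits <- detect_junction_reads(reads, jm)
  # [J-80, J-10] = [525, 595]: 71 clean 100-bp reads
  expect_equal(nrow(hits), 71L)
  expect_equal(sort(hits$start), 525:595)
  expect_true(all(hits$junction == "upstream"))
  expect_true(all(hits$left_overhang > 0 & hits$right_overhang > 0))
  # a read wholly upstream of the junction window is never a hit
  far <- data.frame(read_id = "far", start = 1, cigar = "100M")
  expect_equal(nrow(detect_junction_reads(far, jm)), 0L)
})

test_that("clips are rejected at 5 bp and counted on both ends, hard clips included", {
  jm <- junction_model("tx", 605, 2000)
  reads <- data.frame(
    read_id = c("clean", "small_clip", "exact5", "big", "hard", "right_clip"),
    start = 550,
    cigar = c("100M", "4S96M", "5S95M", "6S94M", "6H94M", "94M6S"),
    stringsAsFactors = FALSE)
  hits <- detect_junction_reads(reads, jm)
  expect_setequal(hits$read_id, c("clean", "small_clip"))
  # internal soft clip is a record-level error
  bad <- data.frame(read_id = "x", start = 550, cigar = "40M5S55M")
  expect_error(detect_junction_reads(bad, jm), "internal clip")
})

test_that("a read hits at most one junction under the default windows", {
  jm <- junction_model("tx", 605, 1002)
  reads <- simulate_junction_reads(jm, read_length = 100, n_reads = 3000,
                                   clip_model = list(prob = 0, lengths = 0),
                                   seed = 3)
  hits <- detect_junction_reads(reads, jm)
  expect_equal(anyDuplicated(hits$read_id), 0L)
})

test_that("the detector matches a per-read brute-force oracle on simulated SAM", {
  jm <- junction_model("tx", 605, 1002)
  sam <- tempfile(fileext = ".sam")
  reads <- simulate_junction_reads(jm, read_length = 100, n_reads = 2000,
                                   seed = 7, sam_path = sam)
  loaded <- read_sam_alignments(sam)
  expect_equal(nrow(loaded), nrow(reads))
  hits <- detect_junction_reads(loaded, jm)

  # oracle: recompute the start-window rule from the simulator's records
  m <- reads$read_length - reads$clip_left - reads$clip_right
  end <- reads$start + m - 1
  clip_ok <- reads$clip_left < 5 & reads$clip_right < 5
  oracle <- character(0)
  for (J in c(jm$upstream, jm$downstream))
    oracle <- c(oracle, reads$read_id[clip_ok & reads$start >= J - 80 &
                                        reads$start <= J - 10 & end > J])
  expect_setequal(hits$read_id, oracle)

  # retained reads with small clips always span the junction by >= 10 bp
  # on each side (the literal rule implies the per-base definition here)
  spans <- reads$spans_any[match(hits$read_id, reads$read_id)]
  expect_true(all(spans))
})

test_that("a forced 6-bp clip on every read suppresses all hits", {
  jm <- junction_model("tx", 605, 1002)
  reads <- simulate_junction_reads(jm, read_length = 100, n_reads = 500,
                                   clip_model = list(prob = 1, lengths = 6),
                                   seed = 5)
  expect_equal(nrow(detect_junction_reads(reads, jm)), 0L)
})

test_that("zero reads give a valid empty SAM and no hits", {
  jm <- junction_model("tx", 605, 1002)
  sam <- tempfile(fileext = ".sam")
  reads <- simulate_junction_reads(jm, n_reads = 0, sam_path = sam)
  expect_equal(nrow(reads), 0L)
  loaded <- read_sam_alignments(sam)  # header-only SAM parses cleanly
  expect_equal(nrow(loaded), 0L)
  expect_equal(nrow(detect_junction_reads(loaded, jm)), 0L)
})
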