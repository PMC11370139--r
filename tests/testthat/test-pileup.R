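test_that("base_at_position handles match, splice, deletion and clip geometry", {
  # pure match block
  expect_equal(base_at_position(100, "50M", strrep("A", 50), 120)$base, "A")
  # site inside an intron skip
  expect_equal(base_at_position(100, "10M100N40M", strrep("A", 50), 115)$base,
               "uncovered")
  # soft clip + deletion: 5S eats query 1-5, M1 aligns ref 100-109 to query
  # 6-15, D eats ref 110-111, so ref 112 maps to query index 16 (1-based)
  seq <- paste(rep(c("C", "G"), length.out = 25), collapse = "")
  got <- base_at_position(100, "5S10M2D10M", seq, 112)
  expect_equal(got$base, substr(seq, 16, 16))
  # deletion itself is uncovered
  expect_equal(base_at_position(100, "5S10M2D10M", seq, 110)$base, "uncovered")
  # outside the aligned span on both sides
  expect_equal(base_at_position(100, "10M", strrep("A", 10), 99)$base,
               "uncovered")
  expect_equal(base_at_position(100, "10M", strrep("A", 10), 110)$base,
               "uncovered")
  # quality extraction at the right offset
  q <- base_at_position(100, "5M", "ACGTA", 102, qual = "!#%')")
  expect_equal(q$base, "G")
  expect_equal(q$qual, 4L)
  # inconsistent CIGAR / sequence length
  expect_error(base_at_position(100, "10M", "ACGT", 105), "length")
})

test_that("base_at_position agrees with a per-base CIGAR expander on random reads", {
  set.seed(402)
  n_checked <- 0L
  for (i in 1:300) {
    al <- random_alignment()
    ref_span <- sum(as.integer(
      sub(".$", "", regmatches(al$cigar,
                               gregexpr("[0-9]+[MDN=X]", al$cigar))[[1]])))
    for (pos in sample(seq(al$start - 3, al$start + ref_span + 3), 4)) {
      want <- oracle_base_at(al$start, al$cigar, al$seq, pos)
      got <- base_at_position(al$start, al$cigar, al$seq, pos)
      expect_identical(got$base, want$base)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 1000L)
})

test_that("pileup counts reads per cell and applies base/mapping quality filters", {
  site <- variant_sites("chr1", 1000, "C", "T")
  reads <- data.frame(
    pos = 991, cigar = "20M",
    seq = c("AAAAAAAAACAAAAAAAAAA",   # ref base, Q37
            "AAAAAAAAACAAAAAAAAAA",   # ref base, low Q
            "AAAAAAAAATAAAAAAAAAA",   # alt base
            "AAAAAAAAAGAAAAAAAAAA",   # other base
            "AAAAAAAAATAAAAAAAAAA"),  # alt, low mapq
    qual = c("F", "#", "F", "F", "F"),
    mapq = c(60L, 60L, 60L, 60L, 3L),
    CB = "CELL1-1", UB = NA_character_,
    stringsAsFactors = FALSE)
  bam <- make_test_bam(reads)
  got <- pileup_site(bam, site, min_base_quality = 20,
                     min_mapping_quality = 10)
  expect_equal(got$barcode, "CELL1")
  expect_equal(got$evidence, "read")
  expect_equal(got[, c("n_ref", "n_alt", "n_other")],
               data.frame(n_ref = 1L, n_alt = 1L, n_other = 1L))
  # raising min_base_quality never increases any count
  loose <- pileup_site(bam, site, min_base_quality = 0,
                       min_mapping_quality = 10)
  expect_true(all(got$depth <= loose$depth))
  expect_equal(loose$n_ref, 2L)
})

test_that("flag and CB filters exclude reads entirely", {
  site <- variant_sites("chr1", 1000, "C", "T")
  reads <- data.frame(
    pos = 1000, cigar = "10M", seq = "TAAAAAAAAA", qual = "F",
    flag = c(0L, 256L, 2048L, 512L, 4L, 0L),
    CB = c("X-1", "X-1", "X-1", "X-1", "X-1", NA),
    UB = NA_character_, stringsAsFactors = FALSE)
  bam <- make_test_bam(reads)
  got <- pileup_site(bam, site)
  expect_equal(got$n_alt, 1L)   # secondary/supplementary/qcfail/unmapped/no-CB gone
  keep_nocb <- pileup_site(bam, site, require_cb = FALSE)
  expect_equal(sum(keep_nocb$n_alt), 2L)
})

test_that("UMI consensus collapses molecules by majority and drops ties", {
  site <- variant_sites("chr1", 1000, "C", "T")
  seq_of <- function(b) paste0(b, strrep("A", 9))
  reads <- data.frame(
    pos = 1000, cigar = "10M",
    seq = c(seq_of("T"), seq_of("T"), seq_of("T"), seq_of("C"),  # UMI u1: majority T
            seq_of("C"), seq_of("T"),                            # UMI u2: tie -> dropped
            seq_of("C")),                                        # UMI u3: ref
    qual = "F", CB = "Y-1",
    UB = c("u1", "u1", "u1", "u1", "u2", "u2", "u3"),
    stringsAsFactors = FALSE)
  bam <- make_test_bam(reads)
  got <- pileup_site(bam, site, umi_mode = "consensus")
  expect_equal(got$evidence, "umi")
  expect_equal(got$n_alt, 1L)
  expect_equal(got$n_ref, 1L)
  expect_equal(got$depth, 2L)
  # read mode counts every read
  rd <- pileup_site(bam, site, umi_mode = "read")
  expect_equal(rd$depth, 7L)
  # auto picks consensus when UB tags exist
  expect_equal(pileup_site(bam, site)$evidence, "umi")
})

test_that("pileup errors name the missing index and the absent chromosome", {
  site <- variant_sites("chr1", 1000, "C", "T")
  reads <- data.frame(pos = 1000, cigar = "10M", seq = "CAAAAAAAAA",
                      qual = "F", CB = "Z-1", UB = NA_character_,
                      stringsAsFactors = FALSE)
  bam <- make_test_bam(reads)
  file.remove(paste0(bam, ".bai"))
  expect_error(pileup_site(bam, site), "\\.bai")

  bam2 <- make_test_bam(reads)
  bad_site <- variant_sites("chrMissing", 1000, "C", "T")
  expect_error(pileup_site(bam2, bad_site), "chr1")
})

test_that("pileup equals a naive full-scan recount on simulated libraries", {
  site <- variant_sites("chr5", 2000, "G", "A", id = "s")
  for (seed in c(3, 17, 91)) {
    cfg <- sim_config(n_cells = 40, depth_lambda = 2, error_rate = 0.02,
                      umi_dup_mean = 1, spliced_fraction = 0.25, seed = seed)
    sim <- simulate_bam(cfg, site, tempfile())
    for (mode in c("consensus", "read")) {
      got <- pileup_site(sim$bam, site, umi_mode = mode)
      want <- naive_pileup(sim$bam, site, umi_mode = mode)
      expect_equal(got[, c("barcode", "n_ref", "n_alt", "n_other")], want,
                   ignore_attr = TRUE)
      # conservation: total counts = filter-passing observations
      expect_equal(sum(got$depth), sum(want$n_ref + want$n_alt + want$n_other))
    }
    # idempotence: same file, same table
    expect_identical(pileup_site(sim$bam, site),
                     pileup_site(sim$bam, site))
  }
})

test_that("a read whose N skip spans the site contributes nothing", {
  site <- variant_sites("chr1", 1000, "C", "T")
  reads <- data.frame(
    pos = c(971, 991),
    cigar = c("20M100N20M", "20M"),
    seq = c(strrep("T", 40), paste0(strrep("A", 9), "T", strrep("A", 10))),
    qual = "F", CB = c("SPL-1", "COV-1"), UB = NA_character_,
    stringsAsFactors = FALSE)
  bam <- make_test_bam(reads)
  got <- pileup_site(bam, site)
  expect_equal(got$barcode, "COV")   # spliced cell absent entirely
  expect_equal(got$n_alt, 1L)
})
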