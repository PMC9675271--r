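toy <- toy_genome()

# convenience: build a single-chromosome profile on toy chr1 (100 Mb,
# centromere 45-51 Mb), padding the remaining chromosomes with 1+1
one_chrom_profile <- function(rows, genome = toy) {
  Mb <- 1e6
  seg <- data.frame(chrom = "chr1", start = rows$start * Mb,
                    end = rows$end * Mb, major_cn = rows$major,
                    minor_cn = rows$minor)
  pad <- data.frame(chrom = genome$chrom[-1], start = 0,
                    end = genome$length[-1], major_cn = 1, minor_cn = 1)
  segment_profile("t", rbind(seg, pad), genome)
}

test_that("merging fuses equal-state neighbors and is idempotent", {
  p <- one_chrom_profile(data.frame(
    start = c(0, 10, 20), end = c(10, 20, 100),
    major = c(2, 2, 1), minor = c(0, 0, 1)))
  m <- merge_equal_segments(p)
  chr1 <- m[m$chrom == "chr1", ]
  expect_equal(nrow(chr1), 2L)
  expect_equal(chr1$end[1], 20e6)
  expect_identical(as.data.frame(merge_equal_segments(m)),
                   as.data.frame(m))
  # property: idempotence on random profiles
  for (s in 1:10) {
    m1 <- merge_equal_segments(random_profile(toy, seed = s))
    expect_identical(as.data.frame(merge_equal_segments(m1)),
                     as.data.frame(m1))
  }
})

test_that("LOH rule: length window and whole-chromosome exclusion", {
  # single 20 Mb 2+0 segment -> 1
  p <- one_chrom_profile(data.frame(
    start = c(0, 20, 40), end = c(20, 40, 100),
    major = c(2, 1, 1), minor = c(0, 1, 1)))
  expect_equal(loh_score(p, toy), 1)
  # whole-chromosome LOH is excluded
  p2 <- one_chrom_profile(data.frame(start = 0, end = 100,
                                     major = 2, minor = 0))
  expect_equal(loh_score(p2, toy), 0)
  # two abutting 10 Mb 2+0 segments merge to one event; a 14 Mb 1+0
  # stays under the 15 Mb threshold
  p3 <- one_chrom_profile(data.frame(
    start = c(0, 10, 20, 40, 54), end = c(10, 20, 40, 54, 100),
    major = c(2, 2, 1, 1, 1), minor = c(0, 0, 1, 0, 1)))
  expect_equal(loh_score(p3, toy), 1)
  expect_equal(oracle_loh(p3, toy), 1)
  # homozygous deletion (0+0) never counts
  p4 <- one_chrom_profile(data.frame(
    start = c(0, 20, 40), end = c(20, 40, 100),
    major = c(0, 1, 1), minor = c(0, 1, 1)))
  expect_equal(loh_score(p4, toy), 0)
})

test_that("TAI rule: telomere contact and centromere exclusion", {
  # 20 Mb 2+1 at the p telomere, centromere at 45 -> 1
  p <- one_chrom_profile(data.frame(
    start = c(0, 20), end = c(20, 100), major = c(2, 1), minor = c(1, 1)))
  expect_equal(tai_score(p, toy), 1)
  # segment spanning the centromere -> 0
  p2 <- one_chrom_profile(data.frame(
    start = c(0, 60), end = c(60, 100), major = c(2, 1), minor = c(1, 1)))
  expect_equal(tai_score(p2, toy), 0)
  # interstitial AI -> 0; both telomeres qualifying -> 2
  p3 <- one_chrom_profile(data.frame(
    start = c(0, 20, 50), end = c(20, 50, 100),
    major = c(1, 2, 1), minor = c(1, 1, 1)))
  expect_equal(tai_score(p3, toy), 0)
  p4 <- one_chrom_profile(data.frame(
    start = c(0, 20, 60), end = c(20, 60, 100),
    major = c(2, 1, 3), minor = c(1, 1, 1)))
  expect_equal(tai_score(p4, toy), 2)
  expect_equal(oracle_tai(p4, toy), 2)
})

test_that("LST rule: flank lengths, smoothing, centromere breakpoints", {
  # two adjacent 12 Mb segments on the p arm -> 1
  p <- one_chrom_profile(data.frame(
    start = c(0, 12, 24, 28), end = c(12, 24, 28, 100),
    major = c(1, 2, 1, 1), minor = c(1, 1, 0, 1)))
  # breakpoints: 12 (1+1|2+1 flanks 12/12 -> count), 24 (flank 4 -> no),
  # 28 (flank 4 -> no)
  expect_equal(lst_score(p, toy), 1)
  # single segment per chromosome -> 0
  p2 <- one_chrom_profile(data.frame(start = 0, end = 100,
                                     major = 2, minor = 1))
  expect_equal(lst_score(p2, toy), 0)
  # 12 Mb 1+1 + 2 Mb 3+1 + long 2+2 (short trailing flank): the 2 Mb
  # segment is smoothed into its longer neighbor, leaving exactly one
  # qualifying breakpoint
  p3 <- one_chrom_profile(data.frame(
    start = c(0, 12, 14, 97), end = c(12, 14, 97, 100),
    major = c(1, 3, 2, 1), minor = c(1, 1, 2, 1)))
  expect_equal(lst_score(p3, toy), 1)
  expect_equal(oracle_lst(p3, toy), 1)
  # breakpoint inside the centromere interval is not counted by default
  p4 <- one_chrom_profile(data.frame(
    start = c(0, 48), end = c(48, 100), major = c(2, 1), minor = c(2, 1)))
  expect_equal(lst_score(p4, toy), 0)
  expect_equal(lst_score(p4, toy, count_centromeric = TRUE), 1)
})

test_that("HRD sum and threshold rule follow the strict boundary", {
  expect_true(classify_hrd(hrd_sum(14, 14, 15)))    # 43 -> high
  expect_false(classify_hrd(hrd_sum(14, 14, 14)))   # 42 -> low
  expect_false(classify_hrd(hrd_sum(0, 0, 0)))
  expect_error(hrd_sum(-1, 0, 0), "nonnegative")
})

test_that("scores match the brute-force oracle on random profiles", {
  for (s in 1:30) {
    p <- random_profile(toy, seed = 100 + s)
    expect_equal(loh_score(p, toy), oracle_loh(p, toy), info = s)
    expect_equal(tai_score(p, toy), oracle_tai(p, toy), info = s)
    expect_equal(lst_score(p, toy), oracle_lst(p, toy), info = s)
  }
})

test_that("scores are invariant to chromosome order", {
  p <- random_profile(toy, seed = 42)
  perm <- as.data.frame(p)
  perm <- perm[order(match(perm$chrom, c("chr3", "chr5", "chr1",
                                         "chr4", "chr2"))), ]
  p2 <- segment_profile("t", perm, toy)
  expect_equal(loh_score(p2, toy), loh_score(p, toy))
  expect_equal(tai_score(p2, toy), tai_score(p, toy))
  expect_equal(lst_score(p2, toy), lst_score(p, toy))
})
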