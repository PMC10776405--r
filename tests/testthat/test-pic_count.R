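test_that("single-fragment contributions follow the three counting rules", {
  reg <- list(start = 90L, end = 200L)
  cases <- list(
    # both insertions inside: pic counts the pair once, insertion twice
    list(f = make_fragments("chr1", 100L, 151L, "A"), exp = c(pic = 1, insertion = 2, fragment = 1)),
    # one insertion inside
    list(f = make_fragments("chr1", 80L, 151L, "A"), exp = c(pic = 1, insertion = 1, fragment = 1)),
    # long-spanning fragment: insertions outside, interval covers the region
    list(f = make_fragments("chr1", 80L, 251L, "A"), exp = c(pic = 0, insertion = 0, fragment = 1)),
    # fully outside
    list(f = make_fragments("chr1", 300L, 400L, "A"), exp = c(pic = 0, insertion = 0, fragment = 0)))
  for (cs in cases)
    for (mode in c("pic", "insertion", "fragment"))
      expect_equal(count_fragment_in_region(cs$f, reg$start, reg$end, 0L, mode),
                   unname(cs$exp[mode]), info = mode)
})

test_that("flanking windows extend insertion mapping symmetrically", {
  # insertion loci at 210 and 299; region covers bases 90..199
  f <- make_fragments("chr1", 210L, 300L, "A")
  expect_equal(count_fragment_in_region(f, 90L, 200L, 0L, "pic"), 0L)
  expect_equal(count_fragment_in_region(f, 90L, 200L, 10L, "pic"), 0L)  # window reaches 200, region ends at 199
  expect_equal(count_fragment_in_region(f, 90L, 200L, 11L, "pic"), 1L)
  expect_equal(count_fragment_in_region(f, 90L, 200L, 11L, "insertion"), 1L)
})

test_that("shared insertion loci are counted twice by insertion mode but once per fragment by PIC", {
  regions <- toy_regions()
  frags <- make_fragments("chr1", c(100L, 150L), c(151L, 190L), c("A", "A"))
  pic <- build_count_matrix(frags, regions, mode = "pic")
  ins <- build_count_matrix(frags, regions, mode = "insertion")
  expect_equal(pic$counts["pA", "A"], 2)
  expect_equal(ins$counts["pA", "A"], 4)
})

test_that("a fragment with insertions in two regions contributes once to each", {
  regions <- toy_regions()
  f <- make_fragments("chr1", 150L, 500L, "A")   # loci 150 (pA) and 499 (pB)
  pic <- build_count_matrix(f, regions, mode = "pic")
  expect_equal(unname(pic$counts[, "A"]), c(1, 1, 0))
})

test_that("insertion mode equals twice PIC and fragment mode equals PIC for fully-inside fragments", {
  withr::local_seed(7)
  regions <- toy_regions()
  frags <- random_inside_fragments(300, regions, sprintf("c%02d", 1:20))
  frags <- frags[frags$end - frags$start >= 2, ]
  pic <- build_count_matrix(frags, regions, mode = "pic", dedup = FALSE)
  ins <- build_count_matrix(frags, regions, mode = "insertion", dedup = FALSE)
  frg <- build_count_matrix(frags, regions, mode = "fragment", dedup = FALSE)
  expect_equal(as.matrix(ins$counts), 2 * as.matrix(pic$counts))
  expect_equal(as.matrix(frg$counts), as.matrix(pic$counts))
})

test_that("counting invariants hold on arbitrary fragments", {
  withr::local_seed(8)
  regions <- toy_regions()
  frags <- random_fragments(400, sprintf("c%02d", 1:10))
  for (flank in c(0L, 37L)) {
    pic <- as.matrix(build_count_matrix(frags, regions, mode = "pic", flank = flank)$counts)
    ins <- as.matrix(build_count_matrix(frags, regions, mode = "insertion", flank = flank)$counts)
    frg <- as.matrix(build_count_matrix(frags, regions, mode = "fragment", flank = flank)$counts)
    expect_true(all(pic <= frg))
    expect_true(all(ins <= 2 * pic))
  }
  # permuting fragment order leaves the matrix unchanged
  perm <- sample(nrow(frags))
  m1 <- build_count_matrix(frags, regions, mode = "pic")
  m2 <- build_count_matrix(frags[perm, ], regions, mode = "pic")
  expect_equal(as.matrix(m1$counts), as.matrix(m2$counts))
})

test_that("no fragments or out-of-range fragments yield all-zero matrices", {
  regions <- toy_regions()
  empty <- build_count_matrix(make_fragments(character(0), integer(0),
                                             integer(0), character(0)),
                              regions, cells = "A", mode = "pic")
  expect_equal(sum(empty$counts), 0)
  far <- make_fragments("chr9", c(10L, 50L), c(40L, 90L), c("A", "A"))
  for (mode in c("pic", "insertion", "fragment"))
    expect_equal(sum(build_count_matrix(far, regions, mode = mode)$counts), 0)
})

test_that("duplicate handling multiplies contributions only when duplicates are retained", {
  regions <- toy_regions()
  f <- make_fragments("chr1", 100L, 151L, "A", dup_count = 3L)
  expect_equal(build_count_matrix(f, regions, mode = "pic", dedup = TRUE)$counts["pA", "A"], 1)
  expect_equal(build_count_matrix(f, regions, mode = "pic", dedup = FALSE)$counts["pA", "A"], 3)
  expect_equal(build_count_matrix(f, regions, mode = "insertion", dedup = FALSE)$counts["pA", "A"], 6)
})

test_that("high-density frequencies reproduce the stated conditional probabilities", {
  # one region; counts 1,1,1,1,2,2,2,3,3,4 -> f = (4,3,2,1)
  counts <- matrix(c(1, 1, 1, 1, 2, 2, 2, 3, 3, 4), nrow = 1)
  regions <- data.frame(chrom = "chr1", start = 0L, end = 500L, region_id = "r1")
  m <- CountMatrix(Matrix::Matrix(counts, sparse = TRUE), regions,
                   sprintf("c%d", 1:10), mode = "pic")
  st <- high_density_stats(m, groups = rep("g", 10), min_high_cells = 3L)
  expect_equal(st$p_ge3_given_pos, 3 / 10)
  expect_equal(st$p_eq2_given_12, 3 / 7)
  expect_true(st$pass_filter)

  # all-zero region: both ratios undefined
  z <- CountMatrix(Matrix::Matrix(0, 1, 10, sparse = TRUE), regions,
                   sprintf("c%d", 1:10), mode = "pic")
  stz <- high_density_stats(z, groups = rep("g", 10))
  expect_true(is.na(stz$p_ge3_given_pos) && is.na(stz$p_eq2_given_12))

  # capped-at-4 matrix with f = (0,0,5,5)
  cc <- matrix(c(3, 3, 3, 3, 3, 4, 4, 4, 4, 4), nrow = 1)
  mc <- CountMatrix(Matrix::Matrix(cc, sparse = TRUE), regions,
                    sprintf("c%d", 1:10), mode = "pic")
  expect_equal(high_density_stats(mc, rep("g", 10))$p_ge3_given_pos, 1)
})

test_that("count capping ceilings stored values", {
  regions <- toy_regions()
  m <- CountMatrix(Matrix::Matrix(rbind(c(0, 9), c(2, 0), c(5, 1)), sparse = TRUE),
                   regions, c("a", "b"), mode = "pic")
  expect_equal(max(cap_counts(m, 4)$counts), 4)
})
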