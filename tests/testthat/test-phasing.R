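# Register assignment, phasing statistic, siRNA naming, tissue tables.

mkwin <- function(pos, counts = 1L, lib = "all", anchor = 100L,
                  len = 21L, cycles = 10L) {
  phasing_window("locus", anchor,
                 data.frame(position = pos, length = len,
                            count = rep(counts, length.out = length(pos)),
                            library = rep(lib, length.out = length(pos))),
                 cycles = cycles)
}

test_that("register assignment follows (position - anchor) mod 21", {
  p <- assign_registers(mkwin(c(100, 121, 142)))
  expect_equal(unname(p$counts[["0"]]), 3)
  expect_equal(p$dominant, 0L)
  expect_equal(p$phase_fraction, 1)
  p2 <- assign_registers(mkwin(101))
  expect_equal(p2$dominant, 1L)
  expect_equal(unname(p2$counts[["1"]]), 1)
  # non-21-nt reads are excluded and logged
  w <- phasing_window("x", 100, data.frame(position = c(100, 121),
                                           length = c(21, 24),
                                           count = c(2L, 5L)))
  expect_equal(w$excluded_non21, 5L)
  expect_equal(assign_registers(w)$total, 2)
})

test_that("anchor shifts act as expected on the register profile", {
  pos <- c(100, 103, 121, 130, 142, 150)
  base <- assign_registers(mkwin(pos))
  shift21 <- assign_registers(phasing_window("x", 100 - 21, data.frame(
    position = pos, length = 21, count = 1L), cycles = 12))
  expect_equal(unname(base$counts), unname(shift21$counts))
  shift1 <- assign_registers(phasing_window("x", 99, data.frame(
    position = pos, length = 21, count = 1L), cycles = 10))
  expect_equal(unname(shift1$counts), unname(base$counts[c(21, 1:20)]))
})

test_that("uniform random positions give phase fraction near 1/21", {
  set.seed(41)
  pos <- sample(100:(100 + 21 * 10), 10000, replace = TRUE)
  p <- assign_registers(mkwin(pos))
  phat <- max(p$counts) / p$total
  # dominant-register share of a uniform multinomial: compare against the
  # binomial sd around 1/21 (the max inflates slightly; 3 sigma + selection)
  expect_lt(abs(phat - 1 / 21), 4 * sqrt((1 / 21) * (20 / 21) / 10000))
})

test_that("phasing statistic behaves at the extremes", {
  p <- assign_registers(mkwin(rep(100, 100)))
  st <- phase_statistic(p)
  expect_equal(st$phase_fraction, 1)
  expect_lt(st$p_value, 1e-6)
  u <- assign_registers(mkwin(100 + 0:20))
  stu <- phase_statistic(u)
  expect_equal(stu$phase_fraction, 1 / 21)
  expect_equal(stu$p_value, 1)
  small <- assign_registers(mkwin(c(100, 121)))
  expect_equal(phase_statistic(small)$status, "under-supported")
})

test_that("phased siRNA names are signed offsets and round-trip", {
  expect_equal(name_phased_sirna("TAS4", 19, 100), "TAS4-siRNA(-81)")
  expect_equal(name_phased_sirna("TAS4", 100, 100), "TAS4-siRNA(+0)")
  set.seed(42)
  offs <- sample(-200:200, 30)
  labs <- name_phased_sirna("L", 500 + offs, 500)
  expect_equal(vapply(labs, parse_phased_sirna, integer(1),
                      USE.NAMES = FALSE), offs)
  expect_error(parse_phased_sirna("not-a-label"), "label")
})

test_that("tissue accumulation fractions sum to one and find the modal tissue", {
  w <- mkwin(c(100, 121, 142, 163), counts = c(5L, 3L, 1L, 1L),
             lib = c("root", "root", "leaf", "flower"))
  acc <- tissue_accumulation(assign_registers(w))
  expect_equal(sum(acc$fraction), 1)
  expect_equal(acc$library[which.max(acc$fraction)], "root")
  eq <- mkwin(rep(100, 4), lib = c("a", "b", "c", "d"))
  expect_equal(tissue_accumulation(assign_registers(eq))$fraction,
               rep(0.25, 4))
})

test_that("phase-fraction recovery across 100 simulated TAS loci", {
  set.seed(43)
  noise <- 0.2
  cycles <- 8L
  fracs <- replicate(100, {
    n <- 400L
    n_off <- rbinom(1, n, noise)
    pos_in <- 100 + 21 * sample(0:(cycles - 1), n - n_off, TRUE)
    pos_off <- 100 + 21 * sample(0:(cycles - 2), n_off, TRUE) +
      sample(1:20, n_off, TRUE)
    p <- assign_registers(mkwin(c(pos_in, pos_off), cycles = cycles))
    p$counts[["0"]] / p$total
  })
  expected <- 1 - noise
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - expected), 3 * se + 0.01)
})

test_that("TAS loci in the simulated study are root/leaf-skewed as planted", {
  w <- tiny_world()
  proc <- tiny_processed()
  for (tas in w$tas) {
    reads <- transcript_read_positions(proc$tags, w$transcriptome[[tas$id]],
                                       proc$libraries)
    prof <- assign_registers(phasing_window(tas$id, tas$cleavage_pos, reads))
    expect_equal(prof$dominant, 0L)
    expect_gt(prof$phase_fraction, 0.5)
    acc <- tissue_accumulation(prof)
    modal <- acc$library[which.max(acc$fraction)]
    expect_equal(modal,
                 names(which.max(tas$tissue_profile)))
    expect_equal(sum(prof$counts), sum(prof$by_library))
  }
})
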