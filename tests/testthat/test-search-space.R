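test_that("big-integer arithmetic matches independently computed digits", {
  expect_identical(format(bigint("12345678901234567890123456789")),
                   "12345678901234567890123456789")
  expect_identical(format(robunet:::big_mul(bigint(99999), bigint(99999))),
                   format(bigint(99999^2)))
  expect_identical(format(robunet:::big_add(bigint("99999999999999999999"),
                                            bigint(1))),
                   "100000000000000000000")
  # digits frozen from an independent arbitrary-precision evaluation
  expect_identical(format(robunet:::big_pow(bigint(450), 10L)),
                   "340506289160156250000000000")
})

test_that("block configuration counts follow the candidate-set product", {
  expect_identical(count_block_configs(unet_space()), 450L)
  expect_identical(count_block_configs(unet_space(), se_allowed = FALSE), 90L)
  expect_identical(
    count_block_configs(unet_space(patterns = 1L, filters = 8L)), 5L)
})

test_that("exact space count matches the closed form and brute force", {
  expect_identical(format(count_search_space(unet_space())),
                   "340507970680999119131250000")
  expect_lt(abs(as.numeric(count_search_space(unet_space())) - 3.4e26),
            0.05e26)
  expect_identical(format(count_search_space(unet_space(), depths = 1L)),
                   "202500")
  expect_identical(format(count_search_space(unet_space(),
                                             depths = integer(0))), "0")
  expect_error(count_search_space(unet_space(), depths = c(2, 6)), "1..5")

  # brute-force enumeration of a reduced space: 2 patterns x 1 filter x
  # SE off, depths 1 and 2
  sp <- unet_space(patterns = c(1L, 2L), filters = 8L, se_allowed = FALSE,
                   depths = 1:2)
  block_choices <- expand.grid(pattern = sp$patterns, filters = sp$filters)
  b <- nrow(block_choices)
  brute <- sum(vapply(sp$depths, function(d) b^(2 * d), numeric(1)))
  expect_identical(as.numeric(count_search_space(sp)), brute)
})

test_that("uniform sampling is seeded, valid, and covers depths evenly", {
  sp <- unet_space()
  set.seed(1); g1 <- sample_genotype(sp)
  set.seed(1); g2 <- sample_genotype(sp)
  expect_identical(g1, g2)

  set.seed(42)
  n <- 4000L
  depths <- integer(n)
  for (i in seq_len(n)) {
    g <- sample_genotype(sp)
    expect_silent(validate_genotype(g, sp))
    depths[i] <- g$depth
  }
  # binomial 3-sigma band around 1/4 per depth
  p <- 0.25
  tol <- 3 * sqrt(p * (1 - p) / n)
  for (d in 2:5) expect_lt(abs(mean(depths == d) - p), tol)
})

test_that("pattern bitstrings use branch A1 as the most significant bit", {
  expect_identical(pattern_to_bits(c(1L, 14L, 15L)), c("0001", "1110", "1111"))
  expect_identical(bits_to_pattern(c("0001", "1110", "1111")), c(1L, 14L, 15L))
  expect_error(bits_to_pattern("0000"), "at least one branch")
  expect_error(bits_to_pattern("201"), "bitstring")
})

test_that("record serialization round-trips and validates while parsing", {
  set.seed(7)
  for (i in 1:200) {
    g <- sample_genotype(unet_space())
    expect_identical(record_to_genotype(genotype_to_record(g)), g)
  }
  bad <- genotype_to_record(tiny_genotype())
  bad$encoders[[1]]$pattern <- NULL
  expect_error(record_to_genotype(bad), "pattern")
  bad2 <- genotype_to_record(tiny_genotype())
  bad2$decoders <- bad2$decoders[0]
  expect_error(record_to_genotype(bad2), "decoders")
})

test_that("the shipped reference architecture parses and validates", {
  g <- searched_genotype()
  expect_s3_class(g, "unet_genotype")
  expect_identical(g$depth, 5L)
  expect_silent(validate_genotype(g, unet_space()))
  expect_identical(pattern_to_bits(vapply(g$encoders, `[[`, integer(1),
                                          "pattern")),
                   c("1110", "0110", "0111", "1110", "0010"))
  expect_identical(vapply(g$decoders, `[[`, integer(1), "filters"),
                   c(8L, 128L, 64L, 128L, 8L))
  # JSON round trip through disk
  path <- tempfile(fileext = ".json")
  write_genotype(g, path)
  expect_identical(read_genotype(path), g)
})

test_that("block invariants are enforced", {
  expect_error(block_config(0, 8), "1..15")
  expect_error(block_config(16, 8), "1..15")
  expect_error(block_config(3, 8, se = TRUE), "se_ratio")
  bc <- block_config(3, 8, se = FALSE, se_ratio = 4)  # ratio dropped
  expect_null(bc$se_ratio)
  expect_error(validate_genotype(
    genotype(list(block_config(1, 7)), list(block_config(1, 8))),
    unet_space()), "outside the space")
})
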