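small_cfg <- function(...) {
  defaults <- list(n_binders = 2L, enrichment_factor = 1.8,
                   n_background = 200L, n_rounds = 5L,
                   reads_per_round = 2000L, error_rate = 0,
                   byproduct_fraction = 0, seed = 99L)
  args <- utils::modifyList(defaults, list(...))
  do.call(selex_sim_config, args)
}

test_that("pool weights follow geometric binder growth and normalize", {
  cfg <- small_cfg(n_binders = 1L, enrichment_factor = 2, n_background = 1L,
                   n_rounds = 3L)
  # round 1: factor^0 = 1, uniform over binder + background
  expect_equal(unname(simulate_pool_weights(cfg, 1L)), c(0.5, 0.5))
  # 1 binder, factor 2, 1 background, round 3: binder frequency 2^2/(2^2+1)
  w3 <- simulate_pool_weights(cfg, 3L)
  expect_equal(unname(w3), c(4 / 5, 1 / 5))

  set.seed(1)
  for (i in 1:5) {
    cfg <- small_cfg(n_binders = sample(1:5, 1),
                     enrichment_factor = stats::runif(1, 1.1, 3),
                     n_background = sample(10:100, 1))
    r <- sample.int(cfg$n_rounds, 1)
    w <- simulate_pool_weights(cfg, r)
    expect_equal(sum(w), 1)
    expect_true(all(w > 0))
    # binder weight ratio to background is exactly factor^(r-1)
    expect_equal(w[[1]] / w[[length(w)]], cfg$enrichment_factor^(r - 1))
  }
  expect_error(simulate_pool_weights(cfg, 0L))
  expect_error(simulate_pool_weights(cfg, cfg$n_rounds + 1L))
})

test_that("by-product chimeras always violate the length window", {
  design <- library_design()
  set.seed(5)
  a <- random_bases(40)
  b <- random_bases(40)
  # fixed minimal elongation: 40 + 2 + 3 = 45 nt
  chim <- make_byproduct(a, b, design, extra = 3L)
  expect_equal(nchar(chim), 45L)
  r <- find_flanks(paste0(design$flank5, chim, design$flank3), design)
  expect_equal(r$status, "LENGTH_FAIL")

  # closure against extraction across the elongation range
  for (i in 1:40) {
    extra <- sample(3:38, 1L)
    chim <- make_byproduct(random_bases(40), random_bases(40), design,
                           extra = extra)
    expect_equal(nchar(chim), 42L + extra)
    read <- paste0(design$flank5, chim, design$flank3)
    expect_equal(find_flanks(read, design)$status, "LENGTH_FAIL")
    # prefix comes from parent a, suffix from parent b
  }
  expect_error(make_byproduct(random_bases(40), random_bases(40), design,
                              extra = 50L), "infeasible|exceed")
})

test_that("simulated rounds are byte-reproducible for a fixed seed", {
  cfg <- small_cfg(error_rate = 0.01, byproduct_fraction = 0.1,
                   reads_per_round = 500L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_round(cfg, 2L, dir = d1)
  s2 <- simulate_round(cfg, 2L, dir = d2)
  for (f in c("r1", "r2", "truth")) {
    expect_identical(readBin(s1$paths[[f]], "raw", file.size(s1$paths[[f]])),
                     readBin(s2$paths[[f]], "raw", file.size(s2$paths[[f]])))
  }
  # different rounds draw from different streams
  s3 <- simulate_round(cfg, 3L)
  expect_false(identical(s1$r1$bases, s3$r1$bases))
})

test_that("simulator output is clean at zero error and zero by-product", {
  cfg <- small_cfg(reads_per_round = 1000L)
  sim <- simulate_round(cfg, 4L)
  expect_equal(nrow(sim$truth), 1000L)  # label conservation
  expect_true(all(sim$truth$class %in% c("binder", "background")))
  expect_true(all(sim$truth$n_substitutions == 0L))
  res <- extract_pool(sim$r1$bases, sim$r2$bases, design = cfg$design)
  expect_equal(res$ledger$pass_fraction, 1.0)
  # extracted inserts equal the ground-truth inserts, in order
  expect_equal(res$inserts, sim$truth$true_insert)
})

test_that("by-product fraction surfaces as LENGTH_FAIL at the configured rate", {
  cfg <- small_cfg(byproduct_fraction = 0.2, reads_per_round = 4000L)
  sim <- simulate_round(cfg, 1L)
  expect_equal(nrow(sim$truth), 4000L)
  res <- extract_pool(sim$r1$bases, sim$r2$bases, design = cfg$design)
  frac <- res$ledger$counts[["LENGTH_FAIL"]] / res$ledger$total
  se <- sqrt(0.2 * 0.8 / 4000)
  expect_lt(abs(frac - 0.2), 3 * se)
  # ground truth agrees read-for-read with the extraction verdict
  verdicts <- res$results$status
  expect_true(all(verdicts[sim$truth$class == "byproduct"] == "LENGTH_FAIL"))
  expect_true(all(verdicts[sim$truth$class != "byproduct"] == "PASS"))
})

test_that("substitution error hits extraction only through the flanks", {
  cfg <- small_cfg(error_rate = 0.01, reads_per_round = 4000L)
  sim <- simulate_round(cfg, 1L)
  res <- extract_pool(sim$r1$bases, sim$r2$bases, design = cfg$design)
  # reads whose flanks were untouched always pass; flank-hit reads cannot
  # (max_mismatch = 0)
  expect_true(all(res$results$status[!sim$truth$flank_mutated] == "PASS"))
  expect_true(all(res$results$status[sim$truth$flank_mutated] != "PASS"))
  p_pass <- expected_pass_fraction(cfg$design, 0.01)
  se <- sqrt(p_pass * (1 - p_pass) / 4000)
  expect_lt(abs(res$ledger$pass_fraction - p_pass), 3 * se)
})

test_that("final-round binder frequencies match expectation within 3 SE", {
  cfg <- small_cfg(n_binders = 3L, n_background = 500L,
                   reads_per_round = 20000L, n_rounds = 8L)
  w <- simulate_pool_weights(cfg, 8L)
  sim <- simulate_round(cfg, 8L)
  tally <- table(sim$truth$source)
  for (b in sprintf("binder%d", 1:3)) {
    exp_n <- cfg$reads_per_round * w[[b]]
    se <- sqrt(cfg$reads_per_round * w[[b]] * (1 - w[[b]]))
    obs <- if (b %in% names(tally)) as.integer(tally[[b]]) else 0L
    expect_lt(abs(obs - exp_n), 3 * se)
  }
})

test_that("config invariants are enforced", {
  expect_error(small_cfg(enrichment_factor = 1))
  expect_error(small_cfg(error_rate = 1.5))
  expect_error(small_cfg(byproduct_fraction = -0.1))
  expect_error(small_cfg(reads_per_round = 0L))
  expect_error(small_cfg(byproduct_extra_length = c(3L, 39L)), "exceed")
  # universe sequences are distinct and of design length
  cfg <- small_cfg()
  expect_false(anyDuplicated(cfg$universe) > 0)
  expect_true(all(nchar(cfg$universe) == 40L))
})
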