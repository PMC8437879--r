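design <- library_design()

test_that("printed candidate inserts are recovered from flanked constructs, both strands", {
  for (nm in names(sp_sequences)) {
    ins <- sp_sequences[[nm]]
    read <- paste0(design$flank5, ins, design$flank3)

    fwd <- find_flanks(read, design)
    expect_equal(fwd$status, "PASS")
    expect_equal(fwd$insert, ins, ignore_attr = TRUE)
    expect_equal(fwd$insert_length, 40L)
    expect_equal(fwd$orientation, "forward")
    expect_equal(fwd$mismatches5 + fwd$mismatches3, 0L)

    rev <- find_flanks(oracle_revcomp(read), design)
    expect_equal(rev$status, "PASS")
    expect_equal(rev$insert, ins, ignore_attr = TRUE)
    expect_equal(rev$orientation, "reverse")
  }
})

test_that("inserts outside the 38-42 nt window fail on length", {
  set.seed(101)
  # 37 nt: just below the window
  r37 <- find_flanks(paste0(design$flank5, random_bases(37), design$flank3),
                     design)
  expect_equal(r37$status, "LENGTH_FAIL")
  expect_true(is.na(r37$insert))

  # 50 nt by-product-like insert; brute-force enumeration confirms no
  # alternative flank placement rescues the read
  read50 <- paste0(design$flank5, random_bases(50), design$flank3)
  expect_equal(find_flanks(read50, design)$status, "LENGTH_FAIL")
  expect_equal(oracle_find_flanks(read50, design)$status, "LENGTH_FAIL")

  # window boundaries are inclusive
  for (len in c(38L, 42L)) {
    r <- find_flanks(paste0(design$flank5, random_bases(len), design$flank3),
                     design)
    expect_equal(r$status, "PASS")
    expect_equal(r$insert_length, len)
  }
})

test_that("failure statuses follow the flank5 -> flank3 -> length order", {
  set.seed(7)
  expect_equal(find_flanks(random_bases(60), design)$status, "NO_FLANK5")
  expect_equal(find_flanks(paste0(design$flank5, random_bases(40)),
                           design)$status, "NO_FLANK3")
  # flank3 upstream of flank5 is not a valid layout
  expect_equal(find_flanks(paste0(design$flank3, random_bases(40),
                                  design$flank5), design)$status,
               "NO_FLANK3")
  # N inside the insert of an otherwise valid layout
  ins <- random_bases(40)
  substr(ins, 20, 20) <- "N"
  expect_equal(find_flanks(paste0(design$flank5, ins, design$flank3),
                           design)$status, "AMBIGUOUS_BASE")
})

test_that("flank mismatch tolerance is honored and opt-in", {
  set.seed(8)
  ins <- random_bases(40)
  f5_mut <- design$flank5
  substr(f5_mut, 4, 4) <- setdiff(c("A", "C", "G", "T"),
                                  substr(f5_mut, 4, 4))[1]
  read <- paste0(f5_mut, ins, design$flank3)
  expect_equal(find_flanks(read, design)$status, "NO_FLANK5")
  tol1 <- library_design(max_mismatch = 1L)
  r <- find_flanks(read, tol1)
  expect_equal(r$status, "PASS")
  expect_equal(r$mismatches5, 1L)
  expect_equal(r$mismatches3, 0L)
  expect_equal(r$insert, ins, ignore_attr = TRUE)
})

test_that("exact-match PASS inserts reconstruct a substring of the read", {
  set.seed(13)
  for (i in 1:200) {
    read <- random_test_read(design)
    r <- find_flanks(read, design)
    if (r$status != "PASS") next
    wrapped <- paste0(design$flank5, r$insert, design$flank3)
    expect_true(grepl(wrapped, read, fixed = TRUE) ||
                  grepl(wrapped, oracle_revcomp(read), fixed = TRUE))
  }
})

test_that("find_flanks agrees with brute-force enumeration of all placements", {
  set.seed(21)
  for (des in list(design, library_design(max_mismatch = 1L))) {
    for (i in 1:150) {
      read <- random_test_read(des)
      got <- find_flanks(read, des)
      want <- oracle_find_flanks(read, des)
      expect_equal(got$status, want$status, label = read)
      if (want$status == "PASS") {
        expect_equal(got$insert, want$insert, ignore_attr = TRUE, label = read)
        expect_equal(got$orientation, want$orientation, ignore_attr = TRUE)
      }
    }
  }
})

test_that("raising tolerances never decreases the PASS count", {
  set.seed(31)
  reads <- vapply(1:300, function(i) random_test_read(design), "")
  pass_count <- function(des) sum(scan_reads(reads, des)$status == "PASS")
  base <- pass_count(design)
  expect_gte(pass_count(library_design(max_mismatch = 1L)), base)
  expect_gte(pass_count(library_design(max_mismatch = 2L)),
             pass_count(library_design(max_mismatch = 1L)))
  expect_gte(pass_count(library_design(length_tolerance = 5L)), base)
  expect_gte(pass_count(library_design(length_tolerance = 5L,
                                       max_mismatch = 2L)), base)
})

test_that("pair reconciliation follows exactly-one-wins / agree-or-discard", {
  set.seed(41)
  x <- random_bases(40)
  y <- random_bases(40)
  wrap <- function(ins) paste0(design$flank5, ins, design$flank3)
  junk <- random_bases(60)

  r <- extract_pair(wrap(x), junk, design)
  expect_equal(r$status, "PASS")
  expect_equal(r$insert, x, ignore_attr = TRUE)

  r <- extract_pair(junk, wrap(x), design)
  expect_equal(r$status, "PASS")
  expect_equal(r$insert, x, ignore_attr = TRUE)

  # both pass, identical inserts (r2 as the biological reverse mate)
  r <- extract_pair(wrap(x), oracle_revcomp(wrap(x)), design)
  expect_equal(r$status, "PASS")
  expect_equal(r$insert, x, ignore_attr = TRUE)
  expect_equal(r$orientation, "forward")

  # both pass with different inserts
  r <- extract_pair(wrap(x), wrap(y), design)
  expect_equal(r$status, "DISCORDANT_PAIR")
  expect_true(is.na(r$insert))
  r <- extract_pair(wrap(x), wrap(y), design, on_discordant = "keep_r1")
  expect_equal(r$status, "PASS")
  expect_equal(r$insert, x, ignore_attr = TRUE)

  # neither passes: the forward mate's failure status
  r <- extract_pair(paste0(design$flank5, random_bases(37), design$flank3),
                    junk, design)
  expect_equal(r$status, "LENGTH_FAIL")
})

test_that("the QC ledger counts every input exactly once", {
  set.seed(51)
  wrap <- function(ins) paste0(design$flank5, ins, design$flank3)
  good <- vapply(1:10, function(i) wrap(random_bases(40)), "")
  flankless <- vapply(1:2, function(i) random_bases(76), "")
  res <- extract_pool(c(good, flankless), design = design)
  expect_length(res$inserts, 10L)
  expect_equal(res$ledger$counts[["PASS"]], 10L)
  expect_equal(res$ledger$counts[["NO_FLANK5"]], 2L)
  expect_equal(sum(res$ledger$counts), res$ledger$total)
  expect_equal(res$ledger$total, 12L)

  empty <- extract_pool(character(0), design = design)
  expect_length(empty$inserts, 0L)
  expect_equal(empty$ledger$total, 0L)
  expect_true(is.na(empty$ledger$pass_fraction))

  # conservation on arbitrary mixed reads, single- and paired-end
  reads <- vapply(1:250, function(i) random_test_read(design), "")
  res <- extract_pool(reads, design = design)
  expect_equal(sum(res$ledger$counts), 250L)
  mates <- vapply(reads, oracle_revcomp, "", USE.NAMES = FALSE)
  res2 <- extract_pool(reads, mates, design = design)
  expect_equal(sum(res2$ledger$counts), 250L)
})

test_that("QC ledger JSON is well-formed", {
  set.seed(61)
  reads <- vapply(1:50, function(i) random_test_read(design), "")
  res <- extract_pool(reads, design = design)
  js <- jsonlite::fromJSON(qc_ledger_json(res$ledger))
  expect_equal(js$total_reads, 50L)
  expect_equal(sum(unlist(js$status_counts)), 50L)
  expect_equal(js$pass_fraction, res$ledger$pass_fraction)
})
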