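# Independent brute-force implementations used as oracles. These share no
# code with the package internals: plain R loops over every (offset5,
# offset3, strand) triple.

oracle_hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

oracle_revcomp <- function(s) {
  comp <- chartr("ACGTN", "TGCAN", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# Enumerate all flank placements on one strand. Returns the progress level
# (0 none, 1 flank5 only, 2 flank5+flank3, 3 in-window layout found) and
# the best candidate under the tie-break rules: fewest total mismatches,
# insert length closest to n_length, leftmost flank5, leftmost flank3.
oracle_scan_strand <- function(s, design) {
  f5 <- design$flank5; f3 <- design$flank3
  l5 <- nchar(f5); l3 <- nchar(f3); L <- nchar(s)
  lo <- design$n_length - design$length_tolerance
  hi <- design$n_length + design$length_tolerance
  level <- 0L
  best <- NULL
  if (L >= l5) {
    for (i in seq_len(L - l5 + 1L)) {
      mm5 <- oracle_hamming(substr(s, i, i + l5 - 1L), f5)
      if (mm5 > design$max_mismatch) next
      level <- max(level, 1L)
      j_start <- i + l5
      if (j_start > L - l3 + 1L) next
      for (j in seq.int(j_start, L - l3 + 1L)) {
        mm3 <- oracle_hamming(substr(s, j, j + l3 - 1L), f3)
        if (mm3 > design$max_mismatch) next
        level <- max(level, 2L)
        len <- j - (i + l5)
        if (len < lo || len > hi) next
        level <- 3L
        cand <- list(mm5 = mm5, mm3 = mm3, off5 = i, off3 = j, len = len)
        if (is.null(best)) {
          best <- cand
        } else {
          key_new <- c(cand$mm5 + cand$mm3, abs(cand$len - design$n_length),
                       cand$off5, cand$off3)
          key_old <- c(best$mm5 + best$mm3, abs(best$len - design$n_length),
                       best$off5, best$off3)
          cmp <- key_new - key_old
          first <- which(cmp != 0)[1]
          if (!is.na(first) && cmp[first] < 0) best <- cand
        }
      }
    }
  }
  list(level = level, best = best)
}

oracle_find_flanks <- function(bases, design) {
  fwd <- oracle_scan_strand(bases, design)
  rev <- oracle_scan_strand(oracle_revcomp(bases), design)
  lev <- max(fwd$level, rev$level)
  if (lev < 3L) {
    status <- c("NO_FLANK5", "NO_FLANK3", "LENGTH_FAIL")[lev + 1L]
    return(list(status = status, insert = NA_character_,
                orientation = NA_character_))
  }
  use_fwd <- fwd$level == 3L
  src <- if (use_fwd) bases else oracle_revcomp(bases)
  b <- if (use_fwd) fwd$best else rev$best
  ins <- substr(src, b$off5 + nchar(design$flank5),
                b$off5 + nchar(design$flank5) + b$len - 1L)
  if (grepl("[^ACGT]", ins)) {
    return(list(status = "AMBIGUOUS_BASE", insert = NA_character_,
                orientation = NA_character_))
  }
  list(status = "PASS", insert = ins,
       orientation = if (use_fwd) "forward" else "reverse",
       mismatches5 = b$mm5, mismatches3 = b$mm3, insert_length = b$len)
}

# Random test-read generator: a mixture of pure random reads, clean
# planted constructs (optionally reverse-complemented, flank-mutated,
# length-shifted, N-contaminated or embedded in random context) designed
# to exercise every verdict.
random_bases <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_test_read <- function(design, max_len = 120L) {
  kind <- sample(c("random", "construct"), 1L, prob = c(0.35, 0.65))
  if (kind == "random") {
    return(random_bases(sample(20:max_len, 1L)))
  }
  ins_len <- sample(30:50, 1L)
  ins <- random_bases(ins_len)
  if (stats::runif(1) < 0.1) {
    p <- sample.int(ins_len, 1L)
    substr(ins, p, p) <- "N"
  }
  read <- paste0(design$flank5, ins, design$flank3)
  if (stats::runif(1) < 0.3) {  # mutate a flank base
    p <- sample(c(seq_len(nchar(design$flank5)),
                  nchar(read) - seq_len(nchar(design$flank3)) + 1L), 1L)
    old <- substr(read, p, p)
    substr(read, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  room <- max_len - nchar(read)
  if (room > 0L && stats::runif(1) < 0.4) {  # random sequencing context
    pre <- sample(0:room, 1L)
    read <- paste0(random_bases(pre), read, random_bases(room - pre))
  }
  if (stats::runif(1) < 0.5) read <- oracle_revcomp(read)
  read
}

# Deterministic multiset tally oracle for collapse: environment dictionary.
oracle_tally <- function(x) {
  env <- new.env(hash = TRUE)
  for (s in x) {
    assign(s, (if (exists(s, envir = env, inherits = FALSE))
      get(s, envir = env)
    else 0L) + 1L, envir = env)
  }
  keys <- ls(env, sorted = TRUE)
  stats::setNames(vapply(keys, get, 0L, envir = env), keys)
}

# Reference constants shared across tests: the default design's three
# known 40-nt candidate inserts and a late-round read-count spectrum.
sp_sequences <- c(
  SP1 = "CACTCTCACCTTCCTGTCACTCCTTTTTTCACTCTCACTC",
  SP2 = "CACTCACTCTTTCCCTTATCTGCTCACTCTTCATTCACTC",
  SP3 = "CACCGTCCTTTTCTAGCATCTCTGTCACTCTTTCTCACTC"
)
table4_counts <- c(252L, 61L, 53L, 48L, 41L, 37L, 37L, 37L, 33L, 30L, 29L,
                   28L, 28L, 28L, 26L)

# A pool with the given count spectrum over distinct random sequences
pool_from_counts <- function(counts, design = library_design(),
                             label = "round14") {
  seqs <- character(length(counts))
  repeat {
    seqs <- vapply(seq_along(counts), function(i)
      random_bases(design$n_length), "")
    if (!anyDuplicated(seqs)) break
  }
  collapse_reads(rep(seqs, counts), label)
}
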