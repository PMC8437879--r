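# Run code under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_inserts <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste, collapse = "")
}

#' Configure a synthetic SELEX sequencing experiment
#'
#' Defines a multi-round Cell-SELEX simulation: a handful of true binder
#' sequences whose pool weight grows geometrically each round against a
#' large set of non-enriching background sequences, with substitution
#' sequencing error and elongated PCR by-product chimeras. Every read
#' carries ground-truth labels, so the extraction/collapse/ranking
#' pipeline can be validated against known answers.
#'
#' Defaults emulate the study conditions this simulator is meant to mirror:
#' a 14-round selection on the default N40 library, a few binders at a
#' modest per-round enrichment factor, Illumina-like per-base substitution
#' error (1e-3, roughly Q30), and a 5% by-product fraction. The by-product
#' elongation range is 3--38 nt: a chimera joins a prefix (at least
#' `n_length - length_tolerance` nt) of one insert to a suffix of another,
#' so two design-length parents bound the total at `2 * n_length` nt.
#'
#' @param design A [library_design()].
#' @param n_binders Number of true binder sequences.
#' @param enrichment_factor Per-round weight multiplier per binder (> 1).
#' @param n_background Number of distinct non-enriching background
#'   sequences.
#' @param n_rounds Number of selection rounds.
#' @param reads_per_round Fragments sequenced per round.
#' @param error_rate Per-base substitution probability, applied once per
#'   fragment (the reverse mate is the exact reverse complement).
#' @param byproduct_fraction Probability that a fragment is an elongated
#'   chimera instead of a clean library member.
#' @param byproduct_extra_length Integer range (`c(min, max)`) of insert
#'   elongation beyond `n_length + length_tolerance`.
#' @param seed Integer seed. Binder/background identities derive from
#'   `seed`; round `r` uses an RNG stream seeded `seed + r`.
#' @return An object of class `selex_sim_config` whose `universe` field
#'   holds the realized binder and background sequences.
#' @export
selex_sim_config <- function(design = library_design(),
                             n_binders = 3L,
                             enrichment_factor = 1.8,
                             n_background = 10000L,
                             n_rounds = 14L,
                             reads_per_round = 100000L,
                             error_rate = 0.001,
                             byproduct_fraction = 0.05,
                             byproduct_extra_length = c(3L, 38L),
                             seed = 1L) {
  stopifnot(inherits(design, "library_design"),
            n_binders >= 1L, n_background >= 1L,
            enrichment_factor > 1, n_rounds >= 1L, reads_per_round > 0L,
            error_rate >= 0, error_rate <= 1,
            byproduct_fraction >= 0, byproduct_fraction <= 1,
            length(byproduct_extra_length) == 2L,
            byproduct_extra_length[1] >= 1L,
            byproduct_extra_length[1] <= byproduct_extra_length[2])
  if (byproduct_extra_length[2] >
      design$n_length - design$length_tolerance) {
    stop("byproduct_extra_length must not exceed n_length - length_tolerance ",
         "(chimeras are built from two design-length inserts)", call. = FALSE)
  }
  universe <- with_seed(seed, {
    seqs <- random_inserts(n_binders + n_background, design$n_length)
    while (anyDuplicated(seqs)) {
      dup <- which(duplicated(seqs))
      seqs[dup] <- random_inserts(length(dup), design$n_length)
    }
    seqs
  })
  names(universe) <- c(sprintf("binder%d", seq_len(n_binders)),
                       sprintf("bg%06d", seq_len(n_background)))
  structure(
    list(design = design, n_binders = as.integer(n_binders),
         enrichment_factor = enrichment_factor,
         n_background = as.integer(n_background),
         n_rounds = as.integer(n_rounds),
         reads_per_round = as.integer(reads_per_round),
         error_rate = error_rate,
         byproduct_fraction = byproduct_fraction,
         byproduct_extra_length = as.integer(byproduct_extra_length),
         seed = as.integer(seed),
         universe = universe),
    class = "selex_sim_config"
  )
}

#' @export
print.selex_sim_config <- function(x, ...) {
  cat(sprintf(
    "SELEX simulation: %d binders (factor %.2f/round) + %d background,\n",
    x$n_binders, x$enrichment_factor, x$n_background))
  cat(sprintf(
    "  %d rounds x %d reads; error rate %g/base; by-product fraction %g\n",
    x$n_rounds, x$reads_per_round, x$error_rate, x$byproduct_fraction))
  invisible(x)
}

#' Expected pool composition at a given round
#'
#' Binder `i` carries relative weight `enrichment_factor^(round_index-1)`
#' against weight 1 for each background sequence; the returned vector is
#' normalized to sum to 1. This geometric growth formalizes round-over-round
#' enrichment of viable binders under repeated selection.
#'
#' @param config A [selex_sim_config()].
#' @param round_index Round number in `1..n_rounds`.
#' @return Named numeric vector of expected sequence frequencies (binders
#'   first, then background).
#' @export
simulate_pool_weights <- function(config, round_index) {
  stopifnot(inherits(config, "selex_sim_config"),
            round_index >= 1L, round_index <= config$n_rounds)
  w <- c(rep(config$enrichment_factor^(round_index - 1), config$n_binders),
         rep(1, config$n_background))
  names(w) <- names(config$universe)
  w / sum(w)
}

#' Build an elongated PCR by-product chimera
#'
#' Models the amplification artifact in which one library molecule primes
#' inside another's randomized region and is extended by the polymerase,
#' yielding a longer-than-design product. The chimera joins a prefix of
#' `insert_a` (at least `n_length - length_tolerance` nt) to a suffix of
#' `insert_b` such that the total length exceeds
#' `n_length + length_tolerance` by `extra` nt — so it always fails the
#' extraction length window.
#'
#' @param insert_a,insert_b Parent inserts of the design length.
#' @param design A [library_design()].
#' @param extra_range Integer range for the elongation draw.
#' @param extra Optional fixed elongation (overrides `extra_range`).
#' @return A single chimeric insert string.
#' @export
make_byproduct <- function(insert_a, insert_b, design,
                           extra_range = c(3L, 38L), extra = NULL) {
  stopifnot(inherits(design, "library_design"),
            nchar(insert_a) == design$n_length,
            nchar(insert_b) == design$n_length)
  n <- design$n_length
  tol <- design$length_tolerance
  if (is.null(extra)) {
    extra <- sample(seq.int(extra_range[1], extra_range[2]), 1L)
  }
  total <- n + tol + extra
  lo <- max(n - tol, total - nchar(insert_b))
  hi <- min(nchar(insert_a), total - 1L)
  if (lo > hi) {
    stop("infeasible by-product: elongation ", extra,
         " cannot be built from two ", n, "-nt inserts", call. = FALSE)
  }
  prefix_len <- if (lo == hi) lo else sample(seq.int(lo, hi), 1L)
  suffix_len <- total - prefix_len
  paste0(substr(insert_a, 1L, prefix_len),
         substr(insert_b, nchar(insert_b) - suffix_len + 1L,
                nchar(insert_b)))
}

# Apply per-base substitutions at `rate` to each sequence. Returns the
# mutated sequences plus per-read substitution counts and whether any
# substitution hit the constant flanks (first l5 / last l3 positions).
apply_substitutions <- function(seqs, rate, l5, l3) {
  n <- length(seqs)
  lens <- nchar(seqs)
  n_sub <- stats::rbinom(n, lens, rate)
  flank_hit <- logical(n)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  for (i in which(n_sub > 0L)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(lens[i], n_sub[i])
    for (p in pos) ch[p] <- sample(alt[[ch[p]]], 1L)
    seqs[i] <- paste(ch, collapse = "")
    flank_hit[i] <- any(pos <= l5 | pos > lens[i] - l3)
  }
  list(seqs = seqs, n_sub = n_sub, flank_hit = flank_hit)
}

#' Simulate one sequenced selection round
#'
#' Draws `reads_per_round` fragments multinomially from
#' [simulate_pool_weights()], replaces a `byproduct_fraction` of them with
#' elongated chimeras ([make_byproduct()]), renders each fragment as
#' `flank5 + insert + flank3`, applies per-base substitutions at
#' `error_rate` once per fragment, and emits the forward read plus its
#' reverse complement as the reverse mate (constant Q30 qualities). The
#' round is fully reproducible: round `r` uses an RNG stream seeded
#' `config$seed + r`, independent of other rounds.
#'
#' @param config A [selex_sim_config()].
#' @param round_index Round number in `1..n_rounds`.
#' @param dir Optional directory; when given, `<label>_R1.fastq`,
#'   `<label>_R2.fastq` and `<label>_truth.tsv` are written there.
#' @param label Round label, default `sprintf("round%02d", round_index)`.
#' @return A list with `r1`, `r2` (FASTQ record data.frames as from
#'   [read_fastq()]), `truth` (per-read ground truth: `read_id`, `source`,
#'   `class` in binder/background/byproduct, `flank_mutated`,
#'   `n_substitutions`, `true_insert`), `label`, and — when `dir` is given
#'   — the written `paths`.
#' @export
simulate_round <- function(config, round_index, dir = NULL,
                           label = sprintf("round%02d", round_index)) {
  stopifnot(inherits(config, "selex_sim_config"),
            round_index >= 1L, round_index <= config$n_rounds)
  design <- config$design
  freq <- simulate_pool_weights(config, round_index)
  out <- with_seed(config$seed + round_index, {
    n <- config$reads_per_round
    idx <- sample.int(length(freq), n, replace = TRUE, prob = freq)
    inserts <- unname(config$universe[idx])
    source <- names(config$universe)[idx]
    is_chim <- stats::runif(n) < config$byproduct_fraction
    for (i in which(is_chim)) {
      partner <- sample.int(length(freq), 1L, prob = freq)
      inserts[i] <- make_byproduct(inserts[i], config$universe[[partner]],
                                   design,
                                   extra_range = config$byproduct_extra_length)
    }
    frags <- paste0(design$flank5, inserts, design$flank3)
    mut <- apply_substitutions(frags, config$error_rate,
                               nchar(design$flank5), nchar(design$flank3))
    ids <- sprintf("sim_%s_%06d", label, seq_len(n))
    q <- strrep(rawToChar(as.raw(63L)), nchar(mut$seqs))  # Phred 30
    list(
      r1 = data.frame(read_id = paste0(ids, "/1"), bases = mut$seqs,
                      quals = q, stringsAsFactors = FALSE),
      r2 = data.frame(read_id = paste0(ids, "/2"),
                      bases = reverse_complement(mut$seqs),
                      quals = q, stringsAsFactors = FALSE),
      truth = data.frame(
        read_id = ids,
        source = ifelse(is_chim, "chimera", source),
        class = ifelse(is_chim, "byproduct",
                       ifelse(startsWith(source, "binder"),
                              "binder", "background")),
        flank_mutated = mut$flank_hit,
        n_substitutions = mut$n_sub,
        true_insert = inserts,
        stringsAsFactors = FALSE
      )
    )
  })
  out$label <- label
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      r1 = file.path(dir, paste0(label, "_R1.fastq")),
      r2 = file.path(dir, paste0(label, "_R2.fastq")),
      truth = file.path(dir, paste0(label, "_truth.tsv"))
    )
    write_fastq(out$r1, paths$r1)
    write_fastq(out$r2, paths$r2)
    utils::write.table(out$truth, paths$truth, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    out$paths <- paths
  }
  out
}

#' Simulate a full multi-round experiment to disk
#'
#' Calls [simulate_round()] for a set of rounds and writes round-stamped
#' paired FASTQ files plus ground-truth TSVs.
#'
#' @param config A [selex_sim_config()].
#' @param dir Output directory.
#' @param rounds Integer vector of rounds to render (default all).
#' @return Named list (per round label) of written file paths.
#' @export
simulate_selex <- function(config, dir, rounds = seq_len(config$n_rounds)) {
  stopifnot(inherits(config, "selex_sim_config"))
  out <- list()
  for (r in rounds) {
    sim <- simulate_round(config, r, dir = dir)
    out[[sim$label]] <- sim$paths
  }
  out
}

#' Closed-form extraction pass probability under substitution error
#'
#' With exact flank matching (`max_mismatch = 0`) and substitution-only
#' error, a clean (non-chimeric) fragment passes extraction exactly when
#' none of its `nchar(flank5) + nchar(flank3)` constant bases is hit:
#' substitutions inside the randomized insert change the recovered
#' sequence but not the flank match or the insert length. The pass
#' probability is therefore `(1 - error_rate)^(nchar(flank5) +
#' nchar(flank3))`. The probability that a fragment is entirely
#' substitution-free is `(1 - error_rate)^amplicon_length(design)`.
#'
#' @param design A [library_design()].
#' @param error_rate Per-base substitution probability.
#' @param what `"pass"` (flank-intact probability, the expected extraction
#'   pass fraction at zero by-product fraction) or `"error_free"` (whole
#'   fragment untouched).
#' @return Probability in `[0, 1]`.
#' @export
expected_pass_fraction <- function(design, error_rate,
                                   what = c("pass", "error_free")) {
  stopifnot(inherits(design, "library_design"),
            error_rate >= 0, error_rate <= 1)
  what <- match.arg(what)
  n_bases <- switch(what,
    pass = nchar(design$flank5) + nchar(design$flank3),
    error_free = amplicon_length(design)
  )
  (1 - error_rate)^n_bases
}
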