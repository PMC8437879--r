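#' Run the end-to-end SELEX analysis pipeline
#'
#' Wires the modules into the full flow for a set of sequenced selection
#' rounds: FASTQ input, pairing, flank-validated extraction with a QC
#' ledger, collapse to unique-sequence counts, cross-round enrichment
#' between the earliest and latest round, and a ranked candidate report
#' for the final round. All outputs are written under `outdir`:
#' `<round>_counts.tsv` and `<round>_qc.json` per round,
#' `enrichment_<early>_vs_<late>.tsv`, `candidates_<late>.tsv`,
#' a machine-readable `summary.json` and a human-readable `pipeline.log`.
#' The pipeline is deterministic: identical inputs produce identical
#' report bundles.
#'
#' @param rounds Named list, one entry per selection round (unique
#'   labels). Each entry is a character vector: either `c(r1 = path)` for
#'   single-end data or `c(r1 = path, r2 = path)` for paired-end.
#' @param outdir Output directory (created if needed).
#' @param design A [library_design()].
#' @param min_count Strict read-count threshold for the candidate report
#'   (default 25: candidates need more than 25 reads).
#' @param pseudocount RPM pseudocount for fold-changes (see
#'   [enrichment()]).
#' @param early,late Round labels compared in the enrichment table;
#'   default first and last of `rounds`.
#' @param on_discordant Pair reconciliation policy, see [extract_pair()].
#' @return Invisibly, a list with per-round `pools` and `ledgers`, the
#'   `enrichment` table, the `candidates` table, and `files` (paths of
#'   everything written).
#' @export
run_pipeline <- function(rounds, outdir, design = library_design(),
                         min_count = 25L, pseudocount = 0.5,
                         early = NULL, late = NULL,
                         on_discordant = c("drop", "keep_r1")) {
  on_discordant <- match.arg(on_discordant)
  stopifnot(is.list(rounds), length(rounds) >= 1L)
  labels <- names(rounds)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels)) {
    stop("rounds must be a named list with unique, non-empty labels",
         call. = FALSE)
  }
  for (lab in labels) {
    paths <- rounds[[lab]]
    if (!"r1" %in% names(paths)) {
      stop(sprintf("round '%s': no 'r1' FASTQ path given", lab),
           call. = FALSE)
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop(sprintf("round '%s': input file not found: %s", lab, missing[1]),
           call. = FALSE)
    }
  }
  if (is.null(early)) early <- labels[1]
  if (is.null(late)) late <- labels[length(labels)]
  stopifnot(early %in% labels, late %in% labels)

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  say("selextract pipeline: %d round(s): %s", length(labels),
      paste(labels, collapse = ", "))
  say("design: %s-N%d-%s, window [%d,%d], max_mismatch %d",
      design$flank5, design$n_length, design$flank3,
      length_window(design)[1], length_window(design)[2],
      design$max_mismatch)

  pools <- list()
  ledgers <- list()
  files <- list()
  for (lab in labels) {
    paths <- rounds[[lab]]
    res <- tryCatch({
      r1 <- read_fastq(paths[["r1"]])
      if ("r2" %in% names(paths)) {
        r2 <- read_fastq(paths[["r2"]])
        pairs <- pair_reads(r1, r2)
        extract_pool(pairs, design = design, on_discordant = on_discordant)
      } else {
        extract_pool(r1$bases, design = design)
      }
    }, error = function(e) {
      stop(sprintf("round '%s' failed: %s", lab, conditionMessage(e)),
           call. = FALSE)
    })
    pools[[lab]] <- collapse_reads(res$inserts, lab)
    ledgers[[lab]] <- res$ledger
    counts_path <- file.path(outdir, paste0(lab, "_counts.tsv"))
    qc_path <- file.path(outdir, paste0(lab, "_qc.json"))
    write_counts_table(pools[[lab]], counts_path)
    qc_ledger_json(res$ledger, qc_path)
    files[[paste0(lab, "_counts")]] <- counts_path
    files[[paste0(lab, "_qc")]] <- qc_path
    say("round %s: %d reads, %d pass (%.2f%%), %d unique sequences",
        lab, res$ledger$total, res$ledger$counts[["PASS"]],
        100 * res$ledger$pass_fraction, length(pools[[lab]]$counts))
  }

  enr <- NULL
  if (early != late &&
      pools[[early]]$total_pass > 0L && pools[[late]]$total_pass > 0L) {
    enr <- enrichment(pools[[early]], pools[[late]],
                      pseudocount = pseudocount)
    enr_path <- file.path(outdir,
                          sprintf("enrichment_%s_vs_%s.tsv", early, late))
    utils::write.table(enr, enr_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files$enrichment <- enr_path
    say("enrichment %s vs %s: %d sequences, pseudocount %.2f RPM",
        early, late, nrow(enr), pseudocount)
  } else {
    say("enrichment skipped (single round or empty pool)")
  }

  cands <- top_candidates(pools[[late]], min_count = min_count)
  cand_path <- file.path(outdir, sprintf("candidates_%s.tsv", late))
  utils::write.table(cands, cand_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  files$candidates <- cand_path
  say("candidates (%s, count > %d): %d sequences", late, min_count,
      nrow(cands))

  summary <- list(
    design = design[c("flank5", "flank3", "n_length", "length_tolerance",
                      "max_mismatch")],
    min_count = min_count,
    pseudocount_rpm = pseudocount,
    rounds = lapply(labels, function(lab) list(
      label = lab,
      total_reads = ledgers[[lab]]$total,
      pass_fraction = ledgers[[lab]]$pass_fraction,
      status_counts = as.list(ledgers[[lab]]$counts),
      unique_sequences = length(pools[[lab]]$counts)
    )),
    enrichment = if (is.null(enr)) NULL else
      list(early = early, late = late, n_sequences = nrow(enr)),
    n_candidates = nrow(cands)
  )
  summary_path <- file.path(outdir, "summary.json")
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"),
             summary_path)
  files$summary <- summary_path
  log_path <- file.path(outdir, "pipeline.log")
  writeLines(log_lines, log_path)
  files$log <- log_path

  invisible(list(pools = pools, ledgers = ledgers, enrichment = enr,
                 candidates = cands, files = files))
}
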