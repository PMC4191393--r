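#' Configuration of an end-to-end tailing analysis run
#'
#' @param mature_path mature miRNA FASTA.
#' @param hairpin_path optional hairpin FASTA.
#' @param context_path optional downstream-context TSV.
#' @param read_paths named character vector: sample label -> read file
#'   (FASTQ or collapsed FASTA). Labels must be unique.
#' @param reference_sample label of the control sample (must be one of
#'   `names(read_paths)`); read-level filters and condition comparisons
#'   are anchored here.
#' @param test_sample optional label of the condition to compare against
#'   the reference; defaults to the first non-reference sample, `NA` to
#'   skip comparisons.
#' @param out_dir output directory (created).
#' @param filter a [filter_config()] (its `reference_sample` is filled in
#'   from this configuration).
#' @param motif a [motif_spec()].
#' @param ambiguity_policy see [classify_tail()].
#' @param min_len,max_len read length window (default 18-30 nt).
#' @param adapter optional 3' adapter to trim.
#' @param min_rpm_read_level read-level RPM filter evaluated in the
#'   reference sample (default 1).
#' @param max_internal_mm,max_tail see [match_read()].
#' @param seed integer seed recorded in the run report (the analysis
#'   itself is deterministic).
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(mature_path, read_paths, reference_sample,
                            hairpin_path = NULL, context_path = NULL,
                            test_sample = NULL, out_dir = "mirtail_out",
                            filter = filter_config(),
                            motif = motif_spec(),
                            ambiguity_policy = "flag",
                            min_len = 18L, max_len = 30L, adapter = NULL,
                            min_rpm_read_level = 1.0,
                            max_internal_mm = 0L, max_tail = 3L,
                            seed = 1L) {
  if (is.null(names(read_paths)) || any(!nzchar(names(read_paths))))
    stop("read_paths must be named by sample label")
  if (anyDuplicated(names(read_paths))) stop("duplicate sample labels")
  if (!reference_sample %in% names(read_paths))
    stop("reference_sample '", reference_sample,
         "' is not among the sample labels")
  if (is.null(test_sample)) {
    others <- setdiff(names(read_paths), reference_sample)
    test_sample <- if (length(others)) others[1L] else NA_character_
  }
  for (p in c(mature_path, hairpin_path, context_path, unname(read_paths)))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  filter$reference_sample <- reference_sample
  structure(list(mature_path = mature_path, hairpin_path = hairpin_path,
                 context_path = context_path, read_paths = read_paths,
                 reference_sample = reference_sample,
                 test_sample = test_sample, out_dir = out_dir,
                 filter = filter, motif = motif,
                 ambiguity_policy = ambiguity_policy,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 adapter = adapter,
                 min_rpm_read_level = min_rpm_read_level,
                 max_internal_mm = as.integer(max_internal_mm),
                 max_tail = as.integer(max_tail), seed = as.integer(seed)),
            class = "PipelineConfig")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full tailing analysis pipeline
#'
#' Stages: load references, scan the motif, load/trim/filter reads per
#' sample, call tails, aggregate compositions, filter uridylated miRNAs,
#' compare conditions, and run the enrichment/compensation statistics.
#' Writes `motif.tsv`, `calls.tsv`, `composition.tsv`, `comparison.tsv`,
#' `stats.tsv` and a plain-text `report.txt` with full read accounting to
#' `cfg$out_dir`. Outputs are bit-for-bit reproducible for identical
#' inputs and configuration. Any stage failure aborts with a
#' stage-tagged message and removes partial outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with `refs`, `motif`, `calls`,
#'   `composition`, `survivors`, `comparison`, `stats`, `accounting`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  written <- character(0)
  emit <- function(x, name) {
    p <- file.path(cfg$out_dir, name)
    write_tsv(x, p)
    written <<- c(written, p)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  refs <- stage("reference_io", load_references(
    cfg$mature_path, cfg$hairpin_path, cfg$context_path))

  motif <- stage("motif_scan", scan_reference_set(refs, cfg$motif))
  emit(motif, "motif.tsv")

  acct <- list()
  reads <- stage("load_reads", {
    parts <- lapply(names(cfg$read_paths), function(s) {
      r <- load_reads(cfg$read_paths[[s]], sample = s,
                      min_len = cfg$min_len, max_len = cfg$max_len,
                      adapter = cfg$adapter)
      acct[[s]] <<- attr(r, "accounting")
      r
    })
    do.call(rbind, parts)
  })

  calls <- stage("tail_caller", call_tails(
    reads, refs, ambiguity_policy = cfg$ambiguity_policy,
    max_internal_mm = cfg$max_internal_mm, max_tail = cfg$max_tail))
  emit(calls, "calls.tsv")
  for (s in names(acct)) {
    sel <- calls$sample == s
    acct[[s]]["assigned"] <- sum(calls$count[sel & calls$category != "unassigned"])
    acct[[s]]["unassigned"] <- sum(calls$count[sel & calls$category == "unassigned"])
  }

  ct <- stage("aggregate_composition", aggregate_composition(
    calls, reference_sample = cfg$reference_sample,
    min_rpm_read_level = cfg$min_rpm_read_level, refs = refs))
  emit(as.data.frame(ct), "composition.tsv")

  survivors <- stage("tailing_stats", filter_uridylated(ct, cfg$filter))

  comparison <- NULL; stats_rows <- NULL
  if (!is.na(cfg$test_sample) && length(survivors) >= 1L) {
    comparison <- stage("tailing_stats", compare_conditions(
      ct, cfg$reference_sample, cfg$test_sample, survivors))
    emit(as.data.frame(comparison), "comparison.tsv")
    stats_rows <- stage("tailing_stats", {
      predicted <- motif$name[motif$matched]
      universe <- unique(ct$mirna[ct$sample == cfg$reference_sample &
                                    ct$arm == "5p"])
      rows <- list()
      if (length(universe)) {
        et <- enrichment_test(intersect(predicted, universe),
                              intersect(survivors, universe), universe)
        rows[[1L]] <- data.frame(
          test = "motif_enrichment", mirna = NA_character_,
          a = et$table[1, 1], b = et$table[1, 2],
          c = et$table[2, 1], d = et$table[2, 2],
          p = et$p, direction = NA_character_, stringsAsFactors = FALSE)
      }
      for (m in survivors) {
        cp <- compensation_test(ct, m, cfg$reference_sample, cfg$test_sample)
        rows[[length(rows) + 1L]] <- data.frame(
          test = "compensation", mirna = m,
          a = cp$table[1, 1], b = cp$table[1, 2],
          c = cp$table[2, 1], d = cp$table[2, 2],
          p = cp$p, direction = cp$direction, stringsAsFactors = FALSE)
      }
      r2 <- tryCatch(abundance_concordance(ct, cfg$reference_sample,
                                           cfg$test_sample),
                     error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        test = "abundance_concordance_R2", mirna = NA_character_,
        a = NA, b = NA, c = NA, d = NA, p = r2,
        direction = NA_character_, stringsAsFactors = FALSE)
      do.call(rbind, rows)
    })
    emit(stats_rows, "stats.tsv")
  }

  report <- c(
    "mirtail run report",
    sprintf("package version: %s",
            as.character(utils::packageVersion("mirtail"))),
    sprintf("seed: %d", cfg$seed),
    sprintf("ambiguity policy: %s", cfg$ambiguity_policy),
    sprintf("length window: %d-%d", cfg$min_len, cfg$max_len),
    sprintf("max internal mismatches: %d; max tail: %d",
            cfg$max_internal_mm, cfg$max_tail),
    sprintf("reference sample: %s; test sample: %s",
            cfg$reference_sample, cfg$test_sample),
    sprintf("read-level RPM filter: %g", cfg$min_rpm_read_level),
    "",
    "read accounting (input = kept + dropped per reason):")
  for (s in names(acct)) {
    a <- acct[[s]]
    report <- c(report, sprintf(
      "  %s: input=%d trimmed=%d dropped_N=%d dropped_length=%d kept=%d assigned=%d unassigned=%d",
      s, a["input"], a["trimmed"], a["dropped_N"], a["dropped_length"],
      a["kept"], a["assigned"], a["unassigned"]))
  }
  report <- c(report,
              sprintf("uridylated (filter-passing) miRNAs: %s",
                      if (length(survivors)) paste(survivors, collapse = ", ")
                      else "none"))
  rp <- file.path(cfg$out_dir, "report.txt")
  writeLines(report, rp)
  written <- c(written, rp)

  invisible(list(refs = refs, motif = motif, calls = calls,
                 composition = ct, survivors = survivors,
                 comparison = comparison, stats = stats_rows,
                 accounting = acct))
}
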