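#' Load small-RNA reads from FASTQ or collapsed FASTA
#'
#' Accepts plain/gzipped FASTQ, or collapsed FASTA where the record header
#' carries the read multiplicity in either the `name_count` or
#' `name count` dialect. Processing order: adapter trimming (exact-prefix
#' search: the read is truncated at the earliest position where its
#' remainder equals a prefix of the adapter), dropping of reads containing
#' ambiguous bases (N), length filtering, T-to-U normalization, and
#' collapsing of identical sequences with summed counts.
#'
#' @param path input file.
#' @param sample sample label attached to every read.
#' @param min_len,max_len post-trimming length window (default 18-30 nt,
#'   the standard small-RNA analysis window).
#' @param adapter optional 3' adapter sequence (DNA or RNA).
#' @return data.frame with columns `sequence`, `count`, `sample`, sorted
#'   by sequence; attribute `accounting` holds a named vector of read
#'   counts at each step (input, trimmed, dropped_N, dropped_length, kept).
#' @export
load_reads <- function(path, sample, min_len = 18L, max_len = 30L,
                       adapter = NULL) {
  if (!file.exists(path)) stop("read file not found: ", path)
  first <- readLines(path, n = 1L)
  is_fastq <- startsWith(first, "@")
  ss <- Biostrings::readBStringSet(path, format = if (is_fastq) "fastq" else "fasta")
  seqs <- toupper(as.character(ss))
  counts <- rep(1L, length(seqs))
  if (!is_fastq) {
    ids <- sub("\\s+$", "", names(ss))
    m1 <- regmatches(ids, regexec("[_ ](\\d+)$", ids))
    got <- lengths(m1) == 2L
    counts[got] <- as.integer(vapply(m1[got], `[`, "", 2L))
  }
  n_input <- sum(counts)
  n_trimmed <- 0L
  if (!is.null(adapter) && nzchar(adapter)) {
    adapter <- toupper(adapter)
    trimmed <- vapply(seqs, trim_adapter, "", adapter = adapter,
                      USE.NAMES = FALSE)
    n_trimmed <- sum(counts[trimmed != seqs])
    seqs <- trimmed
  }
  has_n <- grepl("N", seqs, fixed = TRUE)
  n_dropped_N <- sum(counts[has_n])
  seqs <- seqs[!has_n]; counts <- counts[!has_n]
  len <- nchar(seqs)
  keep <- len >= min_len & len <= max_len
  n_dropped_len <- sum(counts[!keep])
  seqs <- norm_rna(seqs[keep]); counts <- counts[keep]
  check_rna(seqs, "read sequence")
  agg <- collapse_reads(seqs, counts, sample)
  attr(agg, "accounting") <- c(input = n_input, trimmed = n_trimmed,
                               dropped_N = n_dropped_N,
                               dropped_length = n_dropped_len,
                               kept = sum(agg$count))
  agg
}

# Truncate `x` at the earliest i where substr(x, i, ...) is a prefix of
# the adapter (handles adapters running off the read end).
trim_adapter <- function(x, adapter) {
  nx <- nchar(x); na <- nchar(adapter)
  for (i in seq_len(nx)) {
    w <- min(nx - i + 1L, na)
    if (substr(x, i, i + w - 1L) == substr(adapter, 1L, w))
      return(substr(x, 1L, i - 1L))
  }
  x
}

# Collapse identical sequences, summing counts; returns canonical order.
collapse_reads <- function(seqs, counts, sample) {
  if (length(seqs) == 0L)
    return(data.frame(sequence = character(0), count = integer(0),
                      sample = character(0), stringsAsFactors = FALSE))
  tot <- rowsum(as.numeric(counts), group = seqs)
  data.frame(sequence = rownames(tot), count = as.integer(tot[, 1L]),
             sample = sample, stringsAsFactors = FALSE, row.names = NULL)
}

#' Construct read records in code
#'
#' @param sequences character vector (RNA/DNA; normalized).
#' @param counts integer multiplicities (recycled).
#' @param sample sample label.
#' @return data.frame of collapsed reads as from [load_reads()].
#' @export
read_records <- function(sequences, counts = 1L, sample = "s1") {
  sequences <- norm_rna(sequences)
  check_rna(sequences, "read sequence")
  counts <- rep_len(as.integer(counts), length(sequences))
  if (any(counts < 1L)) stop("counts must be >= 1")
  collapse_reads(sequences, counts, sample)
}

# 5'-anchored match of one read against one mature body.
# Returns matched_len (longest prefix of the read consistent with the
# mature allowing <= max_mm mismatches, last matched base exact) and the
# mismatch count within it, or NULL if no admissible alignment.
anchor_match <- function(read, mature, max_mm, max_tail) {
  L <- nchar(mature); nr <- nchar(read)
  n <- min(L, nr)
  rv <- substring(read, seq_len(n), seq_len(n))
  mv <- substring(mature, seq_len(n), seq_len(n))
  eq <- rv == mv
  cmm <- cumsum(!eq)
  ok <- which(eq & cmm <= max_mm)        # candidate matched_len values
  if (length(ok) == 0L) return(NULL)
  lo <- max(L - 2L, 1L)                  # length_offset >= -2
  ok <- ok[ok >= lo & (nr - ok) <= max_tail]
  if (length(ok) == 0L) return(NULL)
  ml <- max(ok)
  list(matched_len = ml, mm = cmm[ml])
}

#' Match one read to a mature miRNA reference (5'-anchored)
#'
#' Deterministic replacement for heuristic short-read alignment: the read
#' is anchored at the mature 5' end and `matched_len` is the longest read
#' prefix consistent with the mature body, allowing up to
#' `max_internal_mm` internal mismatches but requiring the final matched
#' base to be exact (so a 3' mismatch is always part of the tail, never
#' absorbed). Admissible assignments need `matched_len >= canonical - 2`
#' (Dicer 3' heterogeneity window) and a tail of at most `max_tail`
#' bases. Among candidate miRNAs the most matched bases win, then the
#' fewest mismatches; remaining ties are multi-mappers and are returned
#' unassigned.
#'
#' @param read a read sequence (character) or one-row data.frame from
#'   [read_records()].
#' @param refs a `ReferenceSet`.
#' @param max_internal_mm internal mismatch allowance (default 0;
#'   the original heuristic pipeline tolerated 2).
#' @param max_tail maximum tail length (default 3; mono- and short
#'   oligo-tails are the analyte, longer 3' divergence is unassigned).
#' @return a list `TailCall` with `mirna`, `matched_len`,
#'   `canonical_len`, `length_offset`, `tail`, `internal_mismatches`; or
#'   `NULL` when unassigned (no admissible match, or a multi-mapper tie).
#' @export
match_read <- function(read, refs, max_internal_mm = 0L, max_tail = 3L) {
  if (is.data.frame(read)) read <- read$sequence[1L]
  read <- norm_rna(read)
  stopifnot(inherits(refs, "ReferenceSet"), max_tail >= 0L, max_tail <= 5L)
  best <- NULL
  for (i in seq_len(nrow(refs$entries))) {
    m <- anchor_match(read, refs$entries$sequence[i], max_internal_mm, max_tail)
    if (is.null(m)) next
    cand <- list(mirna = refs$entries$name[i], matched_len = m$matched_len,
                 canonical_len = nchar(refs$entries$sequence[i]),
                 length_offset = m$matched_len - nchar(refs$entries$sequence[i]),
                 tail = substr(read, m$matched_len + 1L, nchar(read)),
                 internal_mismatches = m$mm)
    if (is.null(best)) { best <- cand; tie <- FALSE; next }
    if (cand$matched_len > best$matched_len ||
        (cand$matched_len == best$matched_len &&
         cand$internal_mismatches < best$internal_mismatches)) {
      best <- cand; tie <- FALSE
    } else if (cand$matched_len == best$matched_len &&
               cand$internal_mismatches == best$internal_mismatches) {
      tie <- TRUE
    }
  }
  if (is.null(best) || tie) return(NULL)
  best
}

#' Classify the 3' tail of a matched read
#'
#' Splits the tail into a templated prefix (bases equal to the downstream
#' context at the matched 3' position) and an untemplated remainder, then
#' assigns the category: `WT` (no untemplated bases), `U` / `A`
#' (untemplated portion all U / all A), `other` (mixed or C/G), or
#' `ambiguous` (tail non-empty, fully templated, and all U or all A: with
#' a genomic U (or A) directly downstream, Dicer cleavage heterogeneity
#' and non-templated addition are indistinguishable - the miR-10a
#' situation).
#'
#' Policies: `"flag"` (default) reports `ambiguous` as its own category;
#' `"drop"` computes identical per-read calls but
#' [aggregate_composition()] excludes ambiguous reads from denominators;
#' `"count_untemplated"` ignores templating and categorizes the whole
#' tail as untemplated.
#'
#' @param tc a `TailCall` from [match_read()].
#' @param context downstream context at the *matched* 3' position: for a
#'   shortened body this is the remaining mature bases followed by the
#'   genomic context (see [call_tails()], which assembles it). At most 6 nt.
#' @param ambiguity_policy one of `"flag"`, `"count_untemplated"`, `"drop"`.
#' @return `tc` with added `templated_prefix_len`, `untemplated`,
#'   `category`.
#' @export
classify_tail <- function(tc, context,
                          ambiguity_policy = c("flag", "count_untemplated",
                                               "drop")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  if (nchar(context) > 6L) stop("context longer than 6 nt")
  context <- norm_rna(context)
  tail <- tc$tail
  tpl <- lcp_len(tail, context)
  unt <- substr(tail, tpl + 1L, nchar(tail))
  tc$templated_prefix_len <- tpl
  # under count_untemplated the whole tail is the untemplated portion
  tc$untemplated <- if (ambiguity_policy == "count_untemplated") tail else unt
  tc$category <- tail_category(tail, unt, ambiguity_policy)
  tc
}

# Category rule shared by scalar and vectorized paths.
tail_category <- function(tail, untemplated, policy) {
  if (policy == "count_untemplated") untemplated <- tail
  if (!nzchar(tail)) return("WT")
  if (!nzchar(untemplated)) {           # fully templated extension
    if (policy == "count_untemplated") return("WT")  # unreachable; guard
    if (grepl("^U+$", tail) || grepl("^A+$", tail)) return("ambiguous")
    return("WT")
  }
  if (grepl("^U+$", untemplated)) return("U")
  if (grepl("^A+$", untemplated)) return("A")
  "other"
}

#' Match and classify a table of reads end to end
#'
#' Convenience wrapper: applies [match_read()] and [classify_tail()] to
#' every distinct read sequence. The classification context at a shifted
#' 3' position is the unmatched remainder of the mature body followed by
#' the entry's downstream genomic context, so templating is re-checked at
#' the actual matched end.
#'
#' @param reads data.frame from [load_reads()] / [read_records()].
#' @param refs a `ReferenceSet`.
#' @param ambiguity_policy see [classify_tail()].
#' @param max_internal_mm,max_tail see [match_read()].
#' @return data.frame of calls, one row per distinct (sequence, sample):
#'   `sequence`, `count`, `sample`, `mirna` (`NA` when unassigned),
#'   `matched_len`, `canonical_len`, `length_offset`, `tail`,
#'   `templated_prefix_len`, `untemplated`, `category` (`unassigned`
#'   included), `internal_mismatches`, `context_free`.
#' @export
call_tails <- function(reads, refs,
                       ambiguity_policy = c("flag", "count_untemplated",
                                            "drop"),
                       max_internal_mm = 0L, max_tail = 3L) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  stopifnot(inherits(refs, "ReferenceSet"))
  n <- nrow(reads)
  out <- data.frame(
    sequence = reads$sequence, count = reads$count, sample = reads$sample,
    mirna = rep(NA_character_, n), matched_len = rep(NA_integer_, n),
    canonical_len = rep(NA_integer_, n),
    length_offset = rep(NA_integer_, n),
    tail = rep(NA_character_, n),
    templated_prefix_len = rep(NA_integer_, n),
    untemplated = rep(NA_character_, n),
    category = rep("unassigned", n),
    internal_mismatches = rep(NA_integer_, n),
    context_free = rep(FALSE, n),
    stringsAsFactors = FALSE)
  if (n == 0L) {
    attr(out, "policy") <- ambiguity_policy
    return(out)
  }
  # classify each distinct sequence once, then broadcast to samples
  uniq <- unique(reads$sequence)
  idx <- match(reads$sequence, uniq)
  ctx_store <- refs$entries$downstream_context
  free_store <- refs$entries$context_free
  res <- lapply(uniq, function(s) {
    tc <- match_read(s, refs, max_internal_mm = max_internal_mm,
                     max_tail = max_tail)
    if (is.null(tc)) return(NULL)
    i <- match(tc$mirna, refs$entries$name)
    mature <- refs$entries$sequence[i]
    ext <- paste0(substr(mature, tc$matched_len + 1L, nchar(mature)),
                  ctx_store[i])
    ctx <- substr(ext, 1L, 6L)
    tc <- classify_tail(tc, ctx, ambiguity_policy)
    tc$context_free <- free_store[i] && tc$matched_len >= nchar(mature)
    tc
  })
  for (j in seq_len(n)) {
    tc <- res[[idx[j]]]
    if (is.null(tc)) next
    out$mirna[j] <- tc$mirna
    out$matched_len[j] <- tc$matched_len
    out$canonical_len[j] <- tc$canonical_len
    out$length_offset[j] <- tc$length_offset
    out$tail[j] <- tc$tail
    out$templated_prefix_len[j] <- tc$templated_prefix_len
    out$untemplated[j] <- tc$untemplated
    out$category[j] <- tc$category
    out$internal_mismatches[j] <- tc$internal_mismatches
    out$context_free[j] <- tc$context_free
  }
  attr(out, "policy") <- ambiguity_policy
  out
}

#' Aggregate tail calls into a per-miRNA composition table
#'
#' Builds per-(miRNA, sample) category counts, fractions and RPM.
#' Unassigned reads are excluded. When `reference_sample` is given, the
#' read-level expression filter is applied: distinct read sequences whose
#' RPM in the reference (control) sample falls below
#' `min_rpm_read_level` are excluded from *every* sample's composition
#' (reference-sample RPM uses the reference sample's total assigned
#' reads). Under the `drop` ambiguity policy, ambiguous reads are
#' excluded from all counts and denominators.
#'
#' @param calls data.frame from [call_tails()].
#' @param reference_sample sample label in which the read-level filter is
#'   evaluated; `NULL` (default) disables the filter.
#' @param min_rpm_read_level read-level RPM threshold (default 1).
#' @param refs optional `ReferenceSet` used to attach arm labels;
#'   otherwise arms are parsed from `-5p`/`-3p` name suffixes.
#' @return a `CompositionTable`: data.frame with one row per
#'   (mirna, sample): `mirna`, `sample`, `arm`, counts `n_WT`, `n_U`,
#'   `n_A`, `n_other`, `n_ambiguous`, `total`, fractions `frac_*`
#'   (summing to 1 over reported categories), `rpm` (per-sample RPM over
#'   all included assigned reads; sums to 1e6 per sample) and `u_rpm`
#'   (RPM of category-U reads). Attributes: `sample_totals`,
#'   `length_offset_hist` (data.frame mirna/sample/length_offset/count),
#'   `policy`, `reference_sample`, `n_excluded_low_rpm`,
#'   `n_excluded_ambiguous`.
#' @export
aggregate_composition <- function(calls, reference_sample = NULL,
                                  min_rpm_read_level = 1.0, refs = NULL) {
  policy <- attr(calls, "policy")
  if (is.null(policy)) policy <- "flag"
  x <- calls[calls$category != "unassigned" & !is.na(calls$mirna), ,
             drop = FALSE]
  n_excl_amb <- 0L
  if (policy == "drop") {
    amb <- x$category == "ambiguous"
    n_excl_amb <- sum(x$count[amb])
    x <- x[!amb, , drop = FALSE]
  }
  n_excl_rpm <- 0L
  if (!is.null(reference_sample) && nrow(x)) {
    if (!reference_sample %in% calls$sample)
      stop("reference_sample '", reference_sample, "' not present in calls")
    xr <- x[x$sample == reference_sample, , drop = FALSE]
    ref_total <- sum(xr$count)
    ref_rpm <- structure(xr$count / max(ref_total, 1L) * 1e6,
                         names = xr$sequence)
    seq_rpm <- ref_rpm[x$sequence]
    seq_rpm[is.na(seq_rpm)] <- 0
    drop_seq <- seq_rpm < min_rpm_read_level
    n_excl_rpm <- sum(x$count[drop_seq])
    x <- x[!drop_seq, , drop = FALSE]
  }
  cats <- c("WT", "U", "A", "other", "ambiguous")
  if (nrow(x) == 0L) {
    out <- data.frame(mirna = character(0), sample = character(0),
                      arm = character(0))
    for (cc in cats) out[[paste0("n_", cc)]] <- integer(0)
    out$total <- integer(0)
    for (cc in cats) out[[paste0("frac_", cc)]] <- numeric(0)
    out$rpm <- numeric(0); out$u_rpm <- numeric(0)
    class(out) <- c("CompositionTable", "data.frame")
    return(out)
  }
  key <- interaction(x$mirna, x$sample, drop = TRUE, sep = "\r")
  counts <- matrix(0, nrow = nlevels(key), ncol = length(cats),
                   dimnames = list(levels(key), cats))
  for (cc in cats) {
    sel <- x$category == cc
    if (any(sel)) {
      s <- rowsum(as.numeric(x$count[sel]), droplevels(key[sel]))
      counts[rownames(s), cc] <- s[, 1L]
    }
  }
  parts <- strsplit(rownames(counts), "\r", fixed = TRUE)
  mirna <- vapply(parts, `[`, "", 1L)
  sample <- vapply(parts, `[`, "", 2L)
  total <- rowSums(counts)
  sample_totals <- tapply(total, sample, sum)
  stot <- as.numeric(sample_totals[sample])
  arm <- if (!is.null(refs)) {
    refs$entries$arm[match(mirna, refs$entries$name)]
  } else {
    ifelse(grepl("-5p$", mirna), "5p",
           ifelse(grepl("-3p$", mirna), "3p", "unknown"))
  }
  out <- data.frame(mirna = mirna, sample = sample, arm = arm,
                    stringsAsFactors = FALSE)
  for (cc in cats) out[[paste0("n_", cc)]] <- as.integer(counts[, cc])
  out$total <- as.integer(total)
  for (cc in cats) out[[paste0("frac_", cc)]] <- counts[, cc] / total
  out$rpm <- total / stot * 1e6
  out$u_rpm <- counts[, "U"] / stot * 1e6
  out <- out[order(out$sample, out$mirna), , drop = FALSE]
  rownames(out) <- NULL

  lh <- stats::aggregate(count ~ mirna + sample + length_offset, data = x,
                         FUN = sum)
  class(out) <- c("CompositionTable", "data.frame")
  attr(out, "sample_totals") <- sample_totals
  attr(out, "length_offset_hist") <- lh
  attr(out, "policy") <- policy
  attr(out, "reference_sample") <- reference_sample
  attr(out, "n_excluded_low_rpm") <- n_excl_rpm
  attr(out, "n_excluded_ambiguous") <- n_excl_amb
  out
}
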