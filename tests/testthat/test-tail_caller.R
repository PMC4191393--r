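test_that("load_reads trims adapters, collapses, filters, and accounts", {
  fq <- tempfile(fileext = ".fastq")
  insert <- "ACGTACGTACGTACGTACGTAC"        # 22 nt
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  recs <- c(
    paste0(insert, substr(adapter, 1, 8)),   # insert + adapter prefix
    paste0(insert, substr(adapter, 1, 8)),   # identical -> collapsed
    paste0("ACGTACGTACGTACGT", adapter),     # 16 nt insert -> dropped
    "ACGTNCGTACGTACGTACGTAC")                # N -> dropped
  writeLines(as.vector(rbind(paste0("@r", seq_along(recs)), recs, "+",
                             strrep("I", nchar(recs)))), fq)
  rd <- load_reads(fq, "s1", adapter = adapter)
  expect_equal(nrow(rd), 1L)
  expect_equal(rd$sequence, chartr("T", "U", insert))
  expect_equal(rd$count, 2L)
  acc <- attr(rd, "accounting")
  expect_equal(unname(acc["input"]), 4L)
  expect_equal(unname(acc["dropped_N"]), 1L)
  expect_equal(unname(acc["dropped_length"]), 1L)
  expect_equal(unname(acc["kept"]), 2L)
})

test_that("collapsed FASTA header dialects carry counts", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">seq1_5", "ACGTACGTACGTACGTACGTAC",
               ">seq2 3", "TGCATGCATGCATGCATGCATG"), fa)
  rd <- load_reads(fa, "s1")
  expect_equal(sort(rd$count), c(3L, 5L))
  expect_equal(sum(rd$count), 8L)
})

test_that("match_read: identity, tails, length isoforms, ties", {
  rs <- tiny_refs()
  ma <- rs$entries$sequence[rs$entries$name == "tst-mir-a-5p"]

  tc <- match_read(ma, rs)
  expect_equal(tc$mirna, "tst-mir-a-5p")
  expect_equal(tc$matched_len, 22L)
  expect_equal(tc$length_offset, 0L)
  expect_equal(tc$tail, "")

  tc2 <- match_read(paste0(ma, "A"), rs)
  expect_equal(tc2$tail, "A")
  expect_equal(tc2$matched_len, 22L)

  tc3 <- match_read(paste0(substr(ma, 1, 21), "U"), rs)
  expect_equal(tc3$matched_len, 21L)
  expect_equal(tc3$length_offset, -1L)
  expect_equal(tc3$tail, "U")

  # offsets beyond -2 or tails beyond max_tail are unassigned
  expect_null(match_read(substr(ma, 1, 19), rs))
  expect_null(match_read(paste0(ma, "AAAA"), rs, max_tail = 3L))

  # two identical family members -> tie -> unassigned
  rs2 <- reference_set(c("fam-1-5p" = ma, "fam-2-5p" = ma))
  expect_null(match_read(ma, rs2))
})

test_that("classify_tail templating rules across policies", {
  base <- list(mirna = "m", matched_len = 22L, canonical_len = 22L,
               length_offset = 0L, tail = "", internal_mismatches = 0L)
  cl <- function(tail, context, policy = "flag") {
    tc <- base; tc$tail <- tail
    classify_tail(tc, context, policy)$category
  }
  expect_equal(cl("U", "C"), "U")           # untemplated mono-U
  expect_equal(cl("U", "U"), "ambiguous")   # downstream genomic U
  expect_equal(cl("", "C"), "WT")
  expect_equal(cl("UA", "C"), "other")      # mixed untemplated
  expect_equal(cl("AU", "A"), "U")          # templated A prefix, then U
  expect_equal(cl("A", "U"), "A")
  expect_equal(cl("CG", "CG"), "WT")        # fully templated, mixed: genomic
  expect_equal(cl("UU", "UU"), "ambiguous")
  # count_untemplated ignores templating entirely
  expect_equal(cl("U", "U", "count_untemplated"), "U")
  expect_equal(cl("AU", "A", "count_untemplated"), "other")
  expect_error(classify_tail(base, "ACGUACG"), "longer than 6")
})

test_that("templated prefix computation is policy-invariant (flag vs drop)", {
  rs <- tiny_refs()
  mb <- rs$entries$sequence[rs$entries$name == "tst-mir-b-5p"]
  reads <- read_records(c(paste0(mb, "U"), paste0(mb, "UA"), paste0(mb, "A")))
  cf <- call_tails(reads, rs, ambiguity_policy = "flag")
  cd <- call_tails(reads, rs, ambiguity_policy = "drop")
  expect_equal(cf$templated_prefix_len, cd$templated_prefix_len)
  expect_equal(cf$untemplated, cd$untemplated)
  expect_equal(cf$category, cd$category)    # per-read calls identical
})

test_that("call_tails re-checks templating at shifted 3' positions", {
  rs <- tiny_refs()
  ma <- rs$entries$sequence[rs$entries$name == "tst-mir-a-5p"]
  last <- substr(ma, 22, 22)                # "C" for tst-mir-a
  # -1 isoform with a tail equal to the mature's last base: templated
  r1 <- paste0(substr(ma, 1, 21), last)
  # (absorbed into the body by longest-prefix matching -> WT, offset 0)
  c1 <- call_tails(read_records(r1), rs)
  expect_equal(c1$category, "WT")
  expect_equal(c1$length_offset, 0L)
  # -1 isoform with an untemplated U: category U at offset -1
  r2 <- paste0(substr(ma, 1, 21), "U")
  c2 <- call_tails(read_records(r2), rs)
  expect_equal(c2$category, "U")
  expect_equal(c2$length_offset, -1L)
})

test_that("caller equals brute-force oracle on enumerated reads", {
  set.seed(11)
  rs <- tiny_refs()
  oracle_refs <- list(
    "tst-mir-a-5p" = list(
      mature = rs$entries$sequence[1],
      context = rs$entries$downstream_context[1]),
    "tst-mir-b-5p" = list(
      mature = rs$entries$sequence[2],
      context = rs$entries$downstream_context[2]))
  tails <- c("", "U", "A", "C", "G", "UU", "AU", "UA", "CG", "AA", "GC")
  for (nm in names(oracle_refs)) {
    mat <- oracle_refs[[nm]]$mature
    for (off in 0:2) for (tl in tails) {
      read <- paste0(substr(mat, 1, nchar(mat) - off), tl)
      got <- call_tails(read_records(read), rs)
      want <- oracle_classify(read, oracle_refs)
      if (is.null(want)) {
        expect_equal(got$category, "unassigned", info = read)
      } else {
        expect_equal(got$mirna, want$mirna, info = read)
        expect_equal(got$category, want$category, info = read)
        expect_equal(got$matched_len, want$matched_len, info = read)
      }
    }
  }
})

test_that("internal mismatch allowance is monotone in assigned reads", {
  set.seed(3)
  rs <- tiny_refs()
  ma <- rs$entries$sequence[1]
  reads <- vapply(1:60, function(i) {
    r <- ma
    pos <- sample.int(20, 1L)
    substr(r, pos, pos) <- sample(c("A", "C", "G", "U"), 1L)
    paste0(r, sample(c("", "U", "A"), 1L))
  }, "")
  n_assigned <- vapply(0:2, function(mm) {
    calls <- call_tails(read_records(reads), rs, max_internal_mm = mm)
    sum(calls$category != "unassigned")
  }, 0L)
  expect_true(all(diff(n_assigned) >= 0L))
  expect_gt(n_assigned[3], n_assigned[1])
})

test_that("aggregate_composition fractions, RPM and conservation", {
  rs <- tiny_refs()
  ma <- rs$entries$sequence[1]
  seqs <- c(ma, paste0(ma, "U"), paste0(ma, "A"), paste0(ma, "G"))
  reads <- read_records(rep(seqs, c(80, 8, 11, 1)), sample = "ctl")
  calls <- call_tails(reads, rs)
  ct <- aggregate_composition(calls, refs = rs)
  expect_s3_class(ct, "CompositionTable")
  expect_equal(ct$total, 100L)
  expect_equal(ct$frac_WT, 0.80)
  expect_equal(ct$frac_U, 0.08)
  expect_equal(ct$frac_A, 0.11)
  expect_equal(ct$frac_other, 0.01)
  expect_equal(ct$rpm, 1e6)  # only miRNA in the sample
  # fractions over reported categories sum to 1
  expect_equal(ct$frac_WT + ct$frac_U + ct$frac_A + ct$frac_other +
                 ct$frac_ambiguous, 1)
  # all-WT composition
  ct2 <- aggregate_composition(call_tails(read_records(rep(ma, 5)), rs),
                               refs = rs)
  expect_equal(ct2$frac_WT, 1)
  expect_equal(ct2$n_U + ct2$n_A + ct2$n_other + ct2$n_ambiguous, 0L)
  # conservation: category counts sum to assigned totals
  expect_equal(ct$n_WT + ct$n_U + ct$n_A + ct$n_other + ct$n_ambiguous,
               ct$total)
})

test_that("read-level RPM filter is anchored in the reference sample", {
  rs <- tiny_refs()
  ma <- rs$entries$sequence[1]
  # reference: 10 reads total -> 1 read = 1e5 RPM; a sequence absent from
  # the reference sample has 0 RPM there and is excluded everywhere
  ref_reads <- read_records(rep(c(ma, paste0(ma, "U")), c(9, 1)),
                            sample = "ctl")
  test_reads <- read_records(rep(c(ma, paste0(ma, "U"), paste0(ma, "A")),
                                 c(5, 1, 4)), sample = "kd")
  calls <- call_tails(rbind(ref_reads, test_reads), rs)
  ct <- aggregate_composition(calls, reference_sample = "ctl",
                              min_rpm_read_level = 1, refs = rs)
  kd <- ct[ct$sample == "kd", ]
  expect_equal(kd$n_A, 0L)        # mature+A unseen in ctl -> dropped
  expect_equal(kd$total, 6L)
  expect_equal(attr(ct, "n_excluded_low_rpm"), 4L)
  # empty input is not an error
  ct0 <- aggregate_composition(call_tails(read_records(character(0)), rs))
  expect_equal(nrow(ct0), 0L)
})

test_that("drop policy removes ambiguous reads from denominators only", {
  rs <- tiny_refs()
  mb <- rs$entries$sequence[2]   # downstream context starts with U
  seqs <- rep(c(mb, paste0(mb, "U"), paste0(mb, "A")), c(6, 2, 2))
  calls_f <- call_tails(read_records(seqs), rs, ambiguity_policy = "flag")
  calls_d <- call_tails(read_records(seqs), rs, ambiguity_policy = "drop")
  ctf <- aggregate_composition(calls_f, refs = rs)
  ctd <- aggregate_composition(calls_d, refs = rs)
  expect_equal(ctf$n_ambiguous, 2L)
  expect_equal(ctf$total, 10L)
  expect_equal(ctd$n_ambiguous, 0L)
  expect_equal(ctd$total, 8L)
  expect_equal(ctd$frac_A, 2 / 8)
})
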