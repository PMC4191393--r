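#' Configuration for the two-condition small-RNA library simulator
#'
#' The generator emulates the statistical structure of a two-condition
#' (control vs TUTase-depleted) small-RNA experiment: hairpins of 60-80 nt
#' with embedded 22-nt 5p mature miRNAs, per-miRNA abundances log-uniform
#' over three decades, canonical-length and -1 nt Dicer-heterogeneity
#' isoforms, and per-read 3' categories drawn from a (WT, U, A, other)
#' mixture. Untemplated tails are appended at the canonical 3' end and
#' are forced to differ from the downstream context base (the context
#' alphabet is U/C/G, and `other` tails avoid the context base), so a
#' read's intended category is self-consistent; the one deliberate
#' exception is a genomic U downstream (`p_downstream_U`), which makes
#' mono-/oligo-U tails templating-ambiguous exactly as a downstream
#' genomic thymidine does in real data.
#'
#' @param n_mirnas number of simulated miRNAs (default 20).
#' @param fraction_motif_positive fraction of matures carrying a planted
#'   GUAG..UUGU motif (default 0.5).
#' @param depth_per_sample reads per library (default 1e5).
#' @param mixture length-4 numeric `(p_WT, p_U, p_A, p_other)` summing to
#'   1; default `c(0.80, 0.08, 0.11, 0.01)`, the composition of a
#'   heavily tailed miRNA (miR-99a-like) in control cells.
#' @param p_len_minus1 probability that a WT read is the -1 nt Dicer
#'   isoform (default 0.2: the 21-nt species is a significant minority
#'   next to the dominant 22-nt form).
#' @param p_downstream_U probability that a hairpin's first downstream
#'   base is U (default 0.25; downstream uridines are common among let-7
#'   family loci and drive the templating-ambiguity caveat).
#' @param oligo_tail_prob probability that an untemplated U/A tail has
#'   length 2 instead of 1 (default 0.1; mono-additions dominate).
#' @param error_rate per-base substitution rate within the read body
#'   (default 0; exists to stress internal-mismatch handling).
#' @param seed integer master seed; every simulator output is a pure
#'   function of the configuration including the seed.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(n_mirnas = 20L, fraction_motif_positive = 0.5,
                              depth_per_sample = 100000L,
                              mixture = c(WT = 0.80, U = 0.08,
                                          A = 0.11, other = 0.01),
                              p_len_minus1 = 0.2, p_downstream_U = 0.25,
                              oligo_tail_prob = 0.1, error_rate = 0,
                              seed = 1L) {
  mixture <- unname(mixture)
  stopifnot(n_mirnas >= 1L, depth_per_sample >= 1L,
            fraction_motif_positive >= 0, fraction_motif_positive <= 1,
            length(mixture) == 4L, all(mixture >= 0),
            abs(sum(mixture) - 1) < 1e-9,
            p_len_minus1 >= 0, p_len_minus1 <= 1,
            p_downstream_U >= 0, p_downstream_U <= 1,
              oligo_tail_prob >= 0, oligo_tail_prob <= 1,
            error_rate >= 0, error_rate <= 1)
  structure(list(n_mirnas = as.integer(n_mirnas),
                 fraction_motif_positive = fraction_motif_positive,
                 depth_per_sample = as.integer(depth_per_sample),
                 mixture = mixture, p_len_minus1 = p_len_minus1,
                 p_downstream_U = p_downstream_U,
                 oligo_tail_prob = oligo_tail_prob,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "SimulationConfig")
}

MATURE_LEN <- 22L

rand_bases <- function(n, alphabet = RNA_BASES) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# One 22-nt mature; motif planted or rejected out. The last canonical
# base is fixed to C or G so that -1 isoforms plus a U/A tail can never
# be absorbed into the mature body (keeps simulated ground truth exact).
sim_mature <- function(motif_positive, spec = motif_spec()) {
  repeat {
    s <- rand_bases(MATURE_LEN)
    last <- sample(c("C", "G"), 1L)
    substr(s, MATURE_LEN, MATURE_LEN) <- last
    if (motif_positive) {
      e1 <- spec$element1; e2 <- spec$element2
      p1 <- sample(2:6, 1L)
      p2_min <- p1 + nchar(e1)
      p2_max <- MATURE_LEN - 1L - nchar(e2)      # keep last base free
      p2 <- sample(p2_min:p2_max, 1L)
      substr(s, p1, p1 + nchar(e1) - 1L) <- e1
      substr(s, p2, p2 + nchar(e2) - 1L) <- e2
      substr(s, MATURE_LEN, MATURE_LEN) <- last  # may have been overwritten
      if (scan_sequence(s, spec)$matched) return(s)
    } else {
      if (!scan_sequence(s, spec)$matched) return(s)
    }
  }
}

#' Simulate a miRNA reference with planted motifs and known context
#'
#' Generates `n_mirnas` hairpins of 60-80 nt each embedding a 22-nt 5p
#' mature sequence; exactly `round(n_mirnas * fraction_motif_positive)`
#' matures carry the bipartite motif (planting plus rejection sampling of
#' the remainder). The first downstream base is U with probability
#' `p_downstream_U`, otherwise C or G. Per-miRNA abundance weights
#' (log-uniform over three decades) are drawn here so that both samples
#' of a condition pair share them.
#'
#' @param cfg a [simulation_config()].
#' @return list with `refs` (a `ReferenceSet`) and `truth` (a
#'   `GroundTruth` skeleton: data.frame `mirna`, `motif_positive`,
#'   `downstream_base`, `weight`).
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  n <- cfg$n_mirnas
  n_pos <- round(n * cfg$fraction_motif_positive)
  with_seed(cfg$seed, {
    motif_pos <- rep(c(TRUE, FALSE), c(n_pos, n - n_pos))
    names <- sprintf("syn-mir-%03d", seq_len(n))
    matures <- vapply(seq_len(n), function(i) sim_mature(motif_pos[i]), "")
    # downstream context: "UU" with p_downstream_U (genomic U runs after
    # the 3' end, the templating-ambiguity case), else a single C or G
    down <- ifelse(stats::runif(n) < cfg$p_downstream_U, "UU",
                   ifelse(stats::runif(n) < 0.5, "C", "G"))
    hp_len <- sample(60:80, n, replace = TRUE)
    offset <- sample(3:8, n, replace = TRUE)
    hairpins <- vapply(seq_len(n), function(i) {
      pad5 <- rand_bases(offset[i])
      rest_len <- hp_len[i] - offset[i] - MATURE_LEN - nchar(down[i])
      paste0(pad5, matures[i], down[i], rand_bases(max(rest_len, 0L)))
    }, "")
    weight <- 10^stats::runif(n, 0, 3)
    names(matures) <- paste0(names, "-5p")
    names(hairpins) <- names
    refs <- reference_set(matures, hairpins = hairpins,
                          species_tag = "syn")
    truth <- data.frame(mirna = paste0(names, "-5p"),
                        motif_positive = motif_pos,
                        downstream_base = substr(down, 1L, 1L),
                        weight = weight,
                        stringsAsFactors = FALSE)
    structure(list(refs = refs, truth = truth), class = "SimulatedReference")
  })
}

# What an ideal observer (and a correct caller) reports for a read built
# as body_len mature bases plus `tail`, given the full mature and its
# downstream context. Mirrors the templating rules of classify_tail but
# is computed from generative knowledge at emission time.
observable_category <- function(mature, context, body_len, tail) {
  read <- paste0(substr(mature, 1L, body_len), tail)
  ml <- lcp_len(read, mature)                 # absorption into the body
  tl <- substr(read, ml + 1L, nchar(read))
  ext <- paste0(substr(mature, ml + 1L, nchar(mature)), context)
  tpl <- lcp_len(tl, ext)
  unt <- substr(tl, tpl + 1L, nchar(tl))
  if (!nzchar(tl)) return("WT")
  if (!nzchar(unt)) {
    if (grepl("^U+$", tl) || grepl("^A+$", tl)) return("ambiguous")
    return("WT")
  }
  if (grepl("^U+$", unt)) return("U")
  if (grepl("^A+$", unt)) return("A")
  "other"
}

#' Simulate one small-RNA library with per-read ground truth
#'
#' Draws `depth_per_sample` reads: miRNA by the reference's abundance
#' weights, 3' category by `mixture`, the -1 nt Dicer isoform for WT
#' reads with `p_len_minus1`, and untemplated tails (U/UU, A/AA, or a
#' C/G base differing from context for `other`). Each read records both
#' its intended category and the observable category an ideal observer
#' would call given templating (they differ only when the downstream
#' base makes a U tail ambiguous).
#'
#' @param simref result of [simulate_reference()].
#' @param cfg a [simulation_config()].
#' @param sample sample label; the per-sample RNG stream is derived
#'   deterministically from `cfg$seed` and the label.
#' @param mixture optional override of `cfg$mixture` (used for depletion
#'   pairs).
#' @param fastq_path optional path; when given, reads are also written as
#'   a 4-line-record FASTQ (DNA alphabet, fixed quality "I").
#' @return list with `reads` (collapsed data.frame as from
#'   [read_records()]) and `truth` (`GroundTruth`: per-read data.frame
#'   `sample`, `mirna`, `sequence`, `intended_category`,
#'   `observable_category`, plus attribute `mixture`).
#' @export
simulate_reads <- function(simref, cfg, sample, mixture = NULL,
                           fastq_path = NULL) {
  stopifnot(inherits(simref, "SimulatedReference"),
            inherits(cfg, "SimulationConfig"))
  if (is.null(mixture)) mixture <- cfg$mixture
  stopifnot(length(mixture) == 4L, abs(sum(mixture) - 1) < 1e-9,
            all(mixture >= -1e-12))
  mixture <- pmax(mixture, 0)
  refs <- simref$refs; truth0 <- simref$truth
  n <- cfg$depth_per_sample
  seed <- as.integer((as.numeric(cfg$seed) * 131 + str_hash(sample)) %%
                       2000000000)
  with_seed(seed, {
    mi <- sample.int(nrow(truth0), n, replace = TRUE, prob = truth0$weight)
    cat_i <- sample.int(4L, n, replace = TRUE, prob = mixture)
    cats <- c("WT", "U", "A", "other")[cat_i]
    mirna <- truth0$mirna[mi]
    mature <- refs$entries$sequence[match(mirna, refs$entries$name)]
    context <- refs$entries$downstream_context[match(mirna, refs$entries$name)]
    down1 <- substr(context, 1L, 1L)

    body_len <- rep(MATURE_LEN, n)
    minus1 <- cats == "WT" & stats::runif(n) < cfg$p_len_minus1
    body_len[minus1] <- MATURE_LEN - 1L

    tail <- character(n)
    oligo <- stats::runif(n) < cfg$oligo_tail_prob
    tail[cats == "U"] <- ifelse(oligo[cats == "U"], "UU", "U")
    tail[cats == "A"] <- ifelse(oligo[cats == "A"], "AA", "A")
    oth <- which(cats == "other")
    if (length(oth)) {
      # single C or G, never equal to the first context base
      pick <- ifelse(down1[oth] == "C", "G",
                     ifelse(down1[oth] == "G", "C",
                            c("C", "G")[1L + (stats::runif(length(oth)) < 0.5)]))
      tail[oth] <- pick
    }
    seqs <- paste0(substr(mature, 1L, body_len), tail)
    if (cfg$error_rate > 0) {
      hit <- which(stats::runif(n) < cfg$error_rate * nchar(seqs))
      for (j in hit) {
        pos <- sample.int(nchar(seqs[j]) - 1L, 1L)  # spare the 3' end
        old <- substr(seqs[j], pos, pos)
        substr(seqs[j], pos, pos) <- sample(setdiff(RNA_BASES, old), 1L)
      }
    }
    # observable category depends only on (miRNA, body_len, tail):
    # compute once per distinct isoform, then broadcast
    key <- paste(mirna, body_len, tail, sep = "\r")
    uk <- !duplicated(key)
    obs_u <- vapply(which(uk), function(j)
      observable_category(mature[j], context[j], body_len[j], tail[j]), "")
    obs <- obs_u[match(key, key[uk])]

    per_read <- data.frame(sample = sample, mirna = mirna, sequence = seqs,
                           intended_category = cats,
                           observable_category = obs,
                           stringsAsFactors = FALSE)
    attr(per_read, "mixture") <- structure(mixture,
                                           names = c("WT", "U", "A", "other"))
    class(per_read) <- c("GroundTruth", "data.frame")
    if (!is.null(fastq_path)) write_sim_fastq(seqs, fastq_path)
    list(reads = collapse_reads(seqs, rep(1L, n), sample), truth = per_read)
  })
}

# FASTQ writer: sequencer-style DNA alphabet, constant quality.
write_sim_fastq <- function(seqs, path) {
  dna <- chartr("U", "T", seqs)
  qual <- strrep("I", nchar(dna))
  ids <- sprintf("@simread%07d", seq_along(dna))
  con <- file(path, "wb")  # binary: byte-identical output across platforms
  on.exit(close(con))
  writeLines(as.vector(rbind(ids, dna, "+", qual)), con, sep = "\n")
  invisible(path)
}

#' Simulate a control / TUTase-depleted library pair
#'
#' The control sample uses `cfg$mixture`; the depleted sample's U mass is
#' scaled by `1 - u_reduction`, a fraction `a_gain` of the removed U mass
#' moves to A, and the remainder returns to WT. Defaults model the
#' observed depletion response: roughly a 3- to 4-fold drop in the U
#' fraction with a concomitant rise in A.
#'
#' @param cfg a [simulation_config()].
#' @param u_reduction fraction of U mass removed in the test sample, in
#'   (0, 1] (default 0.75, e.g. 8% to 2%).
#' @param a_gain fraction of the removed U mass transferred to A
#'   (default 1, e.g. 11% to 17%).
#' @param samples character(2): reference and test sample labels.
#' @param out_dir optional directory; when given, FASTQ files
#'   `<sample>.fastq` and the reference FASTA pair are written there.
#' @return list with `refs`, `reads` (row-bound collapsed reads of both
#'   samples), `truth` (row-bound per-read ground truth, attribute
#'   `mixtures` holding both mixtures), `mixtures`.
#' @export
make_depletion_pair <- function(cfg, u_reduction = 0.75, a_gain = 1.0,
                                samples = c("control", "depleted"),
                                out_dir = NULL) {
  stopifnot(inherits(cfg, "SimulationConfig"),
            u_reduction > 0, u_reduction <= 1, a_gain >= 0, a_gain <= 1,
            length(samples) == 2L, !anyDuplicated(samples))
  mix_ref <- cfg$mixture
  removed <- mix_ref[2L] * u_reduction
  mix_test <- c(mix_ref[1L] + (1 - a_gain) * removed,
                mix_ref[2L] - removed,
                mix_ref[3L] + a_gain * removed,
                mix_ref[4L])
  if (any(mix_test < -1e-12) || abs(sum(mix_test) - 1) > 1e-9)
    stop("depletion shift yields an invalid mixture")
  simref <- simulate_reference(cfg)
  fq <- function(s) if (is.null(out_dir)) NULL else
    file.path(out_dir, paste0(s, ".fastq"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  ref_lib <- simulate_reads(simref, cfg, samples[1L], mixture = mix_ref,
                            fastq_path = fq(samples[1L]))
  test_lib <- simulate_reads(simref, cfg, samples[2L], mixture = mix_test,
                             fastq_path = fq(samples[2L]))
  if (!is.null(out_dir)) {
    write_reference_fasta(simref$refs,
                          file.path(out_dir, "mature.fa"),
                          file.path(out_dir, "hairpin.fa"))
  }
  truth <- rbind(ref_lib$truth, test_lib$truth)
  class(truth) <- c("GroundTruth", "data.frame")
  mixtures <- list(mix_ref, mix_test)
  names(mixtures) <- samples
  attr(truth, "mixtures") <- mixtures
  list(refs = simref$refs, skeleton = simref$truth,
       reads = rbind(ref_lib$reads, test_lib$reads),
       truth = truth, mixtures = mixtures)
}
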