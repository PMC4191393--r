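#' Build a mature miRNA reference set
#'
#' A `ReferenceSet` holds mature miRNA sequences together with their hairpin
#' of origin, arm assignment (5p/3p), the 0-based offset of the mature 5'
#' end within the hairpin, and the genomic/hairpin bases immediately 3' of
#' the canonical mature end ("downstream context"). The downstream context
#' is what decides whether an observed 3' tail base is templated (genomic)
#' or non-templated, the analyte of the tail caller.
#'
#' Arm assignment follows miRBase practice: a `-5p`/`-3p` name suffix takes
#' precedence; otherwise the mature is located within its hairpin and called
#' 5p when its 5' end lies in the first half (midpoint = `floor(len/2)`,
#' 0-based). A suffix/position disagreement keeps the suffix and is recorded
#' in `attr(x, "log")`.
#'
#' @param mature named character vector of mature sequences (RNA or DNA;
#'   T is normalized to U).
#' @param hairpins optional named character vector of hairpin sequences.
#' @param hairpin_name optional character vector (parallel to `mature`)
#'   naming the hairpin each mature derives from. When `NULL`, a hairpin
#'   with the mature's name stripped of its `-5p`/`-3p` suffix is used if
#'   present, else each hairpin is searched for the mature as a substring.
#' @param context optional named character vector of explicit downstream
#'   context strings (0-6 nt); overrides hairpin-derived context.
#' @param species_tag short label (e.g. `"hsa"`) carried along for
#'   cross-species reports.
#' @return an object of class `ReferenceSet`: a list with elements
#'   `entries` (data.frame: name, sequence, hairpin_name, arm,
#'   hairpin_start, downstream_context, context_free), `hairpins`,
#'   `species_tag`. Record-level problems are collected in
#'   `attr(, "record_errors")` and reported as a warning.
#' @examples
#' rs <- reference_set(c("syn-mir-1-5p" = "ACGUACGUACGUACGUACGUAC"))
#' rs$entries$arm
#' @export
reference_set <- function(mature, hairpins = NULL, hairpin_name = NULL,
                          context = NULL, species_tag = "") {
  if (length(mature) == 0L) stop("empty reference: no mature sequences")
  if (is.null(names(mature)) || any(!nzchar(names(mature))))
    stop("mature sequences must be named")
  if (anyDuplicated(names(mature)))
    stop("duplicate mature miRNA names: ",
         paste(unique(names(mature)[duplicated(names(mature))]), collapse = ", "))
  mature <- vapply(mature, norm_rna, "", USE.NAMES = TRUE)
  check_rna(mature, "mature sequence")
  if (!is.null(hairpins)) {
    if (is.null(names(hairpins)) || anyDuplicated(names(hairpins)))
      stop("hairpins must be uniquely named")
    hairpins <- vapply(hairpins, norm_rna, "", USE.NAMES = TRUE)
    check_rna(hairpins, "hairpin sequence")
  } else {
    hairpins <- character(0)
  }
  nm <- names(mature)
  n <- length(nm)
  if (!is.null(hairpin_name) && length(hairpin_name) != n)
    stop("hairpin_name must be parallel to mature")

  log <- character(0)
  rec_err <- character(0)
  hp_name <- character(n)
  arm <- character(n)
  hp_start <- rep(NA_integer_, n)
  ctx <- character(n)
  ctx_free <- logical(n)

  suffix_arm <- function(name) {
    if (grepl("-5p$", name)) "5p" else if (grepl("-3p$", name)) "3p"
    else NA_character_
  }

  for (i in seq_len(n)) {
    name <- nm[i]
    seq <- mature[[i]]
    sarm <- suffix_arm(name)
    # resolve hairpin
    hpn <- NA_character_
    if (!is.null(hairpin_name) && !is.na(hairpin_name[i]) &&
        nzchar(hairpin_name[i])) {
      hpn <- hairpin_name[i]
      if (!hpn %in% names(hairpins)) {
        rec_err <- c(rec_err, sprintf("%s: hairpin '%s' not found", name, hpn))
        hpn <- NA_character_
      }
    } else if (length(hairpins)) {
      base <- sub("-[53]p$", "", name)
      if (base %in% names(hairpins)) {
        hpn <- base
      } else {
        hits <- names(hairpins)[vapply(hairpins, function(h)
          length(find_all(h, seq)) > 0L, TRUE)]
        if (length(hits) == 1L) hpn <- hits
        else if (length(hits) > 1L) {
          log <- c(log, sprintf("%s: found in %d hairpins; left unresolved",
                                name, length(hits)))
        }
      }
    }
    if (!is.na(hpn)) {
      hp <- hairpins[[hpn]]
      occ <- find_all(hp, seq)
      if (length(occ) == 0L) {
        rec_err <- c(rec_err,
                     sprintf("%s: mature not found in hairpin '%s'", name, hpn))
        hpn <- NA_character_
      } else if (length(occ) > 1L) {
        log <- c(log, sprintf("%s: %d occurrences in hairpin '%s'; arm ambiguous",
                              name, length(occ), hpn))
        hp_start[i] <- occ[1L] - 1L
        arm[i] <- if (!is.na(sarm)) sarm else "unknown"
      } else {
        hp_start[i] <- occ - 1L
        pos_arm <- if (hp_start[i] < nchar(hp) %/% 2L) "5p" else "3p"
        if (!is.na(sarm)) {
          if (sarm != pos_arm)
            log <- c(log, sprintf(
              "%s: name suffix says %s but position in hairpin says %s; keeping suffix",
              name, sarm, pos_arm))
          arm[i] <- sarm
        } else arm[i] <- pos_arm
      }
      if (!is.na(hpn) && !is.na(hp_start[i])) {
        from <- hp_start[i] + nchar(seq) + 1L
        ctx[i] <- substr(hairpins[[hpn]], from, from + 5L)
      }
    }
    if (is.na(hpn)) arm[i] <- if (!is.na(sarm)) sarm else "unknown"
    hp_name[i] <- hpn
  }

  # explicit context overrides hairpin-derived context
  if (!is.null(context)) {
    context <- vapply(context, norm_rna, "", USE.NAMES = TRUE)
    check_rna(context, "downstream context")
    if (any(nchar(context) > 6L)) stop("downstream context longer than 6 nt")
    hit <- intersect(names(context), nm)
    ctx[match(hit, nm)] <- context[hit]
  }
  ctx_free <- !nzchar(ctx)

  entries <- data.frame(
    name = nm, sequence = unname(mature), hairpin_name = hp_name,
    arm = arm, hairpin_start = hp_start, downstream_context = ctx,
    context_free = ctx_free, stringsAsFactors = FALSE)
  entries <- entries[order(entries$name), , drop = FALSE]
  rownames(entries) <- NULL

  out <- structure(
    list(entries = entries, hairpins = hairpins, species_tag = species_tag),
    class = "ReferenceSet")
  attr(out, "log") <- log
  attr(out, "record_errors") <- rec_err
  if (length(rec_err))
    warning(length(rec_err), " reference record(s) with errors; see ",
            "attr(x, 'record_errors')", call. = FALSE)
  out
}

#' Load miRNA reference sequences from FASTA (and optional context TSV)
#'
#' Reads a mature-miRNA FASTA (miRBase-style naming, record IDs up to the
#' first whitespace), an optional hairpin FASTA, and an optional two-column
#' context TSV (`name<TAB>downstream bases`, `#` comments allowed) giving
#' explicit downstream genomic context for matures whose hairpin is absent
#' or truncated at the Dicer cut.
#'
#' @param mature_path path to mature FASTA (required).
#' @param hairpin_path optional path to hairpin FASTA.
#' @param context_path optional path to context TSV.
#' @param species_tag see [reference_set()].
#' @return a `ReferenceSet`; see [reference_set()].
#' @export
load_references <- function(mature_path, hairpin_path = NULL,
                            context_path = NULL, species_tag = "") {
  mature <- read_fasta_named(mature_path, "mature FASTA")
  hairpins <- if (!is.null(hairpin_path))
    read_fasta_named(hairpin_path, "hairpin FASTA") else NULL
  context <- NULL
  if (!is.null(context_path)) {
    lines <- readLines(context_path)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    if (length(lines)) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      bad <- lengths(parts) < 2L
      if (any(bad)) stop("malformed context TSV line: ", lines[bad][1L])
      context <- vapply(parts, `[`, "", 2L)
      names(context) <- vapply(parts, `[`, "", 1L)
    }
  }
  reference_set(mature, hairpins = hairpins, context = context,
                species_tag = species_tag)
}

# FASTA reader returning a named character vector; IDs cut at whitespace.
read_fasta_named <- function(path, what) {
  if (!file.exists(path)) stop(what, " not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop(what, " is empty: ", path)
  x <- as.character(ss)
  names(x) <- sub("\\s.*$", "", names(ss))
  x
}

#' Write a ReferenceSet back to FASTA
#'
#' @param refs a `ReferenceSet`.
#' @param mature_path output path for mature sequences.
#' @param hairpin_path optional output path for hairpins.
#' @return invisibly, `mature_path`.
#' @export
write_reference_fasta <- function(refs, mature_path, hairpin_path = NULL) {
  stopifnot(inherits(refs, "ReferenceSet"))
  ss <- Biostrings::BStringSet(structure(refs$entries$sequence,
                                         names = refs$entries$name))
  Biostrings::writeXStringSet(ss, mature_path)
  if (!is.null(hairpin_path) && length(refs$hairpins)) {
    hs <- Biostrings::BStringSet(refs$hairpins)
    Biostrings::writeXStringSet(hs, hairpin_path)
  }
  invisible(mature_path)
}

#' Assign the precursor arm of a mature sequence
#'
#' 5p when the mature 5' end lies in the first half of the hairpin
#' (midpoint `floor(len/2)`, 0-based), 3p otherwise. A `-5p`/`-3p` suffix
#' on `name` takes precedence; a disagreement is reported as a message.
#'
#' @param mature mature sequence (RNA/DNA).
#' @param hairpin hairpin sequence containing the mature exactly once.
#' @param name optional mature name whose suffix, if any, wins.
#' @return `"5p"`, `"3p"`, or `"unknown"` (multiple occurrences, with a
#'   warning).
#' @export
assign_arm <- function(mature, hairpin, name = NULL) {
  mature <- norm_rna(mature); hairpin <- norm_rna(hairpin)
  occ <- find_all(hairpin, mature)
  if (length(occ) == 0L) stop("mature sequence not found in hairpin")
  sarm <- if (!is.null(name) && grepl("-5p$", name)) "5p"
  else if (!is.null(name) && grepl("-3p$", name)) "3p" else NA_character_
  if (length(occ) > 1L) {
    warning("mature occurs ", length(occ), " times in hairpin; arm ambiguous")
    return(if (!is.na(sarm)) sarm else "unknown")
  }
  pos_arm <- if ((occ - 1L) < nchar(hairpin) %/% 2L) "5p" else "3p"
  if (!is.na(sarm)) {
    if (sarm != pos_arm)
      message("name suffix (", sarm, ") disagrees with position (", pos_arm,
              "); keeping suffix")
    return(sarm)
  }
  pos_arm
}

#' Downstream genomic context of a mature miRNA
#'
#' Returns up to `k` bases immediately 3' of the canonical mature 3' end,
#' taken from the entry's stored context (explicit or hairpin-derived).
#' When no context source exists the result is `""` with attribute
#' `context_free = TRUE`: downstream templating checks then treat every
#' tail base as untemplated-callable but mark the calls context-free.
#'
#' @param refs a `ReferenceSet`.
#' @param name mature miRNA name.
#' @param k number of bases requested (1-6; default 3, enough for the
#'   short mono-/oligo-tails this package calls).
#' @return RNA string of length 0..k with attribute `context_free`.
#' @export
get_downstream_context <- function(refs, name, k = 3L) {
  stopifnot(inherits(refs, "ReferenceSet"), k >= 1L, k <= 6L)
  i <- match(name, refs$entries$name)
  if (is.na(i)) stop("unknown miRNA: ", name)
  ctx <- substr(refs$entries$downstream_context[i], 1L, k)
  structure(ctx, context_free = refs$entries$context_free[i])
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat(sprintf("ReferenceSet%s: %d mature miRNAs, %d hairpins\n",
              if (nzchar(x$species_tag)) paste0(" [", x$species_tag, "]") else "",
              nrow(x$entries), length(x$hairpins)))
  cat("  arms:", paste(sprintf("%s=%d", names(table(x$entries$arm)),
                               table(x$entries$arm)), collapse = " "), "\n")
  invisible(x)
}
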