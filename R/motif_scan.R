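#' Bipartite TUTase-substrate motif specification
#'
#' The default motif is GUAG followed (non-overlapping, any gap) by UUGU,
#' the bipartite signal that marks mature miRNAs as preferred substrates of
#' the terminal uridylyl transferases Zcchc6 (TUT7) and Zcchc11 (TUT4).
#' The strict variant requires UUUGU for the second element; among
#' wild-type let-7 family members only let-7g and let-7i carry it.
#'
#' @param element1 first element (default `"GUAG"`).
#' @param element2 second element (default `"UUGU"`).
#' @param strict_element2 strict second element (default `"UUUGU"`).
#' @param min_gap minimum number of bases between the end of element1 and
#'   the start of element2 (default 0; the gap is unbounded above).
#' @param require_order if `TRUE` (default) element2 must start at or after
#'   the end of an element1 occurrence; if `FALSE` both elements merely
#'   need to occur.
#' @param one_mismatch_element2 allow one mismatch in element2 (default
#'   off). Some family members (e.g. let-7d, miR-99b) are missed by the
#'   exact motif through a single U-to-C change at the last UUGU position;
#'   this flag recovers them at the cost of specificity.
#' @return a `MotifSpec` list.
#' @export
motif_spec <- function(element1 = "GUAG", element2 = "UUGU",
                       strict_element2 = "UUUGU", min_gap = 0L,
                       require_order = TRUE, one_mismatch_element2 = FALSE) {
  element1 <- norm_rna(element1); element2 <- norm_rna(element2)
  strict_element2 <- norm_rna(strict_element2)
  check_rna(c(element1, element2, strict_element2), "motif element")
  if (!nzchar(element1) || !nzchar(element2)) stop("motif elements must be non-empty")
  if (min_gap < 0L) stop("min_gap must be >= 0")
  structure(list(element1 = element1, element2 = element2,
                 strict_element2 = strict_element2, min_gap = as.integer(min_gap),
                 require_order = isTRUE(require_order),
                 one_mismatch_element2 = isTRUE(one_mismatch_element2)),
            class = "MotifSpec")
}

# occurrences of `pat` in `x`, overlapping, optionally with <=1 mismatch
motif_hits <- function(x, pat, one_mm = FALSE) {
  if (!one_mm) return(find_all(x, pat))
  np <- nchar(pat); nx <- nchar(x)
  if (nx < np) return(integer(0))
  pv <- substring(pat, seq_len(np), seq_len(np))
  starts <- seq_len(nx - np + 1L)
  keep <- vapply(starts, function(s) {
    w <- substring(x, s + seq_len(np) - 1L, s + seq_len(np) - 1L)
    sum(w != pv) <= 1L
  }, TRUE)
  starts[keep]
}

#' Scan one sequence for the bipartite motif
#'
#' A sequence matches when some occurrence of element2 starts at index
#' >= (start of some element1 occurrence + length(element1) + min_gap).
#' All element1 occurrences are reported (self-overlaps allowed: let-7
#' members typically carry two overlapping GUAG hits). The strict flag is
#' computed identically with the strict element2 (UUUGU by default).
#'
#' @param seq RNA (or DNA) sequence; empty allowed, matching is
#'   case-insensitive after normalization.
#' @param spec a [motif_spec()].
#' @return a `MotifMatch` list: `matched` (logical), `e1_positions`
#'   (0-based starts of all element1 occurrences), `e2_position` (0-based
#'   start of the first valid element2 occurrence, or `NA`), `strict`.
#' @examples
#' scan_sequence("UGAGGUAGUAGUUUGUACAGUU")  # let-7g: matched, strict
#' @export
scan_sequence <- function(seq, spec = motif_spec()) {
  seq <- norm_rna(seq)
  check_rna(seq)
  e1 <- motif_hits(seq, spec$element1)
  pick_e2 <- function(pat, one_mm = FALSE) {
    e2 <- motif_hits(seq, pat, one_mm)
    if (length(e1) == 0L || length(e2) == 0L) return(NA_integer_)
    if (!spec$require_order) return(e2[1L])
    min_start <- min(e1) + nchar(spec$element1) + spec$min_gap
    ok <- e2[e2 >= min_start]
    if (length(ok)) ok[1L] else NA_integer_
  }
  e2pos <- pick_e2(spec$element2, spec$one_mismatch_element2)
  strictpos <- pick_e2(spec$strict_element2)
  structure(list(matched = !is.na(e2pos),
                 e1_positions = e1 - 1L,
                 e2_position = if (is.na(e2pos)) NA_integer_ else e2pos - 1L,
                 strict = !is.na(strictpos)),
            class = "MotifMatch")
}

#' Scan every mature entry of a ReferenceSet for the motif
#'
#' @param refs a `ReferenceSet`.
#' @param spec a [motif_spec()].
#' @return data.frame (one row per mature entry, lexicographic by name):
#'   `name`, `matched`, `e1_positions` (comma-separated 0-based starts),
#'   `e2_position`, `strict`, `arm`.
#' @export
scan_reference_set <- function(refs, spec = motif_spec()) {
  stopifnot(inherits(refs, "ReferenceSet"))
  e <- refs$entries[order(refs$entries$name), , drop = FALSE]
  ms <- lapply(e$sequence, scan_sequence, spec = spec)
  data.frame(
    name = e$name,
    matched = vapply(ms, `[[`, TRUE, "matched"),
    e1_positions = vapply(ms, function(m)
      paste(m$e1_positions, collapse = ","), ""),
    e2_position = vapply(ms, `[[`, NA_integer_, "e2_position"),
    strict = vapply(ms, `[[`, TRUE, "strict"),
    arm = e$arm,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-species intersection of motif-matched miRNAs
#'
#' Compares the motif-matched entries of two scanned reference sets (e.g.
#' mouse vs human) after stripping species prefixes (`mmu-`, `hsa-`, ...)
#' and applying an optional synonym map.
#'
#' @param a,b data.frames from [scan_reference_set()].
#' @param synonym_map optional named character vector mapping normalized
#'   names in `a`/`b` to canonical names.
#' @return list with `a_only`, `b_only`, `common` counts and the
#'   corresponding name vectors (`a_only_names` etc.).
#' @export
intersect_species <- function(a, b, synonym_map = NULL) {
  normalize <- function(x) {
    x <- sub("^[a-z]{3,4}-", "", x)
    if (!is.null(synonym_map)) {
      hit <- x %in% names(synonym_map)
      x[hit] <- unname(synonym_map[x[hit]])
    }
    x
  }
  am <- unique(normalize(a$name[a$matched]))
  bm <- unique(normalize(b$name[b$matched]))
  common <- sort(intersect(am, bm))
  ao <- sort(setdiff(am, bm)); bo <- sort(setdiff(bm, am))
  list(a_only = length(ao), b_only = length(bo), common = length(common),
       a_only_names = ao, b_only_names = bo, common_names = common)
}
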