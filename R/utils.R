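# Internal helpers shared across modules. All sequences inside the package
# are uppercase RNA (A/C/G/U); conversion happens once, at input boundaries.

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a character vector of sequences to the RNA alphabet
#'
#' Uppercases and converts T to U. Validation is separate (`check_rna()`)
#' so that callers can decide between hard errors and record-level reports.
#'
#' @param x character vector of sequences (DNA or RNA, any case).
#' @return character vector over the RNA alphabet.
#' @keywords internal
#' @noRd
norm_rna <- function(x) {
  chartr("T", "U", toupper(x))
}

# Stop unless every sequence is over {A,C,G,U}. Empty strings allowed.
check_rna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-RNA characters: %s", what,
                 paste(utils::head(x[bad], 3L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

# Length of the longest common prefix of two strings.
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- substring(a, seq_len(n), seq_len(n))
  bv <- substring(b, seq_len(n), seq_len(n))
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Small deterministic hash of a string onto 0..10^6-1, used to derive
# per-sample sub-seeds from one master seed (kept far below 2^31).
str_hash <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 1000000
  as.integer(h)
}

# All start positions (1-based) of fixed pattern `pat` in `x`, overlapping.
find_all <- function(x, pat) {
  np <- nchar(pat)
  nx <- nchar(x)
  if (np == 0L || nx < np) return(integer(0))
  starts <- seq_len(nx - np + 1L)
  starts[substring(x, starts, starts + np - 1L) == pat]
}
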