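# Independent oracles. These deliberately share no code with the package
# internals: plain loops, explicit enumeration, closed forms.

# --- brute-force read classifier -------------------------------------------
# refs: list(name -> list(mature=, context=)); returns list(mirna, category,
# matched_len, tail) or NULL (unassigned), mirroring the stated matching
# rules by exhaustive enumeration of admissible (miRNA, matched_len) pairs.
oracle_classify <- function(read, refs, max_mm = 0L, max_tail = 3L,
                            policy = "flag") {
  cand <- list()
  for (nm in names(refs)) {
    mat <- refs[[nm]]$mature
    L <- nchar(mat)
    best_l <- NA_integer_; best_mm <- NA_integer_
    for (l in seq_len(min(L, nchar(read)))) {
      if (l < L - 2L) next
      if (nchar(read) - l > max_tail) next
      mm <- 0L
      for (i in seq_len(l))
        if (substr(read, i, i) != substr(mat, i, i)) mm <- mm + 1L
      if (mm > max_mm) next
      if (substr(read, l, l) != substr(mat, l, l)) next
      if (is.na(best_l) || l > best_l) { best_l <- l; best_mm <- mm }
    }
    if (!is.na(best_l))
      cand[[length(cand) + 1L]] <- list(mirna = nm, l = best_l, mm = best_mm)
  }
  if (length(cand) == 0L) return(NULL)
  ls <- vapply(cand, `[[`, 0L, "l")
  mms <- vapply(cand, `[[`, 0L, "mm")
  keep <- which(ls == max(ls))
  keep <- keep[mms[keep] == min(mms[keep])]
  if (length(keep) > 1L) return(NULL)              # multi-mapper tie
  b <- cand[[keep]]
  mat <- refs[[b$mirna]]$mature
  tail <- substr(read, b$l + 1L, nchar(read))
  ext <- paste0(substr(mat, b$l + 1L, nchar(mat)), refs[[b$mirna]]$context)
  tpl <- 0L
  while (tpl < nchar(tail) &&
         substr(tail, tpl + 1L, tpl + 1L) == substr(ext, tpl + 1L, tpl + 1L))
    tpl <- tpl + 1L
  unt <- substr(tail, tpl + 1L, nchar(tail))
  if (policy == "count_untemplated") unt <- tail
  category <- if (nchar(tail) == 0L) "WT"
  else if (nchar(unt) == 0L) {
    if (all(strsplit(tail, "")[[1]] == "U") ||
        all(strsplit(tail, "")[[1]] == "A")) "ambiguous" else "WT"
  } else {
    ch <- strsplit(unt, "")[[1]]
    if (all(ch == "U")) "U" else if (all(ch == "A")) "A" else "other"
  }
  list(mirna = b$mirna, category = category, matched_len = b$l, tail = tail)
}

# --- exact two-sided Fisher by direct enumeration --------------------------
# Point probabilities from log-binomial coefficients; sums all tables with
# the observed margins whose probability is <= that of the observed table.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  xs <- max(0, k - n):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  p_obs <- logp[xs == a]
  min(1, sum(exp(logp)[exp(logp) <= exp(p_obs) * (1 + 1e-7)]))
}

# --- regular-expression motif oracle ---------------------------------------
oracle_motif <- function(seq, e1 = "GUAG", e2 = "UUGU", min_gap = 0L) {
  grepl(paste0(e1, ".{", min_gap, ",}", e2), seq)
}
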