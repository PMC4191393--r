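#' Filter configuration for uridylated-miRNA selection
#'
#' Defaults mirror the composition-analysis filters used for ranking
#' uridylated species: at least 10 RPM of category-U reads and a U
#' fraction of at least 1% in the designated reference (control) sample,
#' restricted to 5p-arm miRNAs (only 5p species allow unambiguous
#' post-Dicer tail interpretation).
#'
#' @param min_urid_rpm minimum category-U RPM (default 10).
#' @param min_urid_fraction minimum U fraction of the miRNA's reads
#'   (default 0.01).
#' @param arm_restriction one of `"5p"`, `"3p"`, `"none"` (default 5p).
#' @param reference_sample sample in which thresholds are evaluated.
#' @return a `FilterConfig` list.
#' @export
filter_config <- function(min_urid_rpm = 10.0, min_urid_fraction = 0.01,
                          arm_restriction = c("5p", "3p", "none"),
                          reference_sample = NULL) {
  arm_restriction <- match.arg(arm_restriction)
  stopifnot(min_urid_rpm >= 0, min_urid_fraction >= 0,
            min_urid_fraction <= 1)
  structure(list(min_urid_rpm = min_urid_rpm,
                 min_urid_fraction = min_urid_fraction,
                 arm_restriction = arm_restriction,
                 reference_sample = reference_sample),
            class = "FilterConfig")
}

#' Select uridylated miRNAs passing the expression filters
#'
#' Returns the miRNAs (restricted to the configured arm) whose
#' category-U reads in the reference sample meet *both* thresholds,
#' ordered by descending U fraction (ties broken by name).
#'
#' @param ct a `CompositionTable`.
#' @param cfg a [filter_config()]; `cfg$reference_sample` must be present
#'   in `ct`.
#' @return character vector of miRNA names.
#' @export
filter_uridylated <- function(ct, cfg = filter_config()) {
  stopifnot(inherits(ct, "CompositionTable"))
  rs <- cfg$reference_sample
  if (is.null(rs)) stop("filter_config$reference_sample must be set")
  if (!rs %in% ct$sample) stop("sample '", rs, "' missing from composition table")
  x <- ct[ct$sample == rs, , drop = FALSE]
  if (cfg$arm_restriction != "none")
    x <- x[x$arm == cfg$arm_restriction, , drop = FALSE]
  x <- x[x$u_rpm >= cfg$min_urid_rpm &
         x$frac_U >= cfg$min_urid_fraction, , drop = FALSE]
  x <- x[order(-x$frac_U, x$mirna), , drop = FALSE]
  x$mirna
}

#' Compare uridylation/adenylation fractions between two conditions
#'
#' For each surviving miRNA, reports the U and A fractions in the
#' reference and test samples, their differences, the U fold change
#' (reference/test; infinite with a flag when the test fraction is 0),
#' the rank by U fraction in the reference sample and the rank by A
#' fraction in the test sample (ties broken lexicographically).
#'
#' @param ct a `CompositionTable` holding both samples.
#' @param ref_sample,test_sample sample labels.
#' @param survivors miRNA names, typically from [filter_uridylated()].
#' @return a `ConditionComparison` data.frame, one row per survivor.
#' @export
compare_conditions <- function(ct, ref_sample, test_sample, survivors) {
  stopifnot(inherits(ct, "CompositionTable"))
  for (s in c(ref_sample, test_sample))
    if (!s %in% ct$sample) stop("sample '", s, "' missing from composition table")
  get_fracs <- function(sample) {
    x <- ct[ct$sample == sample, , drop = FALSE]
    i <- match(survivors, x$mirna)
    if (anyNA(i))
      warning("miRNA(s) absent from sample '", sample, "': ",
              paste(survivors[is.na(i)], collapse = ", "),
              "; using fraction 0", call. = FALSE)
    list(U = ifelse(is.na(i), 0, x$frac_U[i]),
         A = ifelse(is.na(i), 0, x$frac_A[i]))
  }
  fr <- get_fracs(ref_sample); ft <- get_fracs(test_sample)
  fU_ref <- fr$U; fU_test <- ft$U
  fA_ref <- fr$A; fA_test <- ft$A
  fold <- ifelse(fU_test == 0,
                 ifelse(fU_ref == 0, 1, Inf), fU_ref / fU_test)
  out <- data.frame(
    mirna = survivors,
    fraction_U_ref = fU_ref, fraction_U_test = fU_test,
    fraction_A_ref = fA_ref, fraction_A_test = fA_test,
    delta_U = fU_test - fU_ref, delta_A = fA_test - fA_ref,
    fold_change_U = fold, fold_infinite = is.infinite(fold),
    stringsAsFactors = FALSE)
  out$rank_by_U_reference <- rank_desc(out$fraction_U_ref, out$mirna)
  out$rank_by_A_test <- rank_desc(out$fraction_A_test, out$mirna)
  class(out) <- c("ConditionComparison", "data.frame")
  out
}

# dense 1..n ranking by descending value, ties broken by name
rank_desc <- function(v, nm) {
  ord <- order(-v, nm)
  r <- integer(length(v)); r[ord] <- seq_along(v)
  r
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value obtained by conditioning on the margins and summing, over
#' the hypergeometric support, the probabilities of all tables whose point
#' probability does not exceed that of the observed table (the
#' conventional minimum-likelihood two-sided rule, with the standard
#' `1 + 1e-7` relative tolerance for floating-point ties).
#'
#' @param table 2x2 matrix (or coercible) of non-negative integer counts.
#' @return list with `p` (in (0, 1]) and `table`. A degenerate margin
#'   (an all-zero row or column pair making the table uninformative)
#'   returns `p = 1` with a warning.
#' @examples
#' fisher_exact(matrix(c(10, 0, 0, 10), 2))$p
#' @export
fisher_exact <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tb < 0)) stop("negative cell counts")
  if (any(tb != round(tb))) stop("cell counts must be integers")
  a <- tb[1, 1]; b <- tb[1, 2]; cc <- tb[2, 1]; d <- tb[2, 2]
  m <- a + b; n <- cc + d; k <- a + cc
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    warning("degenerate margin; p = 1", call. = FALSE)
    return(list(p = 1, table = tb))
  }
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- dens[match(a, support)]
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  list(p = min(p, 1), table = tb)
}

#' Enrichment of a predicted miRNA set in a ranked list
#'
#' Cross-tabulates membership in a ranked list (e.g. miRNAs with
#' uridylation changes) against membership in a predicted set (e.g.
#' motif-positive miRNAs) over a universe, and applies [fisher_exact()].
#'
#' @param predicted character vector, subset of `universe`.
#' @param ranked_list character vector, subset of `universe`.
#' @param universe character vector of all considered miRNAs (non-empty).
#' @return list with `table` (2x2: rows in-list/not-in-list, columns
#'   predicted/not-predicted) and `p`.
#' @export
enrichment_test <- function(predicted, ranked_list, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  predicted <- unique(predicted); ranked_list <- unique(ranked_list)
  if (!all(ranked_list %in% universe)) stop("ranked_list not within universe")
  if (!all(predicted %in% universe)) stop("predicted not within universe")
  inl <- universe %in% ranked_list
  prd <- universe %in% predicted
  tb <- matrix(c(sum(inl & prd), sum(inl & !prd),
                 sum(!inl & prd), sum(!inl & !prd)),
               nrow = 2L, byrow = TRUE,
               dimnames = list(c("in_list", "not_in_list"),
                               c("predicted", "not_predicted")))
  c(fisher_exact(tb)["p"], list(table = tb))
}

#' Test for compensatory adenylation upon uridylation loss
#'
#' Tabulates category-U against category-A read counts of one miRNA in a
#' reference vs test sample and applies [fisher_exact()]. The direction is
#' `"compensatory"` when the U fraction decreases while the A fraction
#' increases from reference to test.
#'
#' @param ct a `CompositionTable`.
#' @param mirna miRNA name present in both samples.
#' @param ref_sample,test_sample sample labels.
#' @return list with `table` (rows ref/test, columns U/A), `p`,
#'   `direction` (`"compensatory"` or `"non-compensatory"`).
#' @export
compensation_test <- function(ct, mirna, ref_sample, test_sample) {
  stopifnot(inherits(ct, "CompositionTable"))
  row_of <- function(sample) {
    x <- ct[ct$sample == sample & ct$mirna == mirna, , drop = FALSE]
    if (nrow(x) != 1L)
      stop("miRNA '", mirna, "' not present exactly once in sample '",
           sample, "'")
    x
  }
  r <- row_of(ref_sample); t <- row_of(test_sample)
  tb <- matrix(c(r$n_U, r$n_A, t$n_U, t$n_A), nrow = 2L, byrow = TRUE,
               dimnames = list(c(ref_sample, test_sample), c("U", "A")))
  if (all(tb == 0)) {
    warning("all four cells zero; p undefined, returning 1", call. = FALSE)
    return(list(table = tb, p = 1, direction = "non-compensatory"))
  }
  p <- fisher_exact(tb)$p
  comp <- (t$frac_U < r$frac_U) && (t$frac_A > r$frac_A)
  list(table = tb, p = p,
       direction = if (comp) "compensatory" else "non-compensatory")
}

#' Concordance of per-miRNA total abundance between two samples
#'
#' Squared Pearson correlation of `log10(RPM + 1)` across miRNAs shared
#' by the two samples; the log transform matches the log-scaled
#' per-miRNA RPM scatter this comparison reproduces, and the pseudocount
#' avoids log(0).
#'
#' @param ct a `CompositionTable`.
#' @param ref_sample,test_sample sample labels.
#' @return R-squared (numeric scalar). Errors with fewer than 3 shared
#'   miRNAs.
#' @export
abundance_concordance <- function(ct, ref_sample, test_sample) {
  stopifnot(inherits(ct, "CompositionTable"))
  xr <- ct[ct$sample == ref_sample, , drop = FALSE]
  xt <- ct[ct$sample == test_sample, , drop = FALSE]
  shared <- intersect(xr$mirna, xt$mirna)
  if (length(shared) < 3L) stop("fewer than 3 shared miRNAs")
  a <- log10(xr$rpm[match(shared, xr$mirna)] + 1)
  b <- log10(xt$rpm[match(shared, xt$mirna)] + 1)
  stats::cor(a, b)^2
}
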