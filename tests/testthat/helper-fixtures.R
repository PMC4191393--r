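# Guide-strand oligo fixtures (synthetic RNAs used in the in vitro
# uridylation assays) with their known motif match status.
GUIDE_OLIGOS <- c(
  "let-7g"          = "UGAGGUAGUAGUUUGUACAGUU",
  "let-7i"          = "UGAGGUAGUAGUUUGUGCUGUU",
  "GL2"             = "UCGAAGUAUUCCGCGUACGUU",
  "GL2-with-motif"  = "UCGAAGUGUAGUUUGUACGUU",
  "miR-10a"         = "UACCCUGUAGAUCCGAAUUUGUG",
  "miR-26a"         = "UUCAAGUAAUCCAGGAUAGGC",
  "let-7i-d12-mut"  = "UAGUCGCUGCAUUUGUGCUGUU",
  "let-7i-d23-mut"  = "UGAGGUAUGCAGCCUAGCUGUU",
  "let-7i-d123-mut" = "UAGUCGCUGCAGCCUAGCUGUU",
  "miR-10a-dbl-mut" = "UACCCUUGCAAUCCGAAGCCUAG",
  "let-7g+A"        = "UGAGGUAGUAGUUUGUACAGUUA",
  "let-7g+U"        = "UGAGGUAGUAGUUUGUACAGUUU")

GUIDE_EXPECT_MATCH <- c(
  "let-7g" = TRUE, "let-7i" = TRUE, "GL2" = FALSE, "GL2-with-motif" = TRUE,
  "miR-10a" = TRUE, "miR-26a" = FALSE, "let-7i-d12-mut" = FALSE,
  "let-7i-d23-mut" = FALSE, "let-7i-d123-mut" = FALSE,
  "miR-10a-dbl-mut" = FALSE, "let-7g+A" = TRUE, "let-7g+U" = TRUE)

# A tiny two-miRNA reference with hairpins, used across modules. The
# downstream base of mir-b is U (templating-ambiguity case).
tiny_refs <- function() {
  mature <- c("tst-mir-a-5p" = "UGAGGUAGUAGCAAGUACAGCC",
              "tst-mir-b-5p" = "UACCCUGUAGAACCGAAUUUGC")
  hairpins <- c(
    "tst-mir-a" = paste0("GGCAU", mature[[1]], "CAGGGUCACCCAUCGAAAGCU",
                         "GGCUGUACUUGCUACUACCUCAGC"),
    "tst-mir-b" = paste0("AGCUU", mature[[2]], "UGUAAUUUAGCUUCCAUGUCG",
                         "GCAAAUUCGGUUCUACAGGGUAG"))
  reference_set(mature, hairpins = hairpins)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random RNA string helper for property-style tests
rand_rna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len[i], replace = TRUE),
          collapse = ""), "")
}
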