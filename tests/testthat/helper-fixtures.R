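# Shared fixtures: seeded random sequences, the 24 assignment orders, and the
# three-column reference grouping of assignments used in several tests.

# Strip names and non-dim attributes so value comparisons are exact.
bare <- function(m) array(as.numeric(m), dim = dim(m))

rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

all_assignments <- function() {
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1L, function(p) length(unique(p)) == 4L), ]
  unname(apply(perms, 1L, function(p) paste(c("A", "C", "G", "T")[p], collapse = "")))
}

# The three slope-equivalence classes (columns s1, s2, s3).
reference_classes <- list(
  `1` = c("ACGT", "ACTG", "CAGT", "CATG", "GTAC", "GTCA", "TGAC", "TGCA"),
  `2` = c("AGCT", "AGTC", "GACT", "GATC", "CTAG", "CTGA", "TCAG", "TCGA"),
  `3` = c("ATCG", "ATGC", "TACG", "TAGC", "CGAT", "CGTA", "GCAT", "GCTA")
)

# Minimal slope series data frame for region tests.
fake_series <- function(starts, window, slopes) {
  data.frame(window_start = starts, window_end = starts + window - 1L,
             slope = slopes, e1 = NA_real_, e2 = NA_real_,
             flag = ifelse(is.na(slopes), "missing",
                           ifelse(is.infinite(slopes),
                                  ifelse(slopes > 0, "pos_inf", "neg_inf"),
                                  "finite")))
}
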