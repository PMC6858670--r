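# Fixtures are built in code at test time; nothing binary ships with the
# package.

write_plain_fixture <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("feature\tS1\tS2",
               "gene1\t10\t0",
               "gene2\t5\t5",
               "gene3\t100\t1"), path)
  path
}

write_taxonomy_fixture <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("feature\tS1\tS2\ttaxonomy",
               "otu1\t10\t0\tk__Bacteria;p__Firmicutes",
               "otu2\t5\t5\tk__Bacteria;p__Actinobacteria",
               "otu3\t100\t1\tk__Bacteria;p__Firmicutes"), path)
  path
}

write_goslim_fixture <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("go_id\tdescription\tcategory\tS1\tS2",
               "GO:0008150\tbiological process\tbiological_process\t40\t7"),
             path)
  path
}

write_metadata_fixture <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("sample\tbv\tph",
               "S1\tpositive\t4.2",
               "S2\tnegative\t5.0",
               "S3\tpositive\t4.4",
               "S4\tnegative\tNA"), path)
  path
}

random_count_table <- function(D = 8, S = 6, seed = 1, lambda = 30) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(D * S, lambda) + 1L, nrow = D,
                dimnames = list(sprintf("f%02d", 1:D),
                                sprintf("s%02d", 1:S)))
    count_table(m)
  })
}

# A hand-built Monte-Carlo ensemble with arbitrary CLR-like values, for
# oracle tests that do not care about the Dirichlet step.
manual_ensemble <- function(values, K) {
  # values: features x samples x K array
  structure(list(clr = values, K = K, prior = 0.5, seed = 0L),
            class = "mc_ensemble")
}

# ---- Independent brute-force oracle for the effect estimands -------------
# Plain loops and sorting only; shares no code with effect_statistics().
oracle_effect_stats <- function(a, b) {
  btw <- numeric(0)
  for (x in b) for (y in a) btw <- c(btw, x - y)
  btw <- sort(btw)
  med <- function(v) {
    n <- length(v); v <- sort(v)
    if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }
  win_med <- function(v) {
    d <- numeric(0)
    n <- length(v)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d <- c(d, abs(v[i] - v[j]))
    med(d)
  }
  n_pos <- sum(btw > 0); n_zero <- sum(btw == 0)
  f_pos <- (n_pos + n_zero / 2) / length(btw)
  wa <- win_med(a); wb <- win_med(b)
  dw <- max(wa, wb)
  db <- med(btw)
  list(diff_btw = db, diff_win = dw,
       effect = if (dw > 0) db / dw else if (db == 0) 0 else sign(db) * Inf,
       overlap = min(f_pos, 1 - f_pos))
}
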