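# quick CtDataset constructor for tests
make_ds <- function(ct, feats = NULL, samples = NULL, flags = NULL,
                    categories = NULL) {
  ct <- as.matrix(ct)
  ct_dataset(ct,
             feature_names = feats %||% sprintf("g%02d", seq_len(nrow(ct))),
             sample_names = samples %||% sprintf("s%02d", seq_len(ncol(ct))),
             flags = flags, categories = categories)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a Plain-dialect report file; rows = list of character vectors
write_report <- function(rows, path = tempfile(fileext = ".txt")) {
  writeLines(vapply(rows, paste, "", collapse = "\t"), path)
  path
}

write_treatment <- function(samples, groups,
                            path = tempfile(fileext = ".tsv")) {
  writeLines(c("SampleName\tTreatment", paste(samples, groups, sep = "\t")),
             path)
  path
}

# all permutations of 1..n as matrix rows
perms_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, sub + (sub >= k))))
}

two_group_tm <- function(n_cal = 3L, n_tar = 3L) {
  treatment_map(sprintf("s%02d", seq_len(n_cal + n_tar)),
                rep(c("A", "B"), c(n_cal, n_tar)))
}
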