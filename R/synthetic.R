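#' Synthetic labeled dataset of sequences and PSSMs
#'
#' Generates a multi-class set of protein sequences with class-specific
#' residue composition together with per-protein L x 20 integer score
#' matrices with class-specific column profiles. How much of each class's
#' discriminative signal sits in the sequence/composition block versus the
#' PSSM block is set per class by `signal_split`: 1 puts all of a class's
#' signal into its residue composition (its PSSM profile stays at the
#' shared baseline), 0 puts it all into the PSSM columns (its composition
#' stays uniform).
#'
#' Per class c, the residue profile is
#' `softmax(signal_split[c] * composition_concentration * z_c)` with `z_c`
#' a standard-normal 20-vector, so the deviation from the uniform
#' composition scales with `signal_split[c] * composition_concentration`.
#' Sequences are drawn i.i.d. from that profile with lengths uniform in
#' `length_range`. Each PSSM row is a shared baseline column profile plus a
#' class shift of magnitude `(1 - signal_split[c]) * pssm_profile_shift`
#' plus Gaussian noise (`pssm_noise_sd`), rounded and clipped to the
#' typical log-odds range [-16, 13].
#'
#' @param n_classes Number of location classes (>= 2).
#' @param per_class Proteins per class (>= 3).
#' @param length_range Integer (min, max) sequence lengths; min must be at
#'   least 12 so every record satisfies both encoders' preconditions at
#'   the default lambda = 10.
#' @param composition_concentration Sharpness of the class composition
#'   profiles (default 1).
#' @param pssm_profile_shift Magnitude of the class-specific PSSM column
#'   shift (default 3, on the log-odds scale).
#' @param pssm_noise_sd Gaussian noise SD on PSSM entries (default 1).
#' @param signal_split Numeric vector of n_classes values in [0, 1]
#'   (default all 0.5: signal split evenly between blocks).
#' @param seed Integer seed; the dataset is fully determined by it.
#' @return A `subnuc_dataset` (see [load_dataset()]).
#' @export
generate_synthetic <- function(n_classes = 3L, per_class = 15L,
                               length_range = c(30L, 60L),
                               composition_concentration = 1,
                               pssm_profile_shift = 3,
                               pssm_noise_sd = 1,
                               signal_split = rep(0.5, n_classes),
                               seed = 1L) {
  stopifnot(n_classes >= 2L, per_class >= 3L,
            length_range[1] >= 12L, length_range[2] >= length_range[1],
            length(signal_split) == n_classes,
            all(signal_split >= 0), all(signal_split <= 1))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  aa <- residue_alphabet()
  # class composition profiles: softmax-perturbed uniform
  profiles <- lapply(seq_len(n_classes), function(c) {
    z <- stats::rnorm(20L)
    w <- exp(signal_split[c] * composition_concentration * z)
    w / sum(w)
  })
  # PSSM column structure: one shared baseline, one shift direction per
  # class scaled by the complementary share of the signal
  base_profile <- round(stats::rnorm(20L, 0, 2))
  shift_dirs <- lapply(seq_len(n_classes), function(c) {
    stats::rnorm(20L) * (1 - signal_split[c]) * pssm_profile_shift
  })
  ids <- character(0)
  seqs <- character(0)
  labels <- character(0)
  pssms <- list()
  for (c in seq_len(n_classes)) {
    for (j in seq_len(per_class)) {
      id <- sprintf("C%d_%03d", c, j)
      L <- sample(length_range[1]:length_range[2], 1L)
      s <- paste(sample(aa, L, replace = TRUE, prob = profiles[[c]]),
                 collapse = "")
      m <- matrix(rep(base_profile + shift_dirs[[c]], each = L), L, 20L) +
        matrix(stats::rnorm(L * 20L, 0, pssm_noise_sd), L, 20L)
      m <- pmin(pmax(round(m), -16), 13)
      colnames(m) <- aa
      ids <- c(ids, id)
      seqs <- c(seqs, s)
      labels <- c(labels, sprintf("loc%d", c))
      pssms[[id]] <- structure(m, class = c("pssm_matrix", class(m)),
                               id = id, provenance = "synthetic")
    }
  }
  records <- data.frame(id = ids, sequence = seqs, length = nchar(seqs),
                        stringsAsFactors = FALSE)
  build_dataset(records, pssms, stats::setNames(labels, ids))
}

#' Write a dataset to disk as a loadable fixture
#'
#' Lays out a FASTA file, one tsv-matrix PSSM per protein and a label TSV
#' exactly as [load_dataset()] expects; the round trip is lossless.
#'
#' @param dataset A `subnuc_dataset`.
#' @param dir Output directory (created if absent; must be empty unless
#'   `overwrite = TRUE`).
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, a list of the paths written (`fasta`, `pssm_dir`,
#'   `labels`).
#' @export
write_fixture <- function(dataset, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0L && !overwrite) {
    stop("directory ", dir, " is not empty (use overwrite = TRUE)")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "sequences.fasta")
  writeLines(paste0(">", dataset$records$id, "\n",
                    dataset$records$sequence), fasta)
  pssm_dir <- file.path(dir, "pssm")
  dir.create(pssm_dir, showWarnings = FALSE)
  for (id in names(dataset$pssms)) {
    write_pssm_tsv(dataset$pssms[[id]], file.path(pssm_dir,
                                                  paste0(id, ".tsv")))
  }
  labels <- file.path(dir, "labels.tsv")
  utils::write.table(
    data.frame(id = dataset$records$id,
               label = dataset$label_levels[dataset$labels]),
    labels, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(list(fasta = fasta, pssm_dir = pssm_dir, labels = labels))
}
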