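#' Dipeptide composition (DipC) encoding
#'
#' Encodes one protein sequence as a 420-dimensional vector: positions 1-20
#' hold the residue frequencies `aa_i / L` in canonical alphabetical order,
#' and positions 21-420 the frequencies `cr_i / (L - 1)` of the 400 ordered
#' residue pairs. The dipeptide (a, b) sits at position
#' `20 + 20 * (index(a) - 1) + index(b)` (row-major over ordered pairs).
#' Both blocks each sum to 1.
#'
#' @param sequence A character string over the canonical alphabet, or a
#'   one-row record as returned by [read_fasta()].
#' @return Named numeric vector of length 420.
#' @examples
#' v <- encode_dipc("ACDE")
#' sum(v[1:20]); sum(v[21:420])  # both 1
#' @export
encode_dipc <- function(sequence) {
  sequence <- as_sequence(sequence)
  idx <- residue_indices(sequence)
  if (anyNA(idx)) {
    stop("sequence holds non-standard residue at position ",
         which(is.na(idx))[1])
  }
  L <- length(idx)
  if (L < 2L) {
    stop("DipC needs L >= 2 residues (the dipeptide denominator is L - 1); got L = ", L)
  }
  comp <- tabulate(idx, nbins = 20L) / L
  dip <- tabulate(20L * (idx[-L] - 1L) + idx[-1L], nbins = 400L) / (L - 1L)
  aa <- residue_alphabet()
  stats::setNames(c(comp, dip),
                  c(aa, paste0(rep(aa, each = 20L), rep(aa, 20L))))
}

#' Pseudo-amino acid composition (PseAAC) encoding
#'
#' Encodes one sequence as a `20 + 2 * lambda` vector of the amphiphilic
#' pseudo-amino-acid form: 20 composition-derived components followed by
#' `lambda` tiers of sequence-order correlation factors, hydrophobicity and
#' hydrophilicity interleaved per tier. With standardized scales `h1`, `h2`
#' the tier-k factors are
#' `tau_{2k-1} = mean_i h1(res_i) h1(res_{i+k})` and `tau_{2k}` likewise
#' with `h2`; the final vector is
#' `p_u = f_u / (sum f + w * sum tau)` for `u <= 20` and
#' `p_{20+j} = w * tau_j / (sum f + w * sum tau)`, so all components sum
#' to 1.
#'
#' @param sequence Character string or one-row record.
#' @param lambda Rank of sequence-order correlation (default 10, giving a
#'   40D vector). Requires `L >= lambda + 1`.
#' @param w Weight of the correlation terms (default 0.05).
#' @param scales List with standardized `hydrophobicity` and
#'   `hydrophilicity` vectors; defaults to
#'   `pseaac_scales(standardize = TRUE)`.
#' @return Named numeric vector of length `20 + 2 * lambda`.
#' @export
encode_pseaac <- function(sequence, lambda = 10L, w = 0.05,
                          scales = pseaac_scales(standardize = TRUE)) {
  sequence <- as_sequence(sequence)
  stopifnot(lambda >= 1L, w > 0)
  idx <- residue_indices(sequence)
  if (anyNA(idx)) {
    stop("sequence holds non-standard residue at position ",
         which(is.na(idx))[1])
  }
  L <- length(idx)
  if (L <= lambda) {
    stop("PseAAC with lambda = ", lambda, " needs L >= lambda + 1; got L = ", L)
  }
  h1 <- unname(scales$hydrophobicity)[idx]
  h2 <- unname(scales$hydrophilicity)[idx]
  tau <- numeric(2L * lambda)
  for (k in seq_len(lambda)) {
    i <- seq_len(L - k)
    tau[2L * k - 1L] <- mean(h1[i] * h1[i + k])
    tau[2L * k] <- mean(h2[i] * h2[i + k])
  }
  f <- tabulate(idx, nbins = 20L) / L
  denom <- sum(f) + w * sum(tau)
  vals <- c(f, w * tau) / denom
  stats::setNames(vals, c(residue_alphabet(),
                          paste0(rep(c("tau.h1.", "tau.h2."), lambda),
                                 rep(seq_len(lambda), each = 2L))))
}

#' Compress a PSSM to a length-free 210D descriptor
#'
#' Forms `M = t(P) %*% P` from an L x 20 score matrix `P` — a symmetric
#' 20 x 20 (400-entry) matrix independent of sequence length — and keeps
#' its 210 non-redundant entries: the lower triangle including the
#' diagonal, read row by row, so element `(i, j)` with `i >= j` sits at
#' position `i * (i - 1) / 2 + j`.
#'
#' @param pssm Numeric L x 20 matrix (canonical column order), e.g. from
#'   [read_pssm()].
#' @return Numeric vector of length 210.
#' @export
compress_pssm <- function(pssm) {
  stopifnot(is.matrix(pssm), ncol(pssm) == 20L, nrow(pssm) >= 1L)
  m <- crossprod(pssm)
  # column-major upper triangle of a symmetric matrix == row-major lower
  # triangle
  v <- m[upper.tri(m, diag = TRUE)]
  ij <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  stats::setNames(v, paste0("M.", ij[, 2L], ".", ij[, 1L]))
}

#' Reconstruct the 20 x 20 matrix behind a compressed PSSM vector
#'
#' Inverse of the triangle flattening in [compress_pssm()].
#'
#' @param values Numeric vector of length 210.
#' @return Symmetric 20 x 20 matrix.
#' @export
expand_pssm_gram <- function(values) {
  stopifnot(length(values) == 210L)
  m <- matrix(0, 20L, 20L)
  m[upper.tri(m, diag = TRUE)] <- values
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Encode every protein in a dataset
#'
#' Applies one of the three single-representation encoders to all records
#' of a dataset, collecting failures (e.g. sequences too short for the
#' encoder) into a single aggregate error (strict) or an exclusion message
#' (lenient).
#'
#' @param dataset A `subnuc_dataset` from [load_dataset()] or
#'   [generate_synthetic()].
#' @param which `"dipc"`, `"pseaac"` or `"pssm"`.
#' @param strict Abort on any failing record (default) instead of dropping
#'   it.
#' @param ... Passed to the underlying encoder (`lambda`, `w`, `scales`).
#' @return Numeric matrix, one row per id (rownames are ids).
#' @export
encode_all <- function(dataset, which = c("dipc", "pseaac", "pssm"),
                       strict = TRUE, ...) {
  which <- match.arg(which)
  ids <- dataset$records$id
  enc <- switch(which,
    dipc = function(id) encode_dipc(
      dataset$records$sequence[dataset$records$id == id], ...),
    pseaac = function(id) encode_pseaac(
      dataset$records$sequence[dataset$records$id == id], ...),
    pssm = function(id) {
      if (is.null(dataset$pssms[[id]])) stop("no PSSM for id")
      compress_pssm(dataset$pssms[[id]])
    })
  out <- vector("list", length(ids))
  errs <- character()
  for (i in seq_along(ids)) {
    v <- tryCatch(enc(ids[i]), error = function(e) e)
    if (inherits(v, "error")) {
      errs <- c(errs, paste0(ids[i], " (", conditionMessage(v), ")"))
    } else {
      out[[i]] <- v
    }
  }
  if (length(errs) > 0L) {
    if (strict) {
      stop("encoding '", which, "' failed for ", length(errs),
           " record(s): ", paste(errs, collapse = "; "))
    }
    message("encode_all: excluded ", length(errs), " record(s)")
  }
  keep <- !vapply(out, is.null, logical(1))
  mat <- do.call(rbind, out[keep])
  rownames(mat) <- ids[keep]
  mat
}

#' Write a feature matrix as TSV
#'
#' Writes an ids-by-features table with a one-line comment header naming
#' the representation.
#'
#' @param features Numeric matrix with id rownames.
#' @param path Output path.
#' @param representation Name recorded in the header line.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(features, path, representation = "features") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# subnucfuse %s v%s", representation,
                     as.character(utils::packageVersion("subnucfuse"))), con)
  utils::write.table(data.frame(id = rownames(features), features,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# accept either a bare string or a row of the records data frame
as_sequence <- function(x) {
  if (is.data.frame(x)) x <- x$sequence
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x
}
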