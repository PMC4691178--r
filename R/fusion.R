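#' Fuse two feature blocks with a balance factor
#'
#' Builds the weighted concatenation `V = [r * A, (1 - r) * B]` of a
#' composition-type block `A` (DipC or PseAAC) and a PSSM block `B`. With
#' DipC (420D) and the compressed PSSM (210D) this yields the 630D DipPSSM
#' vector; with PseAAC at lambda = 10 it yields the 250D PseAAPSSM vector.
#' `r = 0.5` is the equal-importance special case.
#'
#' @param A,B Numeric vectors (non-empty).
#' @param r Balance factor, strictly inside (0, 1).
#' @return Numeric vector of length `length(A) + length(B)` with attributes
#'   `block_lengths` and `weight_used`.
#' @export
fuse_one <- function(A, B, r) {
  stopifnot(length(A) >= 1L, length(B) >= 1L)
  check_balance(r)
  structure(c(r * A, (1 - r) * B),
            block_lengths = c(length(A), length(B)),
            weight_used = r)
}

#' Fuse all samples of a dataset with per-class balance factors
#'
#' In `"true-label"` mode each sample is fused with the balance factor of
#' its own class, `V_i = [r_i A_i, (1 - r_i) B_i]` — usable when labels are
#' known, i.e. for training and for balance-factor optimization. In
#' `"candidate-class"` mode each sample yields one fused variant per class,
#' for label-free prediction (see [knn_predict_fused()]).
#'
#' @param blocksA,blocksB Numeric matrices with identical id rownames.
#' @param labels Named integer class codes 1..n (required in true-label
#'   mode).
#' @param R Numeric balance vector, one factor in (0, 1) per class.
#' @param mode `"true-label"` or `"candidate-class"`.
#' @return True-label mode: one fused matrix. Candidate-class mode: a list
#'   of n fused matrices, element c fused with `R[c]`.
#' @export
fuse_dataset <- function(blocksA, blocksB, labels = NULL, R,
                         mode = c("true-label", "candidate-class")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(blocksA), is.matrix(blocksB))
  if (!identical(rownames(blocksA), rownames(blocksB))) {
    stop("blocksA and blocksB must cover the same ids in the same order")
  }
  check_balance(R)
  if (mode == "true-label") {
    if (is.null(labels)) stop("true-label fusion requires labels")
    lab <- labels[rownames(blocksA)]
    if (anyNA(lab)) {
      stop("missing label for id(s): ",
           paste(rownames(blocksA)[is.na(lab)], collapse = ", "))
    }
    if (max(lab) > length(R)) {
      stop("balance vector has ", length(R), " factors but labels use class ",
           max(lab))
    }
    r <- R[lab]
    cbind(blocksA * r, blocksB * (1 - r))
  } else {
    lapply(seq_along(R), function(c) {
      cbind(blocksA * R[c], blocksB * (1 - R[c]))
    })
  }
}

#' Write / read a balance vector as a key-value text file
#'
#' @param R Numeric balance vector.
#' @param path File path.
#' @param provenance One of `"fixed"`, `"greedy-init"`, `"ga-optimized"`.
#' @param seed Optional integer seed recorded for provenance.
#' @return `write_balance()` returns `path` invisibly; `read_balance()`
#'   returns the numeric vector with a `provenance` attribute.
#' @export
write_balance <- function(R, path, provenance = "fixed", seed = NA) {
  check_balance(R)
  lines <- c(sprintf("provenance\t%s", provenance),
             sprintf("seed\t%s", seed),
             sprintf("r%d\t%.17g", seq_along(R), R))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_balance
#' @export
read_balance <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character")
  rrows <- grepl("^r[0-9]+$", tab[[1]])
  R <- as.numeric(tab[[2]][rrows])[order(as.integer(sub("^r", "", tab[[1]][rrows])))]
  check_balance(R)
  structure(R, provenance = tab[[2]][tab[[1]] == "provenance"][1])
}

check_balance <- function(R) {
  if (!is.numeric(R) || length(R) < 1L || anyNA(R) ||
      any(R <= 0) || any(R >= 1)) {
    stop("balance factors must be numeric and strictly inside (0, 1)")
  }
  invisible(R)
}
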