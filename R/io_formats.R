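#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a data frame of validated sequence records.
#' Residues are checked against the 20-letter canonical alphabet
#' ([residue_alphabet()]); ambiguous or non-standard codes (B, Z, X, U, O,
#' `*`, gaps, ...) either abort the read (`policy = "strict"`, the default)
#' or are removed with a message (`policy = "skip-unknown"`).
#'
#' @param path Path to a FASTA file.
#' @param policy `"strict"` or `"skip-unknown"`.
#' @return A data frame with columns `id`, `sequence`, `length`.
#' @export
read_fasta <- function(path, policy = c("strict", "skip-unknown")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  first <- lines[nzchar(trimws(lines))][1]
  if (is.na(first) || !startsWith(first, ">")) {
    bad <- which(nzchar(trimws(lines)))[1]
    stop("malformed FASTA in ", path, ": line ", bad,
         " holds sequence data before any '>' header")
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  alphabet <- residue_alphabet()
  cleaned <- character(length(seqs))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!(chars %in% alphabet))
    if (length(bad) > 0L) {
      if (policy == "strict") {
        stop("sequence '", ids[i], "' holds non-standard residue '",
             chars[bad[1]], "' at position ", bad[1],
             " (use policy = \"skip-unknown\" to drop such residues)")
      }
      message("read_fasta: dropped ", length(bad),
              " non-standard residue(s) from '", ids[i], "'")
      chars <- chars[-bad]
    }
    if (length(chars) == 0L) {
      stop("sequence '", ids[i], "' is empty after residue filtering")
    }
    cleaned[i] <- paste(chars, collapse = "")
  }
  data.frame(id = ids, sequence = cleaned, length = nchar(cleaned),
             stringsAsFactors = FALSE)
}

#' Read a position-specific scoring matrix
#'
#' Reads one protein's L x 20 PSSM from either the ASCII report written by
#' PSI-BLAST (`dialect = "psiblast-ascii"`; only the 20 log-odds columns are
#' consumed) or a plain header-less TSV of L rows by 20 numbers already in
#' canonical column order (`dialect = "tsv-matrix"`). Whatever the source
#' ordering, the returned matrix has its 20 columns in canonical
#' alphabetical residue order.
#'
#' @param path Path to the PSSM file.
#' @param dialect `"psiblast-ascii"` or `"tsv-matrix"`.
#' @param id Identifier to attach; defaults to the file name without
#'   extension.
#' @return A numeric L x 20 matrix of class `pssm_matrix` with residue
#'   column names and attributes `id` and `provenance`.
#' @export
read_pssm <- function(path, dialect = c("tsv-matrix", "psiblast-ascii"),
                      id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "tsv-matrix") {
    nf <- utils::count.fields(path, sep = "\t")
    bad <- which(nf != 20L)
    if (length(bad) > 0L) {
      stop("tsv-matrix PSSM ", path, ": row ", bad[1], " has ", nf[bad[1]],
           " fields, expected 20")
    }
    m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                     colClasses = "numeric"))
    dimnames(m) <- NULL
  } else {
    m <- parse_psiblast_ascii(path)
  }
  colnames(m) <- residue_alphabet()
  structure(m, class = c("pssm_matrix", class(m)), id = id,
            provenance = dialect)
}

# PSI-BLAST ASCII report: header lines, then one row per position holding
# <pos> <residue> <20 log-odds> <20 weighted percentages> <2 stats>; rows
# are recognized by an integer position followed by a residue letter.
parse_psiblast_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 2L || !grepl("^[0-9]+$", tok[1]) ||
        !grepl("^[A-Za-z]$", tok[2])) {
      next
    }
    num <- suppressWarnings(as.numeric(tok[-(1:2)]))
    num <- num[!is.na(num)]
    if (length(num) < 40L) {
      stop("psiblast-ascii PSSM ", path, ": row at line ", ln, " has ",
           length(num), " numeric fields, expected at least 40")
    }
    rows[[length(rows) + 1L]] <- num[1:20]
  }
  if (length(rows) == 0L) {
    stop("psiblast-ascii PSSM ", path, ": no score rows found")
  }
  m <- do.call(rbind, rows)
  # remap from the PSI-BLAST column order to canonical alphabetical order
  m[, match(residue_alphabet(), PSIBLAST_COLUMN_ORDER), drop = FALSE]
}

#' Write a PSSM in the tsv-matrix dialect
#'
#' Writes the header-less L x 20 tab-separated layout read back by
#' [read_pssm()] with `dialect = "tsv-matrix"`; the round trip is exact for
#' integer scores.
#'
#' @param pssm Numeric L x 20 matrix (canonical column order).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm_tsv <- function(pssm, path) {
  stopifnot(is.matrix(pssm), ncol(pssm) == 20L)
  utils::write.table(pssm, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column label table
#'
#' @param path TSV with two columns: sequence id, location label. No header.
#' @return Named character vector of labels, names are ids.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(tab) != 2L) {
    stop("label table ", path, " has ", ncol(tab), " columns, expected 2")
  }
  if (anyDuplicated(tab[[1]])) {
    stop("duplicate ids in label table: ",
         paste(unique(tab[[1]][duplicated(tab[[1]])]), collapse = ", "))
  }
  stats::setNames(tab[[2]], tab[[1]])
}

#' Assemble a labeled dataset from files
#'
#' Cross-validates FASTA sequences, per-protein PSSMs (one file per id under
#' `pssm_dir`, named `<id>.tsv` or `<id>.pssm`) and a label table into the
#' dataset container used by the encoders and the evaluation pipeline.
#' Location labels are mapped to integer class codes 1..n in sorted label
#' order; the original names are kept in `label_levels`.
#'
#' @param fasta Path to the FASTA file.
#' @param pssm_dir Directory of per-id PSSM files (`NULL` to skip PSSMs).
#' @param labels Path to the two-column label TSV.
#' @param policy Residue policy passed to [read_fasta()].
#' @param dialect PSSM dialect passed to [read_pssm()].
#' @param strict If `TRUE` (default) a labeled id lacking a sequence or a
#'   PSSM is an error; otherwise such ids are dropped with a message.
#' @return A list of class `subnuc_dataset` with elements `records`
#'   (data frame id/sequence/length), `pssms` (named list of matrices),
#'   `labels` (named integer codes 1..n), `label_levels`, `n`,
#'   `class_sizes`.
#' @export
load_dataset <- function(fasta, pssm_dir = NULL, labels,
                         policy = "strict", dialect = "tsv-matrix",
                         strict = TRUE) {
  records <- read_fasta(fasta, policy)
  lab_raw <- read_labels(labels)
  missing_seq <- setdiff(names(lab_raw), records$id)
  if (length(missing_seq) > 0L) {
    if (strict) {
      stop("labeled id(s) missing a sequence: ",
           paste(missing_seq, collapse = ", "))
    }
    message("load_dataset: dropping ", length(missing_seq),
            " labeled id(s) without a sequence")
    lab_raw <- lab_raw[setdiff(names(lab_raw), missing_seq)]
  }
  pssms <- NULL
  if (!is.null(pssm_dir)) {
    pssms <- list()
    missing_pssm <- character()
    for (id in names(lab_raw)) {
      cand <- file.path(pssm_dir, paste0(id, c(".tsv", ".pssm", ".txt")))
      hit <- cand[file.exists(cand)][1]
      if (is.na(hit)) {
        missing_pssm <- c(missing_pssm, id)
      } else {
        pssms[[id]] <- read_pssm(hit, dialect, id = id)
      }
    }
    if (length(missing_pssm) > 0L) {
      if (strict) {
        stop("labeled id(s) missing a PSSM: ",
             paste(missing_pssm, collapse = ", "))
      }
      message("load_dataset: dropping ", length(missing_pssm),
              " labeled id(s) without a PSSM")
      lab_raw <- lab_raw[setdiff(names(lab_raw), missing_pssm)]
    }
    for (id in names(lab_raw)) {
      L <- records$length[records$id == id]
      if (nrow(pssms[[id]]) != L) {
        stop("PSSM for '", id, "' has ", nrow(pssms[[id]]),
             " rows but the sequence has ", L, " residues")
      }
    }
  }
  records <- records[records$id %in% names(lab_raw), , drop = FALSE]
  build_dataset(records, pssms, lab_raw)
}

# shared constructor for load_dataset and the synthetic generator
build_dataset <- function(records, pssms, labels_chr) {
  levels <- sort(unique(unname(labels_chr)))
  if (length(levels) < 2L) {
    stop("dataset needs at least 2 location classes, found ",
         length(levels))
  }
  codes <- stats::setNames(match(unname(labels_chr), levels),
                           names(labels_chr))
  cs <- table(factor(codes, levels = seq_along(levels)))
  if (any(cs == 0L)) stop("every class must have at least one member")
  records <- records[match(names(codes), records$id), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records,
                 pssms = if (is.null(pssms)) NULL else pssms[names(codes)],
                 labels = codes,
                 label_levels = levels,
                 n = length(levels),
                 class_sizes = as.integer(cs)),
            class = "subnuc_dataset")
}

#' @export
print.subnuc_dataset <- function(x, ...) {
  cat("subnuc_dataset:", nrow(x$records), "proteins,", x$n,
      "sub-nuclear locations\n")
  cat("  class sizes:",
      paste(sprintf("%s=%d", x$label_levels, x$class_sizes),
            collapse = ", "), "\n")
  cat("  PSSMs:", if (is.null(x$pssms)) "absent" else "present", "\n")
  invisible(x)
}
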