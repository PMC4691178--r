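# shared fixture builders; everything is generated in code at test time

random_sequence <- function(L) {
  paste(sample(residue_alphabet(), L, replace = TRUE), collapse = "")
}

random_pssm <- function(L) {
  matrix(sample(-16:13, L * 20L, replace = TRUE), L, 20L)
}

# tiny on-disk fixture with two classes and known content
write_tiny_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(">p1", "ACDEFGHIKLMNPQRSTVWY",
               ">p2", "AAAACCCCDDDDEEEEFFFF",
               ">p3", "WYWYWYWYWYWYWYWYWYWY",
               ">p4", "LLLLMMMMNNNNPPPPQQQQ"),
             file.path(dir, "seqs.fasta"))
  pd <- file.path(dir, "pssm")
  dir.create(pd, showWarnings = FALSE)
  for (id in c("p1", "p2", "p3", "p4")) {
    write_pssm_tsv(matrix(1L, 20L, 20L), file.path(pd, paste0(id, ".tsv")))
  }
  writeLines(c("p1\tnucleolus", "p2\tnucleolus",
               "p3\tchromatin", "p4\tchromatin"),
             file.path(dir, "labels.tsv"))
  list(fasta = file.path(dir, "seqs.fasta"), pssm_dir = pd,
       labels = file.path(dir, "labels.tsv"))
}

# independent brute-force cosine KNN used as an oracle (no shared code
# with the package's vectorized ranking)
oracle_knn <- function(train_X, train_y, Q, k) {
  cosv <- function(u, v) sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  apply(Q, 1L, function(q) {
    s <- apply(train_X, 1L, cosv, u = q)
    ord <- order(-s, seq_along(s))
    nb <- ord[seq_len(k)]
    cnt <- table(train_y[nb])
    best <- names(cnt)[cnt == max(cnt)]
    if (length(best) > 1L) {
      sums <- sapply(best, function(cl) sum(s[nb][train_y[nb] == as.integer(cl)]))
      best <- best[sums == max(sums)]
    }
    min(as.integer(best))
  })
}
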