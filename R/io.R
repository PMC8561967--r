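#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read paired FASTQ files into a read-pair data.table
#'
#' @param path1,path2 mate-1 and mate-2 FASTQ files.
#' @return `data.table` with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  ## Biostrings warns that FASTQ metadata columns are dropped; ids and
  ## qualities are all this container carries, so the warning is moot
  r1 <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path1),
    warning = function(w) if (grepl("metadata columns", conditionMessage(w)))
      invokeRestart("muffleWarning"))
  r2 <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path2),
    warning = function(w) if (grepl("metadata columns", conditionMessage(w)))
      invokeRestart("muffleWarning"))
  stopifnot(length(r1) == length(r2))
  data.table(
    id = sub("\\s.*$", "", sub("/[12]$", "", names(r1))),
    seq1 = as.character(r1), qual1 = as.character(Biostrings::quality(r1)),
    seq2 = as.character(r2), qual2 = as.character(Biostrings::quality(r2))
  )
}

#' Write a read-pair table as two FASTQ files
#'
#' @param pairs a read-pair `data.table` (columns `id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`).
#' @param path1,path2 output FASTQ files for mate 1 and mate 2.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  for (mate in 1:2) {
    s <- Biostrings::DNAStringSet(pairs[[paste0("seq", mate)]])
    q <- Biostrings::BStringSet(pairs[[paste0("qual", mate)]])
    names(s) <- paste0(pairs$id, "/", mate)
    Biostrings::writeXStringSet(
      s, c(path1, path2)[mate], format = "fastq", qualities = q)
  }
  invisible(c(path1, path2))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  as.data.table(read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE))
}
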