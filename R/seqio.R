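#' Read sequences from FASTA or FASTQ
#'
#' Sequences are uppercased and restricted to the A/C/G/T/N alphabet; record
#' order is preserved.
#'
#' @param path file path.
#' @param format `"fasta"` or `"fastq"` (default guessed from the extension).
#' @return a data.frame with columns `id`, `sequence` and, for FASTQ,
#'   `quality`.
#' @export
read_sequences <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  format <- match.arg(format, c("fasta", "fastq"))
  set <- if (format == "fasta") {
    Biostrings::readBStringSet(path)
  } else {
    Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("malformed record at index ", which(bad)[1],
         ": non-ACGTN characters after uppercasing")
  }
  out <- data.frame(id = names(set), sequence = unname(seqs),
                    stringsAsFactors = FALSE)
  if (format == "fastq") {
    q <- S4Vectors::mcols(set)$qualities
    out$quality <- unname(as.character(q))
  }
  out
}

#' Write sequences as FASTA or FASTQ
#'
#' @param records data.frame with columns `id`, `sequence` (and `quality` for
#'   FASTQ; a dummy quality of `"I"` per base is used when absent).
#' @param path output file path.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    if (format == "fasta") {
      writeLines(c(paste0(">", records$id[i]), records$sequence[i]), con)
    } else {
      q <- if ("quality" %in% names(records) && !is.na(records$quality[i])) {
        records$quality[i]
      } else strrep("I", nchar(records$sequence[i]))
      writeLines(c(paste0("@", records$id[i]), records$sequence[i], "+", q), con)
    }
  }
  invisible(path)
}

#' Serialize a rooted tree to Newick
#'
#' @param tree an [ape::phylo] object, rooted, with unique leaf labels.
#' @return a Newick string with branch lengths and terminal semicolon.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ape::write.tree(tree)
}

#' Read and write the package's tabular format
#'
#' Tab-separated values with a header row and `.` for missing values: the
#' single tabular dialect used for all stage outputs.
#'
#' @param x a data.frame.
#' @param path file path.
#' @return `read_tsv()` returns a data.frame; `write_tsv()` returns `path`
#'   invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, na.strings = ".",
             stringsAsFactors = FALSE, check.names = FALSE)
}
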