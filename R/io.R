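## Standard-format input/output.  Sequences go through Biostrings; GFF3 is
## written/read directly (nine-column TSV, 1-based inclusive coordinates per
## the standard; internal coordinates everywhere else are 0-based half-open).

#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write reads as four-line Phred+33 FASTQ
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  out <- character(4L * length(reads))
  out[seq(1, length(out), 4)] <- paste0("@", ids)
  out[seq(2, length(out), 4)] <- unname(reads)
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- strrep(qual_char, stri_length(reads))
  writeLines(out, path)
  invisible(path)
}

#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

gff3_escape <- function(x) gsub(";", "%3B", gsub("=", "%3D", x))

#' Write an IES catalog (or gene annotation) as GFF3
#'
#' IES features use the custom type `internal_eliminated_sequence`, carry
#' their excised length and comma-separated floating offsets as attributes,
#' and are anchored at the retained TA (converted to 1-based inclusive).
#'
#' @param catalog data.frame as produced by [build_genome_pair()]
#' @param path output file
#' @export
write_ies_gff3 <- function(catalog, path) {
  att <- sprintf("ID=%s;length=%d;floating_offsets=%s",
                 gff3_escape(catalog$id), catalog$length,
                 vapply(catalog$floating_offsets %||%
                          as.list(rep(0L, nrow(catalog))),
                        function(o) paste(o, collapse = ","), character(1)))
  lines <- sprintf("%s\tiesevo\tinternal_eliminated_sequence\t%d\t%d\t.\t+\t.\t%s",
                   catalog$scaffold, catalog$mac_position + 1L,
                   catalog$mac_position + 2L, att)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' @export
read_ies_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  f <- stri_split_fixed(ln, "\t", simplify = TRUE)
  att <- f[, 9]
  get <- function(key) {
    m <- regmatches(att, regexpr(paste0(key, "=[^;]*"), att))
    sub(paste0(key, "="), "", m)
  }
  data.frame(id = get("ID"), scaffold = f[, 1],
             mac_position = as.integer(f[, 4]) - 1L,
             length = as.integer(get("length")),
             floating = get("floating_offsets"),
             stringsAsFactors = FALSE)
}

#' Write a TSV with provenance comment header
#' @export
write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(sprintf("# %s: %s", names(meta), unlist(meta)), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a k-mer histogram TSV (multiplicity, count)
#' @export
read_histogram <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#")
  kmer_histogram(setNames(df[[2]], df[[1]]))
}
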