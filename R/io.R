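#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet}: gzip-transparent,
#' tolerant of line wrapping, lowercase bases uppercased, FASTQ qualities
#' ignored. Format "auto" sniffs the first non-empty character ('>' FASTA,
#' '@' FASTQ). For FASTQ a validation pass checks the 4-line record geometry
#' and that every quality string matches its sequence length, naming the
#' offending record on failure.
#'
#' @param path input file (optionally .gz).
#' @param format "fasta", "fastq" or "auto".
#' @return a \code{DNAStringSet}.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    con <- gzfile(path, "rt")
    first <- readLines(con, n = 1)
    close(con)
    if (!length(first)) stop("empty file: ", path)
    format <- if (startsWith(first, ">")) "fasta"
    else if (startsWith(first, "@")) "fastq"
    else stop("cannot detect format of ", path,
              " (first character neither '>' nor '@')")
  }
  if (format == "fastq") validate_fastq(path)
  x <- Biostrings::readDNAStringSet(path, format = format)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

# Biostrings' FASTQ parser does not detect a quality/sequence length
# mismatch, so check the 4-line record geometry directly.
validate_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ (", path, "): line count not a multiple of 4")
  n <- length(lines) / 4
  heads <- lines[seq(1, by = 4, length.out = n)]
  seps <- lines[seq(3, by = 4, length.out = n)]
  seqs <- lines[seq(2, by = 4, length.out = n)]
  quals <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], " in ", path)
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("FASTQ record ", bad[1], " in ", path,
         ": quality length ", nchar(quals[bad[1]]),
         " != sequence length ", nchar(seqs[bad[1]]))
  invisible(TRUE)
}

#' Write sequences as FASTA or FASTQ
#'
#' FASTQ output carries a constant placeholder quality ('I').
#'
#' @param seqs a \code{DNAStringSet} (or coercible); names become record ids.
#' @param path output file; a ".gz" suffix triggers gzip compression.
#' @param format "fasta" or "fastq".
#' @return invisibly, \code{path}.
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- as_dna(seqs)
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  compress <- grepl("\\.gz$", path)
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path, format = "fasta", compress = compress)
  } else {
    q <- Biostrings::BStringSet(vapply(Biostrings::width(x), function(w)
      strrep("I", w), character(1)))
    Biostrings::writeXStringSet(x, path, format = "fastq", compress = compress,
                                qualities = q)
  }
  invisible(path)
}

#' Read a reference genome panel
#'
#' Either a directory of FASTA files (one genome per file, file stem as the
#' genome id) or a single multi-FASTA plus a TSV mapping record id to genome
#' id (columns \code{record}, \code{genome}).
#'
#' @param path FASTA file or directory of FASTA files.
#' @param mapping optional record-to-genome TSV (required when \code{path}
#'   is a multi-FASTA holding several genomes).
#' @return named list: genome id -> \code{DNAStringSet} of its records.
#' @export
read_genomes <- function(path, mapping = NULL) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(fa|fasta|fna)(\\.gz)?$",
                        full.names = TRUE)
    if (!length(files)) stop("no FASTA files in ", path)
    out <- lapply(files, read_sequences, format = "fasta")
    names(out) <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(files))
    return(out)
  }
  x <- read_sequences(path, format = "fasta")
  if (is.null(mapping)) return(setNames(lapply(seq_along(x), function(i)
    x[i]), names(x)))
  map <- utils::read.table(mapping, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("record", "genome") %in% names(map)))
    stop("mapping TSV needs columns 'record' and 'genome'")
  missing <- setdiff(names(x), map$record)
  if (length(missing))
    stop("records without genome mapping: ",
         paste(utils::head(missing, 5), collapse = ", "))
  split_ids <- split(map$record, map$genome)
  lapply(split_ids, function(ids) x[ids])
}

#' Write a run manifest
#'
#' Flat key = value text file recording the parameters and outputs of a run.
#'
#' @param params named list of scalar values.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_manifest <- function(params, path) {
  lines <- vapply(names(params), function(k)
    paste0(k, " = ", paste(format(params[[k]]), collapse = ",")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a pipeline parameter combination
#'
#' Enforces the parameter constraints under which the statistics are
#' defined: k >= 2, C >= 1, and background order <= k - 2 (at larger orders
#' the Markov expectation degenerates toward the observed counts).
#'
#' @param k tuple size.
#' @param background_order background Markov order.
#' @param C number of bins.
#' @return invisibly TRUE; stops with an informative message otherwise.
#' @export
validate_config <- function(k, background_order, C = 1) {
  if (k < 2 || k != round(k)) stop("k must be an integer >= 2")
  if (C < 1 || C != round(C)) stop("C must be an integer >= 1")
  if (background_order < 0) stop("background order must be >= 0")
  if (background_order > k - 2)
    stop("background order must be <= k - 2 (got order ", background_order,
         ", k ", k, "): the Markov expectation is undefined beyond that")
  invisible(TRUE)
}
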