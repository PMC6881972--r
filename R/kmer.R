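#' @importFrom methods is
#' @importFrom stats cmdscale cor rbinom rnorm runif setNames
#' @importFrom utils combn
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Coerce sequences to a DNAStringSet
#'
#' Accepts a character vector, a \code{DNAStringSet}, or a list of either, and
#' returns an uppercased \code{DNAStringSet}. Lowercase bases are normalised;
#' characters outside \code{A,C,G,T,N} are rejected by Biostrings.
#'
#' @param seqs sequences in any of the accepted forms.
#' @return a \code{Biostrings::DNAStringSet}.
#' @keywords internal
as_dna <- function(seqs) {
  if (is(seqs, "DNAStringSet")) return(seqs)
  if (is(seqs, "DNAString")) return(Biostrings::DNAStringSet(seqs))
  if (is.list(seqs)) seqs <- unlist(lapply(seqs, as.character))
  if (!is.character(seqs)) stop("sequences must be character or DNAStringSet")
  Biostrings::DNAStringSet(toupper(seqs))
}

#' All k-tuples in lexicographic order
#'
#' Enumerates the 4^k DNA k-tuples over {A,C,G,T} in lexicographic order with
#' A < C < G < T, the fixed indexing used for every count and probability
#' vector in the package.
#'
#' @param k tuple length (>= 1).
#' @return character vector of length 4^k.
#' @examples
#' all_ktuples(1)
#' @export
all_ktuples <- function(k) {
  stopifnot(k >= 1)
  Biostrings::mkAllStrings(DNA_BASES, k)
}

#' Count k-tuples over a read or genome set
#'
#' Counts every length-k window over {A,C,G,T} in the given sequences, summed
#' across sequences. Windows containing N are skipped. With
#' \code{use_complement = TRUE} (the default, and the convention used for all
#' d2S/d2* statistics) each sequence's reverse complement is counted as well,
#' so the count of any tuple equals the count of its reverse complement.
#'
#' @param seqs sequences (character vector or \code{DNAStringSet}).
#' @param k tuple length, >= 1.
#' @param use_complement count each sequence's reverse complement too.
#' @return an object of class \code{ktuple_counts}: list with \code{k},
#'   \code{counts} (named numeric vector of length 4^k, lexicographic order)
#'   and \code{n} (total count).
#' @examples
#' count_ktuples("AAAA", k = 2)
#' @export
count_ktuples <- function(seqs, k, use_complement = TRUE) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    stop("k must be a single integer >= 1")
  x <- as_dna(seqs)
  if (length(x) == 0) {
    counts <- setNames(numeric(4^k), all_ktuples(k))
    return(structure(list(k = as.integer(k), counts = counts, n = 0),
                     class = "ktuple_counts"))
  }
  counts <- as.numeric(Biostrings::oligonucleotideFrequency(
    x, width = k, simplify.as = "collapsed"))
  if (use_complement) {
    counts <- counts + as.numeric(Biostrings::oligonucleotideFrequency(
      Biostrings::reverseComplement(x), width = k, simplify.as = "collapsed"))
  }
  names(counts) <- all_ktuples(k)
  structure(list(k = as.integer(k), counts = counts, n = sum(counts)),
            class = "ktuple_counts")
}

#' @export
print.ktuple_counts <- function(x, ...) {
  cat("k-tuple counts: k =", x$k, ", total n =", format(x$n, big.mark = ","),
      "\n")
  nz <- sum(x$counts > 0)
  cat(" ", nz, "of", length(x$counts), "tuples observed\n")
  invisible(x)
}

# Sum several ktuple_counts objects (same k) into one.
combine_ktuple_counts <- function(lst) {
  ks <- vapply(lst, function(z) z$k, integer(1))
  stopifnot(length(unique(ks)) == 1)
  counts <- Reduce(`+`, lapply(lst, function(z) z$counts))
  structure(list(k = lst[[1]]$k, counts = counts, n = sum(counts)),
            class = "ktuple_counts")
}
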