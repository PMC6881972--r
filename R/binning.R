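#' GC content of a sequence set
#'
#' Fraction (G + C) / (A + C + G + T); N and other ambiguity codes are
#' excluded from both numerator and denominator. For a multi-record genome
#' the fraction is computed over all records pooled.
#'
#' @param seq sequence(s): character vector or \code{DNAStringSet}; multiple
#'   records are pooled into one fraction.
#' @return GC fraction in [0, 1].
#' @examples
#' gc_content("ATGC")
#' @export
gc_content <- function(seq) {
  x <- as_dna(seq)
  f <- colSums(Biostrings::letterFrequency(x, letters = DNA_BASES))
  tot <- sum(f)
  if (tot == 0) stop("GC content undefined: no A/C/G/T bases")
  unname((f["G"] + f["C"]) / tot)
}

#' Bin reference genomes by GC quantiles and train per-bin Markov models
#'
#' Genomes are ranked by GC content and split into C consecutive rank groups
#' of equal size (when the count is not divisible by C, the lowest-GC bins
#' take one extra genome each), so every bin holds the same number of genomes
#' up to the remainder. One Markov model of the given order is trained from
#' all sequences of each bin (reverse complements included). Ties in GC are
#' broken by genome id order. C = 1 degenerates to the classic un-binned
#' background model.
#'
#' @param genomes named list mapping genome id to its sequence set (character
#'   vector or \code{DNAStringSet}; multi-record genomes allowed).
#' @param C number of bins, 1 <= C <= number of genomes.
#' @param order Markov order of the per-bin classification models.
#' @param pseudocount smoothing for the bin models; the default 0.5 keeps read
#'   log-likelihoods finite on transitions unseen in a bin.
#' @return an object of class \code{genome_bins}: list with \code{C},
#'   \code{order}, \code{models} (list of \code{markov_model}),
#'   \code{assignment} (named integer vector genome id -> bin),
#'   \code{gc} (named GC fractions) and \code{boundaries} (C - 1 GC cut
#'   points, midpoints between adjacent bins).
#' @export
build_genome_bins <- function(genomes, C, order, pseudocount = 0.5) {
  if (is.null(names(genomes)) || anyNA(names(genomes)))
    stop("genomes must be a named list (genome id -> sequences)")
  N <- length(genomes)
  if (C < 1 || C != round(C)) stop("C must be a positive integer")
  if (C > N) stop("more bins (", C, ") than genomes (", N, ")")
  gc <- vapply(genomes, gc_content, numeric(1))
  ord <- base::order(gc, names(genomes))   # ties broken by genome id
  sizes <- rep(N %/% C, C)
  rem <- N %% C
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  bin_of_rank <- rep(seq_len(C), times = sizes)
  assignment <- integer(N)
  assignment[ord] <- bin_of_rank
  names(assignment) <- names(genomes)
  gc_sorted <- gc[ord]
  cuts <- cumsum(sizes)[-C]
  boundaries <- (gc_sorted[cuts] + gc_sorted[pmin(cuts + 1, N)]) / 2
  models <- lapply(seq_len(C), function(ci) {
    seqs <- unlist(lapply(genomes[assignment == ci],
                          function(s) as.character(as_dna(s))),
                   use.names = FALSE)
    train_markov(seqs, order = order, pseudocount = pseudocount)
  })
  structure(list(C = as.integer(C), order = as.integer(order),
                 models = models, assignment = assignment, gc = gc,
                 boundaries = unname(boundaries)),
            class = "genome_bins")
}

#' @export
print.genome_bins <- function(x, ...) {
  cat("GC-quantile genome bins: C =", x$C, ", Markov order", x$order, "\n")
  for (c in seq_len(x$C)) {
    ids <- names(x$assignment)[x$assignment == c]
    cat(sprintf("  bin %d: %d genome(s), GC %.3f-%.3f\n", c, length(ids),
                min(x$gc[ids]), max(x$gc[ids])))
  }
  invisible(x)
}

# Per-read log-likelihood under each bin model: one matrix product per bin
# over the reads' (r+1)-tuple count matrix (forward strand, N windows skip).
# Zero transitions are floored to a large negative value so the argmax is
# unaffected while 0-count terms contribute nothing.
log_likelihood_matrix <- function(reads, models) {
  r <- models[[1]]$order
  counts <- Biostrings::oligonucleotideFrequency(reads, width = r + 1)
  lt <- vapply(models, log_transition_vector, numeric(4^(r + 1)),
               floor_zero = -1e12)
  counts %*% lt
}

#' Classify a read into a GC bin by maximum log-likelihood
#'
#' Assigns the read to the bin whose Markov model gives the largest
#' log-likelihood; ties are broken by the lowest bin index.
#'
#' @param read a nucleotide string of length > the bin-model order.
#' @param bins a \code{genome_bins} object.
#' @return the 1-based bin index.
#' @export
classify_read <- function(read, bins) {
  x <- as_dna(read)
  if (Biostrings::width(x)[1] <= bins$order)
    stop("read shorter than order + 1 cannot be classified")
  ll <- log_likelihood_matrix(x, bins$models)
  unname(max.col(ll, ties.method = "first")[1])
}

#' Classify many reads at once
#'
#' Vectorised [classify_read()]. Reads of length <= the model order get NA.
#'
#' @param reads sequences (character vector or \code{DNAStringSet}).
#' @param bins a \code{genome_bins}.
#' @return integer vector of 1-based bin indices (NA for too-short reads).
#' @export
classify_reads <- function(reads, bins) {
  x <- as_dna(reads)
  out <- rep(NA_integer_, length(x))
  ok <- Biostrings::width(x) > bins$order
  if (any(ok))
    out[ok] <- max.col(log_likelihood_matrix(x[ok], bins$models),
                       ties.method = "first")
  out
}

#' Bin a metagenomic sample and accumulate per-bin k-tuple statistics
#'
#' Classifies every read of a sample into the GC bins, then per bin counts
#' the k-tuples (reverse complements included) and estimates an order-r
#' background Markov model. By default the background model of a bin is
#' re-estimated from the reads assigned to that bin of this sample, matching
#' the sample-estimated background of the classic un-binned statistic; set
#' \code{expectation_from = "reference"} to reuse the reference-trained bin
#' models instead. Reads shorter than the classification order + 1 are
#' dropped (the count is recorded). Bins receiving no reads carry zero counts
#' and no background model.
#'
#' @param reads sample reads (character or \code{DNAStringSet}; pool paired
#'   mates before calling — the statistic is strand-symmetric).
#' @param bins a \code{genome_bins}.
#' @param k tuple size for the count vectors.
#' @param background_order Markov order of the per-bin background-expectation
#'   models; must be <= k - 2. Defaults to the bins' classification order.
#' @param background_pseudocount smoothing for the background models
#'   (default 0).
#' @param expectation_from "sample" (default) or "reference".
#' @return an object of class \code{binned_sample}: list with \code{C},
#'   \code{k}, \code{per_bin_counts}, \code{per_bin_models},
#'   \code{n_reads_per_bin}, \code{n_dropped}.
#' @export
bin_sample <- function(reads, bins, k, background_order = NULL,
                       background_pseudocount = 0,
                       expectation_from = c("sample", "reference")) {
  expectation_from <- match.arg(expectation_from)
  if (is.null(background_order)) background_order <- bins$order
  if (background_order > k - 2)
    stop("background order must be <= k - 2 (got order ", background_order,
         ", k ", k, ")")
  x <- as_dna(reads)
  if (length(x) == 0) stop("empty read set")
  lab <- classify_reads(x, bins)
  n_dropped <- sum(is.na(lab))
  if (n_dropped == length(x)) stop("no read long enough to classify")
  if (n_dropped > 0) {
    message(n_dropped, " read(s) shorter than order + 1 dropped")
    x <- x[!is.na(lab)]
    lab <- lab[!is.na(lab)]
  }
  C <- bins$C
  per_bin_counts <- vector("list", C)
  per_bin_models <- vector("list", C)
  n_reads <- integer(C)
  for (c in seq_len(C)) {
    rc <- x[lab == c]
    n_reads[c] <- length(rc)
    per_bin_counts[[c]] <- count_ktuples(rc, k, use_complement = TRUE)
    if (length(rc) > 0) {
      per_bin_models[[c]] <-
        if (expectation_from == "reference") bins$models[[c]]
        else suppressMessages(train_markov(rc, order = background_order,
                                           pseudocount = background_pseudocount))
    }
  }
  structure(list(C = C, k = as.integer(k), per_bin_counts = per_bin_counts,
                 per_bin_models = per_bin_models, n_reads_per_bin = n_reads,
                 n_dropped = n_dropped),
            class = "binned_sample")
}

#' @export
print.binned_sample <- function(x, ...) {
  cat("Binned sample: C =", x$C, ", k =", x$k, "\n")
  cat("  reads per bin:", paste(x$n_reads_per_bin, collapse = ", "), "\n")
  if (x$n_dropped) cat("  dropped (too short):", x$n_dropped, "\n")
  invisible(x)
}

#' Write a genome bin set to a directory
#'
#' Writes one Markov model file per bin plus a TSV of genome-to-bin
#' assignments and GC fractions.
#'
#' @param bins a \code{genome_bins}.
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
write_genome_bins <- function(bins, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (c in seq_len(bins$C))
    write_markov(bins$models[[c]], file.path(dir, sprintf("bin%02d.model", c)))
  df <- data.frame(genome = names(bins$assignment),
                   bin = unname(bins$assignment),
                   gc = unname(bins$gc[names(bins$assignment)]))
  utils::write.table(df, file.path(dir, "assignments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(format(bins$boundaries, digits = 17),
             file.path(dir, "boundaries.txt"))
  invisible(dir)
}

#' Read a genome bin set written by [write_genome_bins()]
#'
#' @param dir directory path.
#' @return a \code{genome_bins} (without the per-genome sequences).
#' @export
read_genome_bins <- function(dir) {
  files <- sort(list.files(dir, pattern = "^bin[0-9]+\\.model$",
                           full.names = TRUE))
  models <- lapply(files, read_markov)
  df <- utils::read.table(file.path(dir, "assignments.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  assignment <- setNames(as.integer(df$bin), df$genome)
  gc <- setNames(df$gc, df$genome)
  boundaries <- as.numeric(readLines(file.path(dir, "boundaries.txt")))
  structure(list(C = length(models), order = models[[1]]$order,
                 models = models, assignment = assignment, gc = gc,
                 boundaries = boundaries),
            class = "genome_bins")
}
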