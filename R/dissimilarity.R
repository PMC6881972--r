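#' Bin-combined centralized k-tuple statistics
#'
#' For each tuple w, subtracts the Markov-expected count from the observed
#' count within every bin and sums over bins:
#' \deqn{\bar X_w = \sum_{c=1}^{C} (X_w^c - n^c p_w^c)}
#' where \eqn{n^c} is the bin's total tuple count and \eqn{p_w^c} the tuple
#' probability under the bin's background model. The total expected count
#' \eqn{\sum_c n^c p_w^c} is retained for the d2* denominator. Empty bins
#' contribute zero. With C = 1 this is the classic single-model centralized
#' count vector.
#'
#' @param sample a \code{binned_sample}.
#' @param k tuple size; must equal the sample's k, with every non-empty bin's
#'   background order <= k - 2.
#' @return an object of class \code{centralized_kmers}: list with \code{k},
#'   \code{xbar} and \code{expected} (numeric vectors of length 4^k).
#' @export
centralize <- function(sample, k = sample$k) {
  if (k != sample$k)
    stop("sample was binned at k = ", sample$k, ", not k = ", k)
  xbar <- numeric(4^k)
  expected <- numeric(4^k)
  for (ci in seq_len(sample$C)) {
    cnt <- sample$per_bin_counts[[ci]]
    if (cnt$n == 0) next
    mod <- sample$per_bin_models[[ci]]
    if (is.null(mod)) stop("non-empty bin ", ci, " has no background model")
    p <- ktuple_probabilities(mod, k)
    e <- cnt$n * as.numeric(p)
    xbar <- xbar + (as.numeric(cnt$counts) - e)
    expected <- expected + e
  }
  structure(list(k = as.integer(k),
                 xbar = setNames(xbar, all_ktuples(k)),
                 expected = setNames(expected, all_ktuples(k))),
            class = "centralized_kmers")
}

#' @export
print.centralized_kmers <- function(x, ...) {
  cat("Centralized k-tuple vector: k =", x$k, "\n")
  cat(sprintf("  total |xbar| = %.4g, total expected = %.4g\n",
              sum(abs(x$xbar)), sum(x$expected)))
  invisible(x)
}

#' d2S dissimilarity between two centralized k-tuple vectors
#'
#' \deqn{D_2^S = \sum_w \bar X_w \bar Y_w / \sqrt{\bar X_w^2 + \bar Y_w^2}}
#' normalised to \eqn{d_2^S = (1 - D_2^S / \sqrt{A_X A_Y}) / 2} with
#' \eqn{A_X = \sum_w \bar X_w^2 / \sqrt{\bar X_w^2 + \bar Y_w^2}} (and
#' symmetrically for Y), which lies in [0, 1] by the Cauchy inequality.
#' Tuples with \eqn{\bar X_w^2 + \bar Y_w^2 = 0} carry no signal and are
#' skipped.
#'
#' @param x,y \code{centralized_kmers} of the same k.
#' @return dissimilarity in [0, 1]; 0 for identical vectors.
#' @export
d2s <- function(x, y) {
  stopifnot(inherits(x, "centralized_kmers"), inherits(y, "centralized_kmers"))
  if (x$k != y$k) stop("tuple sizes differ: ", x$k, " vs ", y$k)
  xb <- as.numeric(x$xbar); yb <- as.numeric(y$xbar)
  denom <- sqrt(xb^2 + yb^2)
  keep <- denom > 0
  if (!any(keep))
    stop("degenerate input: both centralized vectors are identically zero")
  xb <- xb[keep]; yb <- yb[keep]; denom <- denom[keep]
  num <- sum(xb * yb / denom)
  nx <- sqrt(sum(xb^2 / denom))
  ny <- sqrt(sum(yb^2 / denom))
  # the Cauchy bound guarantees [0, 1]; clamp float rounding at the edges
  min(1, max(0, 0.5 * (1 - num / (nx * ny))))
}

#' d2* dissimilarity between two centralized k-tuple vectors
#'
#' \deqn{D_2^* = \sum_w \bar X_w \bar Y_w / \sqrt{E_{X,w} E_{Y,w}}}
#' with \eqn{E_{X,w}} the total Markov-expected count of tuple w in sample X
#' (summed over bins), normalised to
#' \eqn{d_2^* = (1 - D_2^* / \sqrt{\sum_w \bar X_w^2 / E_{X,w}}
#' \sqrt{\sum_w \bar Y_w^2 / E_{Y,w}}) / 2}. Tuples with zero expected count
#' in either sample are skipped (with a warning if they carry a nonzero
#' centralized count).
#'
#' @param x,y \code{centralized_kmers} of the same k.
#' @return dissimilarity in [0, 1]; 0 for identical vectors.
#' @export
d2star <- function(x, y) {
  stopifnot(inherits(x, "centralized_kmers"), inherits(y, "centralized_kmers"))
  if (x$k != y$k) stop("tuple sizes differ: ", x$k, " vs ", y$k)
  xb <- as.numeric(x$xbar); yb <- as.numeric(y$xbar)
  ex <- as.numeric(x$expected); ey <- as.numeric(y$expected)
  keep <- ex > 0 & ey > 0
  if (any(!keep & (xb != 0 | yb != 0)))
    warning(sum(!keep & (xb != 0 | yb != 0)),
            " tuple(s) with zero expectation but nonzero centralized count skipped")
  xb <- xb[keep]; yb <- yb[keep]; ex <- ex[keep]; ey <- ey[keep]
  nx <- sqrt(sum(xb^2 / ex))
  ny <- sqrt(sum(yb^2 / ey))
  if (nx == 0 || ny == 0)
    stop("degenerate input: a centralized vector is identically zero on the supported tuples")
  num <- sum(xb * yb / sqrt(ex * ey))
  min(1, max(0, 0.5 * (1 - num / (nx * ny))))
}

#' Pairwise dissimilarity matrix over binned samples
#'
#' Centralizes every sample once, then evaluates the chosen measure on all
#' unordered pairs.
#'
#' @param samples named list of \code{binned_sample} objects sharing k and
#'   background orders.
#' @param measure "d2s" or "d2star".
#' @param k tuple size (defaults to the samples' k).
#' @return a symmetric zero-diagonal numeric matrix of class \code{d2_dissim}
#'   with sample labels as dimnames.
#' @export
pairwise_dissimilarity <- function(samples, measure = c("d2s", "d2star"),
                                   k = NULL) {
  measure <- match.arg(measure)
  if (length(samples) < 2) stop("need at least 2 samples")
  labels <- names(samples)
  if (is.null(labels)) labels <- paste0("S", seq_along(samples))
  if (is.null(k)) k <- samples[[1]]$k
  cen <- lapply(samples, centralize, k = k)
  fun <- if (measure == "d2s") d2s else d2star
  n <- length(samples)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- tryCatch(fun(cen[[i]], cen[[j]]),
                  error = function(e) stop("pair (", labels[i], ", ",
                                           labels[j], "): ",
                                           conditionMessage(e), call. = FALSE))
    m[i, j] <- v
    m[j, i] <- v
  }
  structure(m, class = c("d2_dissim", "matrix"))
}

#' Write a dissimilarity matrix as labeled TSV (or PHYLIP)
#'
#' @param dm square labeled matrix.
#' @param path output path.
#' @param format "tsv" (header row/column of labels) or "phylip" (square).
#' @return invisibly, \code{path}.
#' @export
write_dissimilarity <- function(dm, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  m <- unclass(dm)
  if (format == "tsv") {
    df <- data.frame(sample = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(m)), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(c(sprintf("%-10s", rownames(m)[i]),
                         format(m[i, ], digits = 10)), collapse = "  "), con)
  }
  invisible(path)
}

#' Read a dissimilarity matrix written as labeled TSV
#'
#' @param path file path.
#' @return labeled numeric matrix of class \code{d2_dissim}.
#' @export
read_dissimilarity <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  structure(m, class = c("d2_dissim", "matrix"))
}
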