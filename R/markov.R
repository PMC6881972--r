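#' Construct a Markov background model
#'
#' Builds an order-r Markov model object from an explicit transition table and
#' initial distribution, validating the probability constraints. Mostly useful
#' for constructing toy models; models are normally estimated from sequence
#' with [train_markov()].
#'
#' @param transitions numeric matrix of size 4^r x 4: rows are the preceding
#'   r-tuples in lexicographic order (a single row for r = 0), columns the
#'   next base A, C, G, T. Every row must sum to 1.
#' @param initial numeric vector of length 4^r over the r-tuples (the scalar 1
#'   for r = 0); must sum to 1.
#' @param order the Markov order r >= 0.
#' @return an object of class \code{markov_model}.
#' @export
markov_model <- function(transitions, initial = NULL, order = NULL) {
  transitions <- as.matrix(transitions)
  if (ncol(transitions) != 4) stop("transitions must have 4 columns")
  if (is.null(order)) order <- as.integer(round(log(nrow(transitions), 4)))
  if (nrow(transitions) != 4^order)
    stop("transitions must have 4^order rows")
  if (is.null(initial)) {
    initial <- if (order == 0) 1 else rep(1 / 4^order, 4^order)
  }
  if (length(initial) != max(1, 4^order))
    stop("initial must have length 4^order")
  if (any(transitions < 0) || any(initial < 0))
    stop("probabilities must be nonnegative")
  if (any(abs(rowSums(transitions) - 1) > 1e-9))
    stop("every transition row must sum to 1")
  if (abs(sum(initial) - 1) > 1e-9)
    stop("initial distribution must sum to 1")
  ctx <- if (order == 0) "" else all_ktuples(order)
  dimnames(transitions) <- list(ctx, DNA_BASES)
  names(initial) <- ctx
  structure(list(order = as.integer(order), transitions = transitions,
                 initial = initial, uniform_contexts = character(0)),
            class = "markov_model")
}

#' Estimate a Markov model from sequences
#'
#' Estimates order-r transition probabilities as smoothed ratios of
#' (r+1)-tuple counts, with counts taken over the sequences and (by default)
#' their reverse complements:
#' \deqn{P(b | u) = (N(ub) + s) / \sum_{b'} (N(ub') + s)}
#' where s is the pseudocount. The initial distribution is the normalised
#' r-tuple count vector. Contexts never observed (all four continuations zero
#' with pseudocount 0) fall back to a uniform row and are recorded in the
#' model's \code{uniform_contexts}.
#'
#' @param seqs sequences (character vector or \code{DNAStringSet}).
#' @param order Markov order r >= 0.
#' @param pseudocount nonnegative smoothing constant added to every
#'   (r+1)-tuple count. Use 0 for background-expectation models; a positive
#'   value (0.5 is the package default for bin-classification models) keeps
#'   log-likelihoods finite on transitions unseen in training.
#' @param use_complement also count each sequence's reverse complement.
#' @return a \code{markov_model}.
#' @examples
#' m <- train_markov("AAAT", order = 1)
#' m$transitions["A", ]
#' @export
train_markov <- function(seqs, order, pseudocount = 0, use_complement = TRUE) {
  if (order < 0 || order != round(order)) stop("order must be an integer >= 0")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  x <- as_dna(seqs)
  if (length(x) == 0 || max(Biostrings::width(x)) <= order)
    stop("training requires at least one sequence longer than the order")
  r <- as.integer(order)
  c1 <- count_ktuples(x, r + 1, use_complement = use_complement)$counts
  tab <- matrix(c1, ncol = 4, byrow = TRUE) + pseudocount
  rs <- rowSums(tab)
  zero <- rs == 0
  trans <- tab / ifelse(rs == 0, 1, rs)
  if (any(zero)) trans[zero, ] <- 0.25
  ctx <- if (r == 0) "" else all_ktuples(r)
  if (any(zero))
    message(sum(zero), " context(s) unobserved; rows set to uniform: ",
            paste(utils::head(ctx[zero], 5), collapse = ", "),
            if (sum(zero) > 5) ", ..." else "")
  if (r == 0) {
    initial <- 1
  } else {
    c0 <- count_ktuples(x, r, use_complement = use_complement)$counts
    initial <- c0 / sum(c0)
  }
  dimnames(trans) <- list(ctx, DNA_BASES)
  names(initial) <- ctx
  structure(list(order = r, transitions = trans, initial = initial,
                 uniform_contexts = ctx[zero]),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("Markov background model, order", x$order, "\n")
  cat("  transitions:", nrow(x$transitions), "context(s) x 4 bases\n")
  if (length(x$uniform_contexts))
    cat("  ", length(x$uniform_contexts), "unobserved context(s) left uniform\n")
  invisible(x)
}

# Map a tuple string to 0-based lexicographic index.
tuple_index <- function(tuple) {
  b <- match(strsplit(tuple, "")[[1]], DNA_BASES) - 1L
  if (anyNA(b)) stop("tuple must be over {A,C,G,T}: ", tuple)
  sum(b * 4^(rev(seq_along(b)) - 1))
}

#' Probability of one k-tuple under a Markov model
#'
#' Returns \eqn{q(w_1..w_r) \prod_i P(w_{i+r} | w_i..w_{i+r-1})}, the
#' probability of the tuple under the model, with q the model's initial
#' r-tuple distribution. The model order must satisfy r <= k - 2; at larger
#' orders the Markov expectation degenerates toward the observed counts and
#' the statistic is undefined.
#'
#' @param model a \code{markov_model}.
#' @param tuple a k-mer string over {A,C,G,T}.
#' @return the tuple probability.
#' @examples
#' m <- markov_model(matrix(0.25, 1, 4), order = 0)
#' ktuple_probability(m, "ACG")
#' @export
ktuple_probability <- function(model, tuple) {
  k <- nchar(tuple)
  r <- model$order
  if (r > k - 2)
    stop("model order must be <= k - 2 (got order ", r, ", k ", k, ")")
  bases <- strsplit(toupper(tuple), "")[[1]]
  if (anyNA(match(bases, DNA_BASES)))
    stop("tuple must be over {A,C,G,T}")
  p <- if (r == 0) 1 else unname(model$initial[paste(bases[1:r], collapse = "")])
  for (i in seq_len(k - r)) {
    ctx <- if (r == 0) 1L else paste(bases[i:(i + r - 1)], collapse = "")
    p <- p * model$transitions[ctx, bases[i + r]]
  }
  unname(p)
}

#' Probabilities of all 4^k k-tuples under a Markov model
#'
#' Vectorised version of [ktuple_probability()]: one dynamic-programming pass
#' extends the initial r-tuple distribution one base at a time, so the full
#' expectation vector is obtained in O(4^k) work.
#'
#' @param model a \code{markov_model}.
#' @param k tuple length; requires model order <= k - 2.
#' @return named numeric vector of length 4^k in lexicographic tuple order.
#' @export
ktuple_probabilities <- function(model, k) {
  r <- model$order
  if (r > k - 2)
    stop("model order must be <= k - 2 (got order ", r, ", k ", k, ")")
  # p over length-m prefixes, m = r..k; lexicographic index of w1..wm+1 is
  # 4 * index(w1..wm) + base(wm+1); context is the last r characters.
  p <- if (r == 0) 1 else as.numeric(model$initial)
  for (m in r:(k - 1)) {
    ctx <- if (r == 0) rep(1L, 4^m) else (seq_len(4^m) - 1L) %% 4^r + 1L
    p <- as.vector(t(p * model$transitions[ctx, , drop = FALSE]))
  }
  setNames(p, all_ktuples(k))
}

# log transition probabilities laid out over (r+1)-tuples in lexicographic
# order; zeros become -Inf (or a finite floor when floor_zero is given).
log_transition_vector <- function(model, floor_zero = NULL) {
  lt <- log(model$transitions)
  if (!is.null(floor_zero)) lt[is.infinite(lt)] <- floor_zero
  as.vector(t(lt))
}

#' Log-likelihood of a sequence under a Markov model
#'
#' Computes \eqn{\sum_{i=1}^{N-r} \log P(y_{i+r} | y_i .. y_{i+r-1})} over the
#' forward strand of the read. Windows containing N are skipped. A transition
#' of probability zero makes the log-likelihood -Inf.
#'
#' @param model a \code{markov_model}.
#' @param seq a single nucleotide string of length > order.
#' @return the log-likelihood (possibly -Inf).
#' @export
log_likelihood <- function(model, seq) {
  x <- as_dna(seq)
  if (length(x) != 1) stop("log_likelihood takes a single sequence")
  r <- model$order
  if (Biostrings::width(x) <= r)
    stop("sequence length must exceed the model order")
  counts <- as.numeric(Biostrings::oligonucleotideFrequency(
    x, width = r + 1, simplify.as = "collapsed"))
  lt <- log_transition_vector(model)
  bad <- is.infinite(lt) & counts > 0
  if (any(bad)) return(-Inf)
  sum(counts[counts > 0] * lt[counts > 0])
}

#' Write a Markov model as a plain-text table
#'
#' Line 1 holds the order r; the next 4^r lines hold the transition rows (four
#' tab-separated probabilities, contexts in lexicographic order); the final
#' line holds the 4^r initial probabilities.
#'
#' @param model a \code{markov_model}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_markov <- function(model, path) {
  fmt <- function(v) paste(format(v, digits = 17, trim = TRUE), collapse = "\t")
  lines <- c(as.character(model$order),
             apply(model$transitions, 1, fmt),
             fmt(as.numeric(model$initial)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Markov model written by [write_markov()]
#'
#' @param path file path.
#' @return a \code{markov_model}.
#' @export
read_markov <- function(path) {
  lines <- readLines(path)
  r <- as.integer(lines[1])
  n <- 4^r
  trans <- do.call(rbind, lapply(lines[1 + seq_len(n)],
                                 function(l) as.numeric(strsplit(l, "\t")[[1]])))
  initial <- as.numeric(strsplit(lines[n + 2], "\t")[[1]])
  markov_model(trans, initial, order = r)
}
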