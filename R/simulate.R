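#' Zipf (power-law) relative abundance vector
#'
#' The genome placed at rank m receives abundance
#' \eqn{m^{-\alpha} / \sum_{n=1}^{N} n^{-\alpha}}; alpha controls evenness
#' (alpha = 0 is uniform, larger alpha concentrates mass on the top ranks).
#' The rank-to-genome mapping is given by a permutation so that independent
#' community centers can share one genome panel.
#'
#' @param alpha decay exponent >= 0.
#' @param N number of genomes.
#' @param ordering permutation of 1:N; \code{ordering[i]} is the genome index
#'   holding rank i. Defaults to the identity.
#' @return numeric abundance vector over genomes, summing to 1.
#' @examples
#' zipf_abundance(1, 2)
#' @export
zipf_abundance <- function(alpha, N, ordering = seq_len(N)) {
  if (N < 1) stop("N must be >= 1")
  if (alpha < 0) stop("alpha must be >= 0")
  if (!identical(sort(as.integer(ordering)), seq_len(as.integer(N))))
    stop("ordering must be a permutation of 1:N")
  ranks <- seq_len(N)
  f <- ranks^(-alpha) / sum(ranks^(-alpha))
  v <- numeric(N)
  v[ordering] <- f
  v
}

#' Perturb an abundance vector with absolute Gaussian noise
#'
#' Adds the absolute value of a zero-mean Gaussian to every component and
#' renormalises. Three noise scales are supported. \code{"sd1"} (the
#' default) draws noise with standard deviation equal to the component — a
#' proportional perturbation under which community structure survives, and
#' the only dimensionally consistent convention for a relative-abundance
#' vector. \code{"variance10sq"} uses variance equal to 10 times the squared
#' component (sd = sqrt(10) v), i.e. ten times the \code{"sd1"} variance.
#' \code{"variance10"} sets variance = 10 v; because components of a
#' relative-abundance vector are of order 1/N, that noise is an order of
#' magnitude larger than the signal and erases any community structure — it
#' is kept for completeness (see the methods vignette).
#'
#' @param v abundance vector (nonnegative, sums to 1).
#' @param model "sd1", "variance10sq" or "variance10".
#' @return perturbed abundance vector summing to 1.
#' @export
perturb_abundance <- function(v, model = c("sd1", "variance10sq",
                                           "variance10")) {
  model <- match.arg(model)
  if (any(v < 0) || abs(sum(v) - 1) > 1e-9)
    stop("v must be a nonnegative vector summing to 1")
  sdv <- switch(model, variance10 = sqrt(10 * v), variance10sq = sqrt(10) * v,
                sd1 = v)
  w <- v + abs(rnorm(length(v), mean = 0, sd = sdv))
  w / sum(w)
}

# Sample one sequence from an order-r Markov chain given cumulative
# transition rows (4^r x 4) and an initial context index.
markov_walk <- function(cumrows, r, len) {
  out <- integer(len)
  u <- runif(len)
  if (r == 0) {
    # cumrows is 1 x 4 cumulative; clamp guards the u ~ 1 float edge
    return(pmin(findInterval(u, c(0, cumrows[1, ])), 4L))
  }
  # seed the first r bases uniformly, then walk
  out[seq_len(r)] <- sample.int(4, r, replace = TRUE)
  ctx <- sum((out[seq_len(r)] - 1) * 4^(rev(seq_len(r)) - 1)) + 1L
  pow <- 4^(r - 1)
  for (i in (r + 1):len) {
    b <- 1L
    x <- u[i]
    row <- cumrows[ctx, ]
    while (b < 4L && x > row[b]) b <- b + 1L
    out[i] <- b
    ctx <- ((ctx - 1L) %% pow) * 4L + b
  }
  out
}

#' Generate a panel of synthetic genomes with controlled GC content
#'
#' Emits N genome sequences from per-genome Markov chains whose GC targets
#' are spread evenly across \code{gc_range}. Each genome's transition rows
#' get small multiplicative log-normal jitter (then are rescaled so the
#' G+C mass of every row stays at the genome's target), making genomes of
#' similar GC still distinguishable by higher-order structure. This panel
#' stands in for a set of real reference genomes; it is synthetic data.
#'
#' @param N number of genomes.
#' @param gc_range GC interval, strictly inside (0, 1), e.g. c(0.3, 0.7).
#' @param length genome length in bp (>= 1000).
#' @param order Markov order of the generating chains (default 1).
#' @param jitter log-normal sd of the per-row transition jitter.
#' @return named list of single-sequence character vectors
#'   (\code{g01 ... gNN}); the generating transition tables are attached as
#'   attribute \code{"generator_models"}.
#' @export
synth_genomes <- function(N, gc_range = c(0.3, 0.7), length = 100000,
                          order = 1, jitter = 0.15) {
  if (length < 1000) stop("genome length must be >= 1000")
  if (gc_range[1] <= 0 || gc_range[2] >= 1 || gc_range[1] >= gc_range[2])
    stop("gc_range must be a nondegenerate interval inside (0, 1)")
  targets <- if (N == 1) mean(gc_range) else
    seq(gc_range[1], gc_range[2], length.out = N)
  ids <- sprintf("g%02d", seq_len(N))
  models <- vector("list", N)
  genomes <- vector("list", N)
  at_idx <- c(1, 4)  # A, T columns
  gc_idx <- c(2, 3)  # C, G columns
  for (g in seq_len(N)) {
    gc <- targets[g]
    base <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    rows <- matrix(rep(base, each = 4^order), ncol = 4)
    rows <- rows * exp(jitter * rnorm(base::length(rows)))
    # re-pin every row's G+C mass to the target so the genome GC is honored
    rows[, gc_idx] <- rows[, gc_idx] * gc / rowSums(rows[, gc_idx, drop = FALSE])
    rows[, at_idx] <- rows[, at_idx] * (1 - gc) /
      rowSums(rows[, at_idx, drop = FALSE])
    cumrows <- t(apply(rows, 1, cumsum))
    codes <- markov_walk(cumrows, order, length)
    genomes[[g]] <- paste(DNA_BASES[codes], collapse = "")
    models[[g]] <- markov_model(rows, order = order)
  }
  names(genomes) <- ids
  names(models) <- ids
  attr(genomes, "generator_models") <- models
  genomes
}

#' Simulate paired-end reads from a genome panel
#'
#' Draws \code{n_pairs} fragments: a genome per fragment with probability
#' proportional to abundance (optionally weighted by genome length, the
#' default, interpreting the abundance vector as organism abundance), a
#' uniform fragment start, mate 1 read forward from the fragment start and
#' mate 2 reverse-complemented from the fragment end. Substitution errors
#' are applied independently per base at \code{error_rate}, uniform over the
#' three alternative bases; no indels.
#'
#' @param genomes named list/vector of genome sequences.
#' @param abundance relative abundance vector over the genomes.
#' @param n_pairs number of read pairs (>= 1).
#' @param read_len read length in bp (default 150).
#' @param insert total fragment span in bp (default 300, i.e. abutting
#'   mates); must be >= read_len and <= the shortest genome.
#' @param error_rate per-base substitution probability in [0, 1).
#' @param weight_by_length multiply abundance by genome length when drawing
#'   the source genome.
#' @return list with \code{mate1}, \code{mate2} (\code{DNAStringSet}s of
#'   length n_pairs) and \code{source} (integer genome index per pair).
#' @export
simulate_sample <- function(genomes, abundance, n_pairs, read_len = 150,
                            insert = 300, error_rate = 0,
                            weight_by_length = TRUE) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (insert < read_len) stop("insert must be >= read_len")
  gset <- lapply(genomes, function(s) as_dna(s)[[1]])
  glen <- vapply(gset, base::length, integer(1))
  if (any(glen < insert)) stop("every genome must be at least `insert` long")
  w <- abundance * if (weight_by_length) glen else 1
  if (any(w < 0) || sum(w) <= 0) stop("invalid abundance vector")
  src <- sample.int(length(gset), n_pairs, replace = TRUE, prob = w / sum(w))
  m1 <- vector("list", length(gset))
  m2 <- vector("list", length(gset))
  pair_order <- integer(n_pairs)
  taken <- 0L
  for (g in seq_along(gset)) {
    idx <- which(src == g)
    if (!base::length(idx)) next
    starts <- sample.int(glen[g] - insert + 1L, base::length(idx),
                         replace = TRUE)
    m1[[g]] <- Biostrings::extractAt(
      gset[[g]], IRanges::IRanges(starts, width = read_len))
    m2[[g]] <- Biostrings::reverseComplement(Biostrings::extractAt(
      gset[[g]], IRanges::IRanges(starts + insert - read_len, width = read_len)))
    pair_order[idx] <- taken + seq_along(idx)
    taken <- taken + base::length(idx)
  }
  mate1 <- do.call(c, m1[!vapply(m1, is.null, logical(1))])[pair_order]
  mate2 <- do.call(c, m2[!vapply(m2, is.null, logical(1))])[pair_order]
  if (error_rate > 0) {
    mate1 <- add_substitutions(mate1, error_rate)
    mate2 <- add_substitutions(mate2, error_rate)
  }
  names(mate1) <- sprintf("p%07d/1", seq_len(n_pairs))
  names(mate2) <- sprintf("p%07d/2", seq_len(n_pairs))
  list(mate1 = mate1, mate2 = mate2, source = src)
}

# iid substitution errors, uniform over the 3 alternative bases, applied to a
# fixed-width DNAStringSet.
add_substitutions <- function(reads, rate) {
  wd <- Biostrings::width(reads)
  long <- unlist(reads)
  B <- base::length(long)
  hits <- which(runif(B) < rate)
  if (base::length(hits)) {
    old <- as.character(Biostrings::extractAt(
      long, IRanges::IRanges(hits, width = 1)))
    old_i <- match(old, DNA_BASES)
    new_i <- (old_i - 1L + sample.int(3, base::length(hits), replace = TRUE)) %% 4L + 1L
    long <- Biostrings::replaceLetterAt(long, hits, DNA_BASES[new_i])
  }
  ends <- cumsum(wd)
  out <- Biostrings::DNAStringSet(long, start = ends - wd + 1L, end = ends)
  names(out) <- names(reads)
  out
}

#' Describe a simulated community study
#'
#' Bundles the design parameters of the two supported study shapes: a
#' \code{"group"} design (g groups of replicate samples, each group a Zipf
#' center from an independent genome ordering, replicates perturbed with the
#' variance-scaled noise) and a \code{"gradient"} design (one ordering, one
#' sample per alpha on a strictly increasing grid, sd-scaled noise).
#'
#' @param mode "group" or "gradient".
#' @param n_genomes number of genomes in the panel.
#' @param alpha Zipf exponent (group mode).
#' @param alpha_grid strictly increasing vector of exponents (gradient mode).
#' @param n_groups,replicates group-mode shape (samples = n_groups x
#'   replicates).
#' @param noise "sd1" (default), "variance10sq" or "variance10".
#' @param depth read pairs per sample (>= 1).
#' @param read_len read length in bp.
#' @param insert fragment span in bp.
#' @param error_rate per-base substitution rate.
#' @return a \code{study_design} list.
#' @export
study_design <- function(mode = c("group", "gradient"), n_genomes = 100,
                         alpha = 0.3, alpha_grid = seq(0.30, 0.70, by = 0.02),
                         n_groups = 3, replicates = 20, noise = NULL,
                         depth = 100000, read_len = 150, insert = 300,
                         error_rate = 0) {
  mode <- match.arg(mode)
  if (depth < 1) stop("depth must be >= 1")
  if (mode == "gradient" && any(diff(alpha_grid) <= 0))
    stop("alpha_grid must be strictly increasing")
  if (is.null(noise)) noise <- "sd1"
  noise <- match.arg(noise, c("sd1", "variance10sq", "variance10"))
  structure(list(mode = mode, n_genomes = n_genomes, alpha = alpha,
                 alpha_grid = alpha_grid, n_groups = n_groups,
                 replicates = replicates, noise = noise, depth = depth,
                 read_len = read_len, insert = insert,
                 error_rate = error_rate),
            class = "study_design")
}

#' Simulate a full community study
#'
#' Group mode: draws one random genome ordering per group, turns it into a
#' Zipf center at the design's alpha, perturbs the center once per replicate
#' sample, and simulates reads per sample. Gradient mode: one ordering
#' shared by all samples, one sample per alpha on the grid (perturbed), so
#' the community composition shifts continuously along the grid. Ground
#' truth (group labels or alpha values) is returned alongside the reads.
#' All randomness derives from the single seed through per-sample substreams,
#' so identical seeds give identical read sets.
#'
#' @param design a \code{study_design}.
#' @param genomes named genome panel (e.g. from [synth_genomes()]); its
#'   length must equal the design's \code{n_genomes}.
#' @param seed integer seed driving all randomness.
#' @return list with \code{samples} (named list; each has \code{mate1},
#'   \code{mate2}, \code{source}, \code{abundance}), \code{truth}
#'   (data.frame sample/label or sample/alpha) and \code{design}.
#' @export
simulate_study <- function(design, genomes, seed = 1) {
  stopifnot(inherits(design, "study_design"))
  if (base::length(genomes) != design$n_genomes)
    stop("genome panel size (", base::length(genomes),
         ") != design n_genomes (", design$n_genomes, ")")
  N <- design$n_genomes
  set.seed(seed)
  samples <- list()
  truth <- NULL
  if (design$mode == "group") {
    orderings <- lapply(seq_len(design$n_groups),
                        function(g) sample.int(N, N))
    sample_seeds <- sample.int(.Machine$integer.max - 1,
                               design$n_groups * design$replicates)
    s <- 0L
    for (g in seq_len(design$n_groups)) {
      center <- zipf_abundance(design$alpha, N, ordering = orderings[[g]])
      for (rep in seq_len(design$replicates)) {
        s <- s + 1L
        id <- sprintf("g%d_r%02d", g, rep)
        set.seed(sample_seeds[s])
        ab <- perturb_abundance(center, model = design$noise)
        sm <- simulate_sample(genomes, ab, design$depth,
                              read_len = design$read_len,
                              insert = design$insert,
                              error_rate = design$error_rate)
        sm$abundance <- ab
        samples[[id]] <- sm
        truth <- rbind(truth, data.frame(sample = id,
                                         label = paste0("group", g)))
      }
    }
  } else {
    na <- base::length(design$alpha_grid)
    ordering <- sample.int(N, N)
    sample_seeds <- sample.int(.Machine$integer.max - 1, na)
    for (i in seq_len(na)) {
      a <- design$alpha_grid[i]
      id <- sprintf("a%.2f", a)
      set.seed(sample_seeds[i])
      ab <- perturb_abundance(zipf_abundance(a, N, ordering = ordering),
                              model = design$noise)
      sm <- simulate_sample(genomes, ab, design$depth,
                            read_len = design$read_len,
                            insert = design$insert,
                            error_rate = design$error_rate)
      sm$abundance <- ab
      samples[[id]] <- sm
      truth <- rbind(truth, data.frame(sample = id, alpha = a))
    }
  }
  list(samples = samples, truth = truth, design = design)
}
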