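#' Dissimilarity matrix over several read sets
#'
#' Runs the full per-sample pipeline — classify reads into the GC bins,
#' accumulate per-bin k-tuple counts and background models, centralize, and
#' evaluate the chosen measure on every pair.
#'
#' @param read_sets named list of read sets (character vectors or
#'   \code{DNAStringSet}s; pool paired mates beforehand).
#' @param bins a \code{genome_bins} from [build_genome_bins()].
#' @param k tuple size.
#' @param background_order background-expectation Markov order
#'   (default: the bins' classification order); must be <= k - 2.
#' @param measure "d2s" or "d2star".
#' @param ... passed on to [bin_sample()].
#' @return a \code{d2_dissim} matrix.
#' @export
compare_samples <- function(read_sets, bins, k, background_order = NULL,
                            measure = c("d2s", "d2star"), ...) {
  measure <- match.arg(measure)
  binned <- lapply(read_sets, bin_sample, bins = bins, k = k,
                   background_order = background_order, ...)
  pairwise_dissimilarity(binned, measure = measure, k = k)
}

#' Score group recovery of a dissimilarity matrix
#'
#' Clusters the samples with UPGMA and scores the tree against the
#' polytomous reference tree of the known grouping by rooted triplet
#' distance.
#'
#' @param dm a dissimilarity matrix with sample labels.
#' @param groups named vector sample id -> group label.
#' @return list with \code{tree}, \code{reference}, \code{triplet_distance},
#'   \code{max_triplets} (= choose(n, 3)) and \code{fraction}
#'   (distance / maximum, in [0, 1]; smaller is better).
#' @export
group_recovery <- function(dm, groups) {
  tree <- upgma(dm)
  ref <- reference_tree(groups[rownames(dm)])
  td <- triplet_distance(tree, ref)
  mx <- choose(nrow(dm), 3)
  list(tree = tree, reference = ref, triplet_distance = td,
       max_triplets = mx, fraction = td / mx)
}

#' Score gradient recovery of a dissimilarity matrix
#'
#' Ordinates the samples by PCoA and reports the magnitude (and sign) of the
#' Pearson correlation between PC1 and the known gradient.
#'
#' @param dm a dissimilarity matrix with sample labels.
#' @param gradient numeric vector in the matrix's sample order.
#' @return list with \code{ordination}, \code{pcc} (|r|) and
#'   \code{pcc_signed}.
#' @export
gradient_recovery <- function(dm, gradient) {
  ord <- pcoa(dm, dims = 2)
  list(ordination = ord,
       pcc = gradient_correlation(ord, gradient),
       pcc_signed = gradient_correlation(ord, gradient, signed = TRUE))
}

#' Desk-scale group-design benchmark
#'
#' End-to-end experiment on a synthetic three-group community: generates a
#' genome panel spanning the GC range, simulates a group-design study (Zipf
#' centers perturbed per replicate), trains GC bins on the panel, and scores
#' UPGMA group recovery by triplet distance — once with the requested number
#' of bins and once without binning (C = 1). The default Zipf exponent,
#' 0.3 log(100) / log(12), preserves the 100-genome reference design's
#' most-to-least-abundant dynamic range (about 4:1, since max/min = N^alpha)
#' at the 12-genome desk scale; genomes default to order-3 chains so that an
#' order-2 background model underfits them, as any low-order Markov model
#' underfits a real genome.
#'
#' @param seed integer seed for panel and study.
#' @param n_genomes,genome_length,gc_range,genome_order panel parameters.
#' @param n_groups,replicates,depth,alpha,error_rate,noise study parameters
#'   (depth = read pairs per sample).
#' @param k,order,bins,measure analysis parameters (order is both the
#'   classification and background order).
#' @return list with \code{fraction} and \code{fraction_nobin} (triplet
#'   distance as a fraction of choose(n, 3)), the raw distances, and the
#'   dissimilarity matrices.
#' @export
group_recovery_benchmark <- function(seed, n_genomes = 12,
                                     genome_length = 100000,
                                     gc_range = c(0.3, 0.7), genome_order = 3,
                                     n_groups = 3, replicates = 5,
                                     depth = 20000,
                                     alpha = 0.3 * log(100) / log(12),
                                     error_rate = 0, k = 5, order = 2,
                                     bins = 4, measure = "d2s",
                                     noise = NULL) {
  set.seed(seed)
  panel <- synth_genomes(n_genomes, gc_range = gc_range,
                         length = genome_length, order = genome_order)
  design <- study_design("group", n_genomes = n_genomes, alpha = alpha,
                         n_groups = n_groups, replicates = replicates,
                         depth = depth, error_rate = error_rate,
                         noise = noise)
  study <- simulate_study(design, panel, seed = seed)
  reads <- lapply(study$samples, function(s) c(s$mate1, s$mate2))
  groups <- setNames(study$truth$label, study$truth$sample)
  bset <- build_genome_bins(panel, C = bins, order = order)
  bset1 <- build_genome_bins(panel, C = 1, order = order)
  # binned arm: expectation under the reference-trained bin models (the
  # bin-combined statistic); un-binned arm: the classic sample-estimated
  # background of the original d2S/d2*
  dm <- compare_samples(reads, bset, k = k, background_order = order,
                        measure = measure, expectation_from = "reference")
  dm1 <- compare_samples(reads, bset1, k = k, background_order = order,
                         measure = measure)
  r <- group_recovery(dm, groups)
  r1 <- group_recovery(dm1, groups)
  list(fraction = r$fraction, fraction_nobin = r1$fraction,
       triplet_distance = r$triplet_distance,
       triplet_distance_nobin = r1$triplet_distance,
       max_triplets = r$max_triplets, dm = dm, dm_nobin = dm1,
       truth = study$truth)
}

#' Desk-scale gradient-design benchmark
#'
#' End-to-end experiment on a synthetic alpha-gradient community: one Zipf
#' ordering shifted along a strictly increasing alpha grid with sd-scaled
#' perturbation, then PCoA gradient recovery scored by |PCC| between PC1 and
#' alpha — with the requested binning and without (C = 1).
#'
#' The panel keeps the reference design's 100 genomes (the gradient signal
#' scales with the community's effective dimensionality); the grid is
#' thinned to one sample per alpha step of 0.05.
#'
#' @inheritParams group_recovery_benchmark
#' @param alpha_grid strictly increasing alpha values (one sample each).
#' @return list with \code{pcc}, \code{pcc_nobin}, the signed correlations
#'   and the dissimilarity matrices.
#' @export
gradient_recovery_benchmark <- function(seed, n_genomes = 100,
                                        genome_length = 100000,
                                        gc_range = c(0.3, 0.7),
                                        genome_order = 3,
                                        alpha_grid = seq(0.30, 0.70, by = 0.05),
                                        depth = 20000, error_rate = 0,
                                        k = 7, order = 2, bins = 4,
                                        measure = "d2star") {
  set.seed(seed)
  panel <- synth_genomes(n_genomes, gc_range = gc_range,
                         length = genome_length, order = genome_order)
  design <- study_design("gradient", n_genomes = n_genomes,
                         alpha_grid = alpha_grid, depth = depth,
                         error_rate = error_rate)
  study <- simulate_study(design, panel, seed = seed)
  reads <- lapply(study$samples, function(s) c(s$mate1, s$mate2))
  bset <- build_genome_bins(panel, C = bins, order = order)
  bset1 <- build_genome_bins(panel, C = 1, order = order)
  dm <- compare_samples(reads, bset, k = k, background_order = order,
                        measure = measure, expectation_from = "reference")
  dm1 <- compare_samples(reads, bset1, k = k, background_order = order,
                         measure = measure)
  g <- gradient_recovery(dm, study$truth$alpha)
  g1 <- gradient_recovery(dm1, study$truth$alpha)
  list(pcc = g$pcc, pcc_nobin = g1$pcc, pcc_signed = g$pcc_signed,
       pcc_signed_nobin = g1$pcc_signed, dm = dm, dm_nobin = dm1,
       truth = study$truth)
}

#' Read-classification accuracy on a two-genome GC contrast
#'
#' Generates two synthetic genomes from order-1 chains at the given GC
#' targets, trains a two-bin classifier on them, simulates reads of the
#' requested length from each genome in equal proportion, and reports the
#' fraction of reads classified into their source genome's bin.
#'
#' @param seed integer seed.
#' @param gc two GC targets (default 0.25 and 0.75).
#' @param read_len read length in bp.
#' @param n_pairs read pairs simulated per genome.
#' @param order classification Markov order.
#' @param genome_length genome length in bp.
#' @return classification accuracy in [0, 1].
#' @export
binning_accuracy_experiment <- function(seed, gc = c(0.25, 0.75),
                                        read_len = 150, n_pairs = 1000,
                                        order = 1, genome_length = 50000) {
  set.seed(seed)
  panel <- synth_genomes(2, gc_range = gc, length = genome_length,
                         order = order)
  bset <- build_genome_bins(panel, C = 2, order = order)
  correct <- 0L
  total <- 0L
  for (g in 1:2) {
    ab <- c(0, 0); ab[g] <- 1
    sm <- simulate_sample(panel, ab, n_pairs, read_len = read_len,
                          insert = max(300, read_len))
    lab <- classify_reads(c(sm$mate1, sm$mate2), bset)
    correct <- correct + sum(lab == bset$assignment[g])
    total <- total + length(lab)
  }
  correct / total
}
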