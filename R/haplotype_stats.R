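# Haplotype collapsing and sampling-sufficiency statistics for aligned
# mitochondrial (COI) sequences.

#' Build a validated set of aligned sequences
#'
#' @param seq_id Character vector of unique sequence identifiers.
#' @param residues Character vector of aligned sequences over
#'   A/C/G/T, IUPAC ambiguity codes and '-'; uppercased on ingestion.
#' @param locality,group Optional per-sequence annotations.
#' @return A data.frame of class `aligned_sequences` with one row per
#'   sequence.
#' @export
aligned_sequences <- function(seq_id, residues, locality = NA_character_,
                              group = NA_character_) {
  stopifnot(is.character(seq_id), is.character(residues),
            length(seq_id) == length(residues))
  if (!length(seq_id)) stop("empty alignment")
  if (anyDuplicated(seq_id))
    stop("duplicated seq_id: ",
         paste(unique(seq_id[duplicated(seq_id)]), collapse = ", "))
  residues <- toupper(residues)
  lens <- nchar(residues)
  if (length(unique(lens)) != 1L)
    stop("unequal sequence lengths; offending ids: ",
         paste(seq_id[lens != lens[1]], collapse = ", "))
  allowed <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-", "?")
  chars <- unique(unlist(strsplit(residues, "", fixed = TRUE)))
  bad <- setdiff(chars, allowed)
  if (length(bad))
    stop("invalid residue characters: ", paste(bad, collapse = ", "))
  out <- data.frame(seq_id = seq_id, residues = residues,
                    locality = rep_len(locality, length(seq_id)),
                    group = rep_len(group, length(seq_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("aligned_sequences", class(out))
  out
}

# A, B, ..., Z, AA, AB, ... for arbitrarily many haplotypes
hap_labels <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  extra <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(LETTERS, extra)[seq_len(n)]
}

#' Collapse an alignment into haplotypes
#'
#' Sequences that are identical as strings (after uppercasing) share a
#' haplotype; identity is exact, so a sequence bearing an N is its own
#' haplotype unless it matches another character-for-character. Labels A,
#' B, ... are assigned by order of first occurrence in the input.
#'
#' @param alignment An [aligned_sequences()] data.frame.
#' @return A data.frame (class `haplotype_table`) with columns
#'   `haplotype_id`, `count`, `frequency`, plus an attribute
#'   `per_locality`: a locality x haplotype count table (when localities
#'   are annotated).
#' @examples
#' aln <- aligned_sequences(paste0("s", 1:5),
#'                          c("ACGT", "ACGT", "ACGT", "ACGA", "ACGA"))
#' collapse_haplotypes(aln)  # A: 3 (60%), B: 2 (40%)
#' @export
collapse_haplotypes <- function(alignment) {
  stopifnot(inherits(alignment, "aligned_sequences"))
  uniq <- unique(alignment$residues)
  labels <- hap_labels(length(uniq))
  assigned <- labels[match(alignment$residues, uniq)]
  counts <- as.integer(table(factor(assigned, levels = labels)))
  out <- data.frame(haplotype_id = labels, count = counts,
                    frequency = counts / sum(counts),
                    stringsAsFactors = FALSE)
  if (!all(is.na(alignment$locality))) {
    attr(out, "per_locality") <-
      table(locality = alignment$locality,
            haplotype = factor(assigned, levels = labels))
  }
  attr(out, "assignment") <- stats::setNames(assigned, alignment$seq_id)
  class(out) <- c("haplotype_table", class(out))
  out
}

#' Pairwise nucleotide differences with pairwise deletion
#'
#' Only sites where both residues are unambiguous bases (A/C/G/T) are
#' compared; gaps and ambiguity codes are deleted pairwise.
#'
#' @param a,b Aligned sequence strings of equal length (or single rows of an
#'   [aligned_sequences()] data.frame).
#' @return A list with `diff_count` and `compared_sites`.
#' @export
pairwise_differences <- function(a, b) {
  a <- extract_residues(a); b <- extract_residues(b)
  if (nchar(a) != nchar(b)) stop("sequences have unequal lengths")
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  ok <- av %in% bases & bv %in% bases
  list(diff_count = sum(av[ok] != bv[ok]), compared_sites = sum(ok))
}

extract_residues <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L, "residues" %in% names(x))
    x$residues
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    x
  }
}

#' Probability that a sample contains all haplotypes
#'
#' Coalescent-theory closed form: a sample of n sequences contains every
#' haplotype segregating in the population with probability
#' p = (n - 1) / (n + 1).
#'
#' @param n Sample size (integer >= 1); vectorised.
#' @return The probability, in \[0, 1).
#' @examples
#' prob_all_haplotypes_sampled(39)  # 0.95
#' @export
prob_all_haplotypes_sampled <- function(n) {
  if (any(!is.finite(n)) || any(n < 1) || any(n != round(n)))
    stop("n must be an integer >= 1")
  (n - 1) / (n + 1)
}

#' Smallest sample size attaining a target sampling probability
#'
#' Inverts the coalescent formula: the smallest integer n with
#' (n - 1)/(n + 1) >= p_target.
#'
#' @param p_target Target probability in \[0, 1).
#' @return Integer sample size.
#' @examples
#' min_n_for_prob(0.95)  # 39
#' @export
min_n_for_prob <- function(p_target) {
  stopifnot(length(p_target) == 1L, is.finite(p_target))
  if (p_target < 0) stop("p_target must be >= 0")
  if (p_target >= 1) stop("p_target = 1 is unreachable at finite n")
  n <- max(1L, as.integer(floor((1 + p_target) / (1 - p_target))) - 1L)
  while ((n - 1) / (n + 1) < p_target) n <- n + 1L
  n
}

#' Minimum sample size to detect a haplotype of given frequency
#'
#' n = ln(1 - beta) / ln(1 - p): the number of sequences needed to observe,
#' with confidence beta, at least one copy of a haplotype segregating at
#' frequency p (equivalently, to exclude its presence if none is seen).
#' Returned as a real number; round up to plan an actual sample.
#'
#' @param p_freq Haplotype frequency, in (0, 1).
#' @param beta Desired confidence level, in (0, 1); default 0.95.
#' @param ceiling If `TRUE`, return the integer ceiling.
#' @return Required sample size (real, or integer when `ceiling = TRUE`).
#' @examples
#' min_detection_sample_size(0.5, 0.75)  # 2
#' @export
min_detection_sample_size <- function(p_freq, beta = 0.95, ceiling = FALSE) {
  if (any(!is.finite(p_freq)) || any(p_freq <= 0) || any(p_freq >= 1))
    stop("p_freq must lie strictly in (0, 1)")
  if (any(!is.finite(beta)) || any(beta <= 0) || any(beta >= 1))
    stop("beta must lie strictly in (0, 1)")
  n <- log(1 - beta) / log(1 - p_freq)
  if (ceiling) base::ceiling(n) else n
}

#' Iterative sampling-sufficiency trace over an ordered sample stream
#'
#' Processes haplotype labels in sampling order. After each new sample the
#' observed haplotype frequencies are updated, p is set to the frequency of
#' the rarest haplotype observed so far, and the detection sample size
#' n = ln(1 - beta)/ln(1 - p) is re-evaluated. Steps at which only one
#' haplotype has been observed (p would be 1) are recorded as not
#' computable (`NA`).
#'
#' @param samples Character vector of haplotype labels in sampling order
#'   (>= 2 samples).
#' @param beta Confidence level for the detection formula (default 0.95).
#' @return A data.frame (class `sufficiency_trace`) with one row per step:
#'   `step`, `n_haplotypes`, `p_all_sampled` (coalescent formula at the
#'   current n), `rare_frequency`, `n_min_detect`. The final row's
#'   `n_min_detect` is the procedure's result, also in attribute `final`.
#' @export
iterative_sufficiency <- function(samples, beta = 0.95) {
  stopifnot(is.character(samples))
  if (length(samples) < 2) stop("need at least 2 samples")
  n <- length(samples)
  out <- data.frame(step = seq_len(n),
                    n_haplotypes = integer(n),
                    p_all_sampled = numeric(n),
                    rare_frequency = numeric(n),
                    n_min_detect = numeric(n))
  for (k in seq_len(n)) {
    tab <- table(samples[seq_len(k)])
    out$n_haplotypes[k] <- length(tab)
    out$p_all_sampled[k] <- prob_all_haplotypes_sampled(k)
    if (length(tab) >= 2) {
      p <- min(tab) / k
      out$rare_frequency[k] <- p
      out$n_min_detect[k] <- min_detection_sample_size(p, beta)
    } else {
      out$rare_frequency[k] <- NA_real_
      out$n_min_detect[k] <- NA_real_
    }
  }
  attr(out, "final") <- out$n_min_detect[n]
  attr(out, "beta") <- beta
  class(out) <- c("sufficiency_trace", class(out))
  out
}
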