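#!/usr/bin/env Rscript
# Stage 3 — haplotype frequencies and sampling sufficiency.
#
# Collapses the synthetic COI stream, then answers the two design
# questions of a haplotype survey: (1) how many samples suffice to have
# seen every haplotype (coalescent closed form p = (n-1)/(n+1)); (2) how
# many samples exclude a haplotype of frequency p at confidence beta
# (n = ln(1-beta)/ln(1-p)), updated iteratively as samples accrue.

suppressMessages(library(sapsource))

syn <- "results/synthetic"
haps <- readLines(file.path(syn, "haplotype_stream.txt"))

freqs <- table(haps) / length(haps)
cat(sprintf("observed haplotype frequencies over %d samples: %s\n",
            length(haps),
            paste(sprintf("%s %.1f%%", names(freqs), 100 * freqs),
                  collapse = ", ")))

n_obs <- length(haps)
cat(sprintf("p(all haplotypes seen | n = %d) = %.3f\n",
            n_obs, prob_all_haplotypes_sampled(n_obs)))
cat(sprintf("samples needed for p = 0.95: %d\n", min_n_for_prob(0.95)))

trace <- iterative_sufficiency(haps, beta = 0.95)
write.csv(as.data.frame(trace), "results/sufficiency_trace.csv",
          row.names = FALSE)
final <- attr(trace, "final")
cat(sprintf("iterative detection sample size (beta = 0.95): %.2f (ceil %d)\n",
            final, ceiling(final)))
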