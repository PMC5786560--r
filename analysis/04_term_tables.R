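#!/usr/bin/env Rscript
# Step 4 — term tables behind the word clouds.
#
# Top-40 terms of each dream document in the rank-reduced matrix, and the
# jointly weighted table (average of the substance-side and dream-side term
# ranks) for the four substances most similar to high-lucidity dreams.
# These tables are what a word-cloud renderer would consume; no images are
# produced here.

library(dreamlsa)

st <- readRDS("scratch/space.rds")
space <- st$space

rk <- rank_documents(similarity_to_reference(space, "dream_high"))
probes <- head(rk$label, 4)

for (ref in c("dream_high", "dream_low")) {
  tt <- top_terms(space, ref, n = 40)
  write.table(tt, sprintf("results/top_terms_%s.tsv", ref), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jt <- joint_rank_weights(space, probes, ref, n = 40)
  write.table(jt, sprintf("results/joint_terms_%s.tsv", ref), sep = "\t",
              quote = FALSE, row.names = FALSE)
  shared <- intersect(head(tt$term, 40), head(jt$term, 40))
  cat(ref, ": top term '", tt$term[1], "'; ", length(shared),
      " of the joint top-40 also in the document's own top-40.\n", sep = "")
}
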