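#!/usr/bin/env Rscript
# Step 2 — preprocess the corpus and build the latent semantic space.
#
# Reads the simulated corpus back through the same readers a real corpus
# would use, pools reports into one document per substance plus the two
# dream-lucidity documents, censors substance documents, weights terms by
# tf-idf (plain ln(N/n_t), terms kept only inside the open 5%-95%
# document-frequency band), and truncates the SVD at D = 20.

library(dreamlsa)

reports <- load_reports("scratch/benchmark/reports.jsonl", "jsonl")
censor <- load_censor_list("scratch/benchmark/censor.txt")

docs <- assemble_documents(reports, min_reports = 10)
docs <- preprocess_collection(docs, censor = censor)
tdm <- build_term_document_matrix(docs, df_min = 0.05, df_max = 0.95)
space <- truncate_svd(tdm, D = 20)

saveRDS(list(docs = docs, tdm = tdm, space = space), "scratch/space.rds")

stats <- docs$preprocess_stats
write.table(stats, "results/preprocess_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(component = seq_along(space$sigma),
                       singular_value = space$sigma),
            "results/singular_values.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Documents:", length(docs$label), "(",
    sum(docs$source == "substance"), "substances + 2 dream classes )\n")
cat("Vocabulary: ", length(tdm$vocabulary), " terms survive the df band (of ",
    length(tdm$df_all), " candidates); censoring removed ",
    sum(stats$censored_out), " tokens.\n", sep = "")
cat("Retained rank D = 20 captures ",
    round(100 * sum(space$sigma[1:20]^2) / sum(space$sigma^2), 1),
    "% of the spectral energy.\n", sep = "")
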