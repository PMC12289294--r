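#!/usr/bin/env Rscript
# Apply the study inclusion filters (date window, US page-admin country,
# exact-duplicate removal) and annotate every retained post with its
# exclusive drug category and adverse-event set.

library(aeminer)

posts <- read_corpus("results/corpus.csv")
fc <- filter_corpus(posts, corpus_filter())
r <- fc$report
cat(sprintf("Posts: %d read -> %d in window -> %d US pages -> %d after removing %d duplicates\n",
            r$n_input, r$n_after_date, r$n_after_country, r$n_after_dedup,
            r$n_duplicates_removed))
jsonlite::write_json(unclass(r), "results/filter_report.json",
                     auto_unbox = TRUE, pretty = TRUE)

ann <- annotate_corpus(fc$posts)
cat(sprintf("Annotated %d drug-mentioning posts (%.1f%% of deduplicated corpus)\n",
            nrow(ann), 100 * nrow(ann) / r$n_after_dedup))
counts <- sort(table(ann$drug_category), decreasing = TRUE)
for (d in names(counts)) {
  cat(sprintf("  %-12s %6d (%.1f%%)\n", d, counts[[d]],
              100 * counts[[d]] / nrow(ann)))
}
stopifnot(sum(counts) == nrow(ann))  # exclusive category partition

out <- ann
out$ae_ids <- vapply(out$ae_ids, paste, character(1), collapse = ";")
readr::write_csv(out, "results/annotated.csv")
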