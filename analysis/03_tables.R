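#!/usr/bin/env Rscript
# Per-drug adverse-event frequency/percentage table and the share of
# posts mentioning any adverse event.

library(aeminer)

ann <- readr::read_csv("results/annotated.csv", show_col_types = FALSE)
ann$ae_ids <- lapply(strsplit(dplyr::coalesce(ann$ae_ids, ""), ";"),
                     function(s) s[nzchar(s)])

ft <- frequency_table(ann)
readr::write_csv(ft$cells, "results/frequency_table_long.csv")
readr::write_csv(frequency_table_wide(ft), "results/frequency_table_wide.csv")
readr::write_csv(ft$drug_totals, "results/drug_totals.csv")

share <- ae_share_of_total(ann)
cat(sprintf("%d of %d posts (%.1f%%) mention at least one adverse event\n",
            share$n_ae_posts, share$n_posts, share$pct))

cat("Top (drug, adverse event) cells by percentage:\n")
top <- dplyr::slice_max(ft$cells, order_by = pct, n = 8)
print(as.data.frame(top[, c("ae_id", "category_id", "n", "total_posts", "pct")]),
      row.names = FALSE)
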