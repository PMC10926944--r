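#!/usr/bin/env Rscript

# Stage 4 — rank genes by methylation discordance: maximum promoter JSD
# (and dNME) within 2 kb of the TSS, permutation significance for the top
# genes, and top-N gene lists for downstream enrichment tools.

suppressPackageStartupMessages(library(methpel))
source(file.path("analysis", "helpers.R"))

sim <- load_sim()
tracks <- load_tracks(sim)
diff <- differential_track(tracks$tumor, tracks$normal)
out <- res_dir("ranking")

rankings <- list(
  promoter_jsd = rank_genes(diff, sim$genes, mode = "promoter_jsd"),
  promoter_dnme = rank_genes(diff, sim$genes, mode = "promoter_dnme"),
  gene_body_jsd = rank_genes(diff, sim$genes, mode = "gene_body_jsd")
)

rankings$promoter_jsd <- add_gene_significance(
  rankings$promoter_jsd, diff, sim$tumor, sim$normal, sim$map,
  sim$partition, top_n = 10, n_perm = 199, seed = 404)

for (mode in names(rankings)) {
  rk <- rankings[[mode]]
  write.table(as.data.frame(rk),
              file.path(out, sprintf("ranking_%s.tsv", mode)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  # top-N list for external enrichment tools
  top_n <- min(100, sum(!is.na(rk$rank)))
  writeLines(rk$gene[!is.na(rk$rank)][seq_len(top_n)],
             file.path(out, sprintf("top%d_%s.txt", top_n, mode)))
}

rk <- rankings$promoter_jsd
planted <- sim$genes$label[sim$genes$planted]
message(sprintf("planted genes in the promoter-JSD top 20: %d/%d",
                sum(planted %in% rk$gene[!is.na(rk$rank) & rk$rank <= 20]),
                length(planted)))
message("top 10 genes by promoter JSD:")
print(head(rk[, c("gene", "statistic", "rank", "p_value", "q_value")], 10))
message("wrote ", out)
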