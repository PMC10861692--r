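#!/usr/bin/env Rscript
# Step 4 — reporting.
#
# Writes the convergent/divergent key-event tables in Markdown and shows the
# packaged reference fixtures: the 13-pathway nephrotoxicity inventory
# (endpoints only; interiors are namespaced placeholders) merged through the
# same builder, and the published convergence classification lists used to
# cross-check classify_convergence() once a full curated table is available.

suppressPackageStartupMessages(library(aopnet))

m <- summarise_network(read_network_json("results/network.json"))$metrics
write_convergence_md(m, "results/convergence_tables.md")
cat("wrote results/convergence_tables.md\n\n")

fx1 <- table1_fixture()
net1 <- build_network(fx1$records)
cat(sprintf(
  "pathway inventory fixture: %d AOPs -> endpoint network of %d nodes / %d edges\n",
  length(net1$aop_ids), nrow(net1$nodes), nrow(net1$edges)
))
cat(sprintf("  dropped on build: %s\n", paste(net1$dropped_nodes, collapse = ", ")))
shared_mie <- fx1$expected$shared_mie
cat(sprintf("  only MIE shared by multiple AOPs (%s): %s\n",
            paste(fx1$expected$shared_mie_aops, collapse = ", "), shared_mie))

fx2 <- table2_fixture()
cat(sprintf(
  "convergence reference fixture: %d convergent / %d divergent key events\n",
  nrow(fx2$expected$convergent), nrow(fx2$expected$divergent)
))
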