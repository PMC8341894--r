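#!/usr/bin/env Rscript
# Stage 5: phylogenetic PCA of the residual trait space with ML Pagel's
# lambda, plus PGLS of the leading axes on body size (is any axis secretly
# allometric?).

suppressMessages(library(morphconv))

tree <- parse_newick(readLines("results/data/tree.nwk"))
traits <- utils::read.csv("results/data/traits.csv")
res <- utils::read.csv("results/residual_traits.tsv", sep = "\t")
rownames(res) <- res$species
Y <- as.matrix(res[tree$tip.label, -1])

p <- phylo_pca(tree, Y)
cat("ML lambda:", round(p$lambda, 3), "\n")
cat("variance explained by PC1-PC3:",
    round(100 * sum(p$var_explained[1:3]), 1), "%\n")

size <- stats::setNames(traits$standard_length, traits$species)
sr <- score_regression(tree, p$scores, size)
print(sr, digits = 3)

utils::write.table(cbind(species = rownames(p$scores),
                         as.data.frame(p$scores)),
                   "results/pca_scores.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(cbind(trait = rownames(p$loadings),
                         as.data.frame(p$loadings)),
                   "results/pca_loadings.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(sr, "results/pca_score_regressions.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
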