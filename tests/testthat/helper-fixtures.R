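# Shared fixtures: tiny deterministic trees and fast sampler settings.

newick_tree <- function(txt) {
  phylomi::validate_phylogeny(ape::read.tree(text = txt))
}

# three tips, ultrametric: ((A:1,B:1):1,C:2);
balanced3 <- function() newick_tree("((A:1,B:1):1,C:2);")

# quick Gibbs settings for unit tests (acceptance uses the defaults)
quick_sampler <- function(chains = 2) {
  sampler_settings(n_iter = 1200, burnin = 200, thin = 2, chains = chains)
}

# brute-force phylogenetic covariance: root-to-MRCA path sums via ape's
# mrca() and node depths -- an independent route from vcv.phylo()
vcv_path_oracle <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  mrca <- ape::mrca(tree)
  n <- length(tree$tip.label)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n))
    C[i, j] <- depth[mrca[tree$tip.label[i], tree$tip.label[j]]]
  C
}

# small complete trait table over a tree for mixed-model tests
toy_table <- function(tree, y, body = NULL) {
  n <- length(tree$tip.label)
  if (is.null(body)) body <- seq_len(n) / n
  df <- data.frame(row.names = tree$tip.label,
                   log_ecv = as.numeric(y), log_body = as.numeric(body))
  trait_table(df, c(log_ecv = "continuous", log_body = "continuous"))
}
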