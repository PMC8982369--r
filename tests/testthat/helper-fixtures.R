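# Shared fixtures, built in code and cached per test file.

.fixture_env <- new.env(parent = emptyenv())

# A small six-generation population (230 animals x 300 SNPs on 3 chromosomes).
small_pop <- function() {
  if (is.null(.fixture_env$small_pop)) {
    f <- simulate_founders(n_snps = 300, n_chromosomes = 3, seed = 42)
    d <- population_design(generation_sizes = c(30, 20, 50, 50, 30, 50))
    .fixture_env$small_pop <- drop_generations(f, d, seed = 43)
  }
  .fixture_env$small_pop
}

# An additive trait (h2 = 0.4, 60 QTL) on the small population, precorrected.
small_sim <- function() {
  if (is.null(.fixture_env$small_sim)) {
    sim <- simulate_trait(small_pop(),
                          trait_architecture(n_additive_qtl = 60,
                                             h2_additive = 0.4),
                          seed = 44)
    sim$traits <- precorrect(sim$traits)
    .fixture_env$small_sim <- sim
  }
  .fixture_env$small_sim
}

# Random complete dosage panel with all SNPs segregating.
random_panel <- function(n, m, seed = 1, p_range = c(0.1, 0.5)) {
  set.seed(seed)
  repeat {
    p <- runif(m, p_range[1], p_range[2])
    dos <- sapply(p, function(pp) rbinom(n, 2, pp))
    dimnames(dos) <- list(sprintf("a%04d", seq_len(n)),
                          sprintf("s%04d", seq_len(m)))
    pm <- colMeans(dos) / 2
    if (all(pm > 0 & pm < 1)) break
  }
  map <- data.frame(snp_id = colnames(dos), chrom = 1,
                    pos_cM = seq_len(m))
  genotype_panel(dos, map)
}
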