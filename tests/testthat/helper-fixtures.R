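# Shared fixtures: scaled-down designs and the standard preprocessing chain.

# compact two-species design for fast unit tests
small_design <- function(seed = 1, modules = data.frame(
                           label = c("M1", "M2", "S1"),
                           size = c(40, 40, 40),
                           shared = c(TRUE, TRUE, FALSE),
                           within_cor = c(0.8, 0.8, 0.8)),
                         n_genes = 300, n_shared = 180,
                         samples_per_study = c(20, 20),
                         batch_shift_sd = 0.5, trait_links = data.frame(
                           trait = "disease", module = "M1", effect = 1.5)) {
  synthetic_design(n_genes = n_genes, n_shared_orthologs = n_shared,
                   modules = modules,
                   samples_per_study = samples_per_study,
                   batch_shift_sd = batch_shift_sd,
                   trait_links = trait_links, seed = seed)
}

# per-study Z-score merge of one species of a simulated meta-set
merge_species <- function(sim, sp) {
  st <- sim$study[[sp]]
  zscore_merge(lapply(unique(st), function(s)
    sim$expr[[sp]][, st == s, drop = FALSE]))
}

# ortholog-harmonized shared-gene pair of matrices plus truth labels
shared_pair <- function(sim) {
  ea <- merge_species(sim, "a")
  eb <- suppressMessages(map_orthologs(merge_species(sim, "b"),
                                       sim$truth$ortholog_table))
  sh <- intersect_genes(list(ea, eb))
  list(a = sh[[1]], b = sh[[2]],
       truth = sim$truth$modules$a[rownames(sh[[1]])])
}

# module assignment usable as reference modules: background -> unassigned
truth_as_modules <- function(truth) {
  out <- truth
  out[out == "background"] <- "unassigned"
  out
}

# single-factor block matrix: m genes correlated rho around one factor
factor_block <- function(m, n, rho, f = rnorm(n)) {
  r <- sqrt(rho)
  r * rep(1, m) %o% f + sqrt(1 - rho) * matrix(rnorm(m * n), m, n)
}
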