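# Shared fixtures: all molecular inputs are built in code.

# canonical-equality expectation for SMILES written in different orders
expect_canon_equal <- function(got, want) {
  expect_equal(canonical_smiles(got), canonical_smiles(want))
}

# small class-valid building blocks used across files
fix <- list(
  tbaa = "CC(=O)CC(=O)OC(C)(C)C",       # tert-butyl acetoacetate
  etaa = "CC(=O)CC(=O)OCC",             # ethyl acetoacetate
  phenylacetylene = "C#Cc1ccccc1",
  cpca = "OC(=O)C1CC1",                 # cyclopropane carboxylic acid
  alkynes = c("C#Cc1ccccc1", "C#CCCO", "C#CC1CC1", "C#Cc1ccncc1"),
  acids = c("OC(=O)C1CC1", "OC(=O)c1ccc(Cl)cc1", "OC(=O)CCO",
            "OC(=O)c1ccncc1"),
  actmeths = c("CC(=O)CC(=O)OC(C)(C)C", "CC(=O)CC(=O)OCC",
               "N#CCC(=O)C1CC1", "CS(=O)(=O)CC(=O)C")
)

# evaluate expr under a fixed seed, restoring the global RNG afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# deterministic standard-normal sample without touching the global RNG
rnorm2d <- function(n, seed, mean = c(0, 0), sd = c(1, 1)) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cbind(stats::rnorm(n, mean[1], sd[1]), stats::rnorm(n, mean[2], sd[2]))
}
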